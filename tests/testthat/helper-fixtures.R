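# Shared fixtures, built in code at test time.

# small complete study: panel + two trait models + trial
small_study <- function(seed = 7, n = 150, n_chrom = 3, snps = 50, n_qtl = 6,
                        ...) {
  cfg <- sim_config(n_accessions = n, n_chromosomes = n_chrom,
                    snps_per_chromosome = snps, n_qtl = n_qtl, seed = seed, ...)
  simulate_panel_study(cfg)
}

check_ids <- function(study, role) {
  study$trial$checks$accession[study$trial$checks$role == role]
}

# membership-index accession means for one trait of a study
indicator_means <- function(study, trait = "plant_weight") {
  X <- relative_trait(study$trial$trial, trait)
  membership_index(X, check_ids(study, "tolerant_check"),
                   check_ids(study, "sensitive_check"))
}

# genotype_matrix built directly from a calls matrix (one chromosome,
# positions spaced `spacing` bp apart)
toy_geno <- function(calls, spacing = 1000L, chrom = "Chr01") {
  calls <- as.matrix(calls)
  n_snp <- nrow(calls)
  snps <- data.frame(chrom = chrom, pos = seq_len(n_snp) * spacing,
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(calls, snps, sprintf("ACC%03d", seq_len(ncol(calls))))
}

# marker_set with hand-set allele calls: `calls` is accession x marker
# integer codes, `effects` optional list for building models
toy_marker_set <- function(calls, chrom = "Chr01") {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("%s_M%d", chrom, seq_len(ncol(calls)))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("ACC%03d", seq_len(nrow(calls)))
  ids <- colnames(calls)
  alleles <- lapply(seq_len(ncol(calls)), function(j) {
    k <- max(calls[, j]); sprintf("h%d", seq_len(k))
  })
  freqs <- lapply(seq_len(ncol(calls)), function(j)
    as.numeric(table(factor(calls[, j], levels = seq_len(max(calls[, j])))) /
                 nrow(calls)))
  info <- data.frame(id = ids, chrom = chrom,
                     start_bp = seq_along(ids) * 1000L,
                     end_bp = seq_along(ids) * 1000L,
                     n_snps = 1L,
                     n_alleles = vapply(alleles, length, integer(1)),
                     type = "block", stringsAsFactors = FALSE)
  structure(list(info = info, alleles = setNames(alleles, ids),
                 freqs = setNames(freqs, ids),
                 snp_rows = setNames(as.list(seq_along(ids)), ids),
                 calls = calls, accessions = rownames(calls)),
            class = "marker_set")
}

# qtl_allele_matrix built directly from per-accession allele labels
toy_allele_matrix <- function(alleles, effect_map, subpop = NULL,
                              intercept = 0) {
  alleles <- as.matrix(alleles)
  effects <- alleles
  eff <- matrix(NA_real_, nrow(alleles), ncol(alleles),
                dimnames = dimnames(alleles))
  for (j in colnames(alleles))
    eff[, j] <- effect_map[[j]][alleles[, j]]
  structure(list(alleles = alleles, effects = eff, intercept = intercept,
                 predicted = setNames(intercept + rowSums(eff),
                                      rownames(alleles)),
                 pos_neg = NULL,
                 subpop = if (is.null(subpop)) NULL else
                   setNames(subpop, rownames(alleles)),
                 allele_effects = effect_map, freq_tables = NULL),
            class = "qtl_allele_matrix")
}
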