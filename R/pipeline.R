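#' Run the full QTL-allele analysis pipeline
#'
#' Orchestrates phenotype -> SNPLDB -> similarity -> association (per
#' trait) -> QTL-allele matrix -> subpopulation differentiation -> optimal
#' crosses, writing every stage table under `out_dir`.  Inputs are either a
#' synthetic-study configuration (`sim`) or real-data paths (genotypes,
#' trial CSV, check roster, subpopulation labels).  Every output file
#' carries a header with the package version, a configuration hash and the
#' master seed; tables are written atomically (write-then-rename).
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()], or `NULL` when real inputs are given.
#' @param genotype_path,genotype_format,trial_path,checks_path,subpop_path
#'   real-data inputs (see [read_genotypes()], [read_trial_csv()]; the
#'   check roster is a TSV with columns `accession`, `role`; the subpop
#'   file a TSV with columns `accession`, `subpop`).
#' @param max_missing_het,min_maf QC thresholds.
#' @param max_dist,frac_strong LD-block parameters (bp; fraction).
#' @param rare_allele_floor haplotype-merge floor.
#' @param k_eigen number of structure eigenvectors.
#' @param alpha1 stage-one pre-selection level.
#' @param alpha_entry,alpha_stay stepwise entry/staying levels.
#' @param h2_cap optional explicit heritability cap per trait (named
#'   numeric); defaults to each trait's ANOVA heritability estimate.
#' @param n_progeny,q,criterion cross-prediction parameters.
#' @param n_top_parents crosses are ranked among the top accessions by
#'   predicted weighted value (full enumeration of a large panel is
#'   available directly through [enumerate_crosses()] + [rank_optimal()]).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param verbose log stage counts to the console.
#' @return list with all stage objects (`phenotype`, `h2`, `markers`,
#'   `eigen`, `models`, `matrices`, `differentiation`, `turnover`,
#'   `crosses`, `counts`, `paths`).
#' @export
run_pipeline <- function(out_dir,
                         sim = NULL,
                         genotype_path = NULL, genotype_format = "vcf",
                         trial_path = NULL, checks_path = NULL,
                         subpop_path = NULL,
                         max_missing_het = 0.30, min_maf = 0.01,
                         max_dist = 200000, frac_strong = 0.95,
                         rare_allele_floor = 0.01,
                         k_eigen = 10L,
                         alpha1 = 0.05, alpha_entry = 0.01, alpha_stay = 0.01,
                         h2_cap = NULL,
                         n_progeny = 2000L, q = 95,
                         criterion = "exceeds_population_max",
                         n_top_parents = 25L,
                         seed = 1L, verbose = TRUE) {
  if (is.null(sim) && (is.null(genotype_path) || is.null(trial_path) ||
                       is.null(checks_path)))
    stop("provide either `sim` or genotype/trial/checks paths", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(sim = unclass(sim), max_missing_het = max_missing_het,
              min_maf = min_maf, max_dist = max_dist,
              frac_strong = frac_strong, rare_allele_floor = rare_allele_floor,
              k_eigen = k_eigen, alpha1 = alpha1, alpha_entry = alpha_entry,
              alpha_stay = alpha_stay, n_progeny = n_progeny, q = q,
              criterion = criterion, n_top_parents = n_top_parents,
              seed = seed)
  hash <- config_hash(cfg)
  hdr <- c(sprintf("qtlallele %s", as.character(utils::packageVersion("qtlallele"))),
           sprintf("config_hash %s", hash), sprintf("seed %d", seed))
  stamp <- function(df, name) write_tsv_atomic(df, file.path(out_dir, name), hdr)
  counts <- list()

  # --- inputs ---------------------------------------------------------------
  if (!is.null(sim)) {
    set.seed(seed)
    study <- simulate_panel_study(sim)
    geno_raw <- study$panel$geno
    trial <- study$trial$trial
    checks <- study$trial$checks
    subpop <- study$panel$subpop
  } else {
    geno_raw <- read_genotypes(genotype_path, genotype_format)
    trial <- read_trial_csv(trial_path)
    checks <- read_tsv_plain(checks_path)
    subpop <- NULL
    if (!is.null(subpop_path)) {
      sp <- read_tsv_plain(subpop_path)
      subpop <- setNames(sp$subpop, sp$accession)
    }
  }
  tol_ids <- checks$accession[checks$role == "tolerant_check"]
  sen_ids <- checks$accession[checks$role == "sensitive_check"]

  # --- phenotype ------------------------------------------------------------
  traits <- unique(trial$trait)
  indicator <- list(); h2 <- list()
  for (tr in traits) {
    X <- relative_trait(trial, tr)
    mem <- membership_index(X, tol_ids, sen_ids)
    indicator[[tr]] <- mem$accession_mean
    h2[[tr]] <- anova_heritability(mem)
    msg("phenotype[%s]: %d accessions, h2 = %.3f", tr,
        length(mem$accession_mean), h2[[tr]]$h2, verbose = verbose)
  }
  ind_tab <- data.frame(accession = names(indicator[[1]]),
                        stringsAsFactors = FALSE)
  for (tr in traits) ind_tab[[tr]] <- as.numeric(indicator[[tr]])
  if (!is.null(subpop)) ind_tab$subpop <- subpop[ind_tab$accession]
  stamp(ind_tab, "indicators.tsv")
  summ <- summarize_indicators(indicator[[traits[1]]], indicator[[traits[2]]],
                               subpop = subpop)
  stamp(summ$summary, "indicator_summary.tsv")

  # --- snpldb ---------------------------------------------------------------
  qc <- qc_filter_snps(geno_raw, max_missing_het, min_maf)
  imp <- impute_missing(qc$geno)
  blocks <- find_ld_blocks(imp$geno, max_dist = max_dist, min_maf = min_maf,
                           frac_strong = frac_strong)
  markers <- build_snpldb_markers(imp$geno, blocks, rare_allele_floor)
  counts$snps_kept <- qc$report$n_kept
  counts$blocks_found <- nrow(blocks)
  counts$markers <- nrow(markers$info)
  msg("snpldb: %d/%d SNPs kept, %d blocks, %d markers",
      qc$report$n_kept, qc$report$n_input, nrow(blocks), nrow(markers$info),
      verbose = verbose)
  write_marker_set(markers, file.path(out_dir, "markers.tsv"),
                   file.path(out_dir, "marker_calls.tsv"), hdr)

  # --- structure ------------------------------------------------------------
  simm <- genetic_similarity(markers)
  eig <- top_eigenvectors(simm, k = min(k_eigen, nrow(simm) - 1L))
  stamp(data.frame(accession = rownames(eig$vectors), eig$vectors),
        "eigenvectors.tsv")
  stamp(data.frame(component = seq_along(eig$values), eigenvalue = eig$values),
        "eigenvalues.tsv")

  # --- association per trait ------------------------------------------------
  models <- list(); matrices <- list()
  for (tr in traits) {
    cap <- if (!is.null(h2_cap)) h2_cap[[tr]] else h2[[tr]]$h2
    s1 <- stage1_scan(markers, indicator[[tr]], eig, alpha = alpha1)
    counts[[paste0("preselected_", tr)]] <- length(s1$preselected)
    mod <- stage2_stepwise(markers, indicator[[tr]], eig, h2_cap = cap,
                           alpha_entry = alpha_entry, alpha_stay = alpha_stay,
                           candidates = s1$preselected)
    counts[[paste0("selected_", tr)]] <- nrow(mod$loci)
    msg("gwas[%s]: %d preselected, %d selected, total R2 = %.3f (cap %.3f)",
        tr, length(s1$preselected), nrow(mod$loci), mod$total_r2, cap,
        verbose = verbose)
    models[[tr]] <- mod
    stamp(s1$scan, sprintf("scan_%s.tsv", tr))
    stamp(mod$loci, sprintf("qtl_%s.tsv", tr))
    eff <- do.call(rbind, lapply(names(mod$allele_effects), function(id)
      data.frame(locus = id, allele = names(mod$allele_effects[[id]]),
                 effect = unname(mod$allele_effects[[id]]),
                 stringsAsFactors = FALSE)))
    if (!is.null(eff)) stamp(eff, sprintf("allele_effects_%s.tsv", tr))
    matrices[[tr]] <- build_matrix(mod, markers, subpop)
    cells <- matrix(paste(matrices[[tr]]$alleles,
                          signif(matrices[[tr]]$effects, 4), sep = ":"),
                    nrow(matrices[[tr]]$alleles),
                    dimnames = dimnames(matrices[[tr]]$alleles))
    stamp(data.frame(accession = rownames(cells), cells, check.names = FALSE),
          sprintf("allele_matrix_%s.tsv", tr))
  }

  # --- differentiation ------------------------------------------------------
  differentiation <- NULL; turnover <- NULL
  if (!is.null(subpop) && length(unique(subpop)) >= 2) {
    pops <- unique(subpop)
    differentiation <- lapply(matrices, subpop_differentiation)
    turnover <- lapply(matrices, allele_turnover,
                       ancestral = pops[1], derived = pops[2])
    for (tr in traits) {
      stamp(differentiation[[tr]], sprintf("differentiation_%s.tsv", tr))
      tt <- turnover[[tr]]
      parts <- list()
      if (nrow(tt$excluded)) parts$x <- cbind(change = "X", tt$excluded)
      if (nrow(tt$emerged)) parts$n <- cbind(change = "N", tt$emerged)
      if (length(parts))
        stamp(do.call(rbind, unname(parts)),
              sprintf("allele_turnover_%s.tsv", tr))
    }
    counts$differentiated <- sum(vapply(differentiation, function(d)
      sum(d$significant), numeric(1)))
  }

  # --- optimal crosses ------------------------------------------------------
  wav_parent <- weighted_average_value(
    matrices[[traits[1]]]$predicted, matrices[[traits[2]]]$predicted,
    h2[[traits[1]]]$h2, h2[[traits[2]]]$h2)
  top <- names(sort(wav_parent, decreasing = TRUE))
  top <- top[seq_len(min(n_top_parents, length(top)))]
  crosses <- enumerate_crosses(top)
  ranking <- rank_optimal(crosses, matrices,
                          observed = indicator,
                          n_progeny = n_progeny, q = q,
                          criterion = criterion, joint = TRUE,
                          h2 = vapply(traits, function(tr) h2[[tr]]$h2,
                                      numeric(1)),
                          seed = seed)
  counts$crosses_ranked <- nrow(ranking)
  counts$crosses_optimal <- sum(ranking$optimal)
  msg("crosses: %d ranked among top %d parents, %d optimal (%s)",
      nrow(ranking), length(top), sum(ranking$optimal), criterion,
      verbose = verbose)
  stamp(as.data.frame(ranking), "cross_ranking.tsv")

  # --- run metadata ---------------------------------------------------------
  meta <- data.frame(key = c("config_hash", "seed", "alpha1", "alpha_entry",
                             "alpha_stay", "criterion", "q", "n_progeny",
                             vapply(traits, function(tr)
                               paste0("h2_cap_", tr), character(1))),
                     value = c(hash, seed, alpha1, alpha_entry, alpha_stay,
                               criterion, q, n_progeny,
                               vapply(traits, function(tr)
                                 sprintf("%.4f", models[[tr]]$h2_cap),
                                 character(1))),
                     stringsAsFactors = FALSE)
  stamp(meta, "run_metadata.tsv")

  invisible(list(phenotype = indicator, h2 = h2, summary = summ,
                 qc_report = qc$report, blocks = blocks, markers = markers,
                 eigen = eig, models = models, matrices = matrices,
                 differentiation = differentiation, turnover = turnover,
                 crosses = ranking, counts = counts, config_hash = hash,
                 out_dir = out_dir))
}
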