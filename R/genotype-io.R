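#' Construct a genotype matrix for an inbred panel
#'
#' Container for biallelic SNP calls of inbred accessions.  Calls are coded
#' as integers: `0` = homozygous reference, `1` = homozygous alternate,
#' `2` = heterozygous, `NA` = missing.  Rows are SNPs, columns accessions.
#'
#' @param calls integer matrix (SNPs x accessions) with codes 0/1/2/NA.
#' @param snps data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt` and optionally `id`; positions must be strictly increasing within
#'   a chromosome.
#' @param accessions character vector of accession ids.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snps, accessions) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == nrow(snps), ncol(calls) == length(accessions))
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("genotype codes must be 0 (ref), 1 (alt), 2 (het) or NA",
                     call. = FALSE)
  if (is.null(snps$id)) snps$id <- paste0(snps$chrom, "_", snps$pos)
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("SNP positions not strictly increasing on %s", ch),
           call. = FALSE)
  }
  dimnames(calls) <- list(snps$id, accessions)
  structure(list(calls = calls, snps = snps, accessions = accessions),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d accessions (%d chromosomes)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$snps$chrom))))
  miss <- mean(is.na(x$calls))
  het <- mean(x$calls == 2L, na.rm = TRUE)
  cat(sprintf("  missing %.2f%%, heterozygous %.2f%%\n", 100 * miss, 100 * het))
  invisible(x)
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("sim_panel: %d accessions, %d blocks, subpops: %s\n",
              length(x$subpop), nrow(x$truth$blocks),
              paste(names(table(x$subpop)), table(x$subpop),
                    sep = "=", collapse = ", ")))
  print(x$geno)
  invisible(x)
}

gt_string <- c(`0` = "0/0", `1` = "1/1", `2` = "0/1")

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a plain-text VCFv4.2 file with GT fields only.  Homozygous calls are
#' written as `0/0` / `1/1`, heterozygous as `0/1`, missing as `./.`.
#'
#' @param geno a [genotype_matrix].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=qtlallele",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$accessions), collapse = "\t")),
             con)
  gt <- matrix("./.", nrow(geno$calls), ncol(geno$calls))
  ok <- !is.na(geno$calls)
  gt[ok] <- gt_string[as.character(geno$calls[ok])]
  body <- paste(geno$snps$chrom, geno$snps$pos, geno$snps$id, geno$snps$ref,
                geno$snps$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write a genotype matrix as a plain SNP x accession TSV
#'
#' Columns `chrom`, `pos`, `ref`, `alt`, `id`, then one column per accession
#' holding codes 0/1/2 or NA.
#'
#' @param geno a [genotype_matrix].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_genotype_matrix <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- cbind(geno$snps[c("chrom", "pos", "ref", "alt", "id")],
              as.data.frame(geno$calls))
  write_tsv_atomic(df, path)
}

#' Read genotypes from VCF or a plain matrix TSV
#'
#' VCF reading is delegated to \pkg{vcfR}; only biallelic SNPs with GT calls
#' are accepted and coordinates stay 1-based.  Multi-allelic sites are
#' rejected with the offending site named.  The TSV format is the one
#' written by [write_genotype_matrix()].
#'
#' @param path input file.
#' @param format `"vcf"` or `"matrix_tsv"`.
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi))
      stop(sprintf("multi-allelic site(s) not supported, e.g. %s:%s",
                   fix$CHROM[multi][1], fix$POS[multi][1]), call. = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    code <- function(g) {
      g <- gsub("\\|", "/", g)
      out <- rep(NA_integer_, length(g))
      out[g %in% "0/0"] <- 0L
      out[g %in% "1/1"] <- 1L
      out[g %in% c("0/1", "1/0")] <- 2L
      out
    }
    calls <- matrix(code(gt), nrow = nrow(gt), dimnames = dimnames(gt))
    snps <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                       ref = fix$REF, alt = fix$ALT,
                       id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                   paste0(fix$CHROM, "_", fix$POS), fix$ID),
                       stringsAsFactors = FALSE)
    genotype_matrix(calls, snps, colnames(gt))
  } else {
    df <- read_tsv_plain(path)
    meta_cols <- c("chrom", "pos", "ref", "alt", "id")
    if (!all(meta_cols %in% names(df)))
      stop("matrix TSV must have columns chrom, pos, ref, alt, id", call. = FALSE)
    acc <- setdiff(names(df), meta_cols)
    calls <- as.matrix(df[acc])
    suppressWarnings(storage.mode(calls) <- "integer")
    bad <- which(!(calls %in% c(0L, 1L, 2L) | is.na(calls)), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("bad genotype code at row %d, column '%s'",
                   bad[1, 1], acc[bad[1, 2]]), call. = FALSE)
    genotype_matrix(calls, df[meta_cols], acc)
  }
}

#' Write trial data as a tidy CSV
#'
#' @param trial a `sim_trial` or a tidy trial data.frame.
#' @param path output CSV.
#' @param checks_path optional path for the check roster TSV.
#' @return the path, invisibly.
#' @export
write_trial_csv <- function(trial, path, checks_path = NULL) {
  df <- if (inherits(trial, "sim_trial")) trial$trial else trial
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(checks_path) && inherits(trial, "sim_trial"))
    write_tsv_atomic(trial$checks, checks_path)
  invisible(path)
}

#' Read a tidy trial CSV (accession, replication, regime, trait, value)
#'
#' @param path input CSV.
#' @return a data.frame.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "replication", "regime", "trait", "value")
  if (!all(need %in% names(df)))
    stop("trial CSV must have columns accession, replication, regime, trait, value",
         call. = FALSE)
  df
}

#' Write the ground-truth QTL effects of a synthetic study
#'
#' @param models named list of `true_qtl_model` (per trait).
#' @param path output TSV (locus, allele, effect per trait).
#' @return the path, invisibly.
#' @export
write_truth_tsv <- function(models, path) {
  rows <- do.call(rbind, lapply(names(models), function(tr) {
    m <- models[[tr]]
    do.call(rbind, lapply(names(m$allele_effects), function(b) {
      e <- m$allele_effects[[b]]
      data.frame(trait = tr, locus = b, allele = names(e), effect = unname(e),
                 stringsAsFactors = FALSE)
    }))
  }))
  write_tsv_atomic(rows, path)
}
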