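#' Read a QTL summary table
#'
#' Expected columns: `qtl` (label), `marker` (SNPLDB id), `n_alleles`,
#' `neglog10p`, `r2` (per-locus contribution on the percentage scale).
#' Two such transcribed tables for the published 564-accession soybean
#' drought-tolerance scan ship in `inst/extdata/` (one per indicator).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_qtl_summary <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("qtl", "marker", "n_alleles", "neglog10p", "r2")
  if (!all(need %in% names(df)))
    stop("QTL summary needs columns qtl, marker, n_alleles, neglog10p, r2",
         call. = FALSE)
  df
}

#' Variance bookkeeping of a detected QTL system
#'
#' Splits a QTL table into large-contribution (LC, `r2 >= lc_threshold`)
#' and small-contribution (SC) major QTL, sums contributions and allele
#' counts, and computes the unmapped minor-QTL share `h2 - total R2` and
#' each category's portion of the total genetic contribution
#' (`100 * R2 / h2`).  All contributions are on the percentage scale.
#'
#' @param tbl data.frame from [read_qtl_summary()] (or a `stepwise_model`'s
#'   loci table with `r2` rescaled to percent).
#' @param h2 trait heritability in percent (the total genetic contribution).
#' @param lc_threshold LC/SC split on per-locus `r2`, percent.
#' @return list with `n_qtl`, `n_alleles`, `total_r2`, `unmapped_share`,
#'   `portion_of_h2`, and per-category rows in `categories`
#'   (whole / lc_major / sc_major: n_qtl, n_alleles, r2, portion_of_h2).
#' @export
qtl_system_summary <- function(tbl, h2, lc_threshold = 1.0) {
  lc <- tbl$r2 >= lc_threshold
  cat_row <- function(name, sub) {
    data.frame(category = name, n_qtl = nrow(sub),
               n_alleles = sum(sub$n_alleles), r2 = sum(sub$r2),
               portion_of_h2 = 100 * sum(sub$r2) / h2,
               stringsAsFactors = FALSE)
  }
  categories <- rbind(cat_row("whole", tbl),
                      cat_row("lc_major", tbl[lc, , drop = FALSE]),
                      cat_row("sc_major", tbl[!lc, , drop = FALSE]))
  list(n_qtl = nrow(tbl), n_alleles = sum(tbl$n_alleles),
       total_r2 = sum(tbl$r2), unmapped_share = h2 - sum(tbl$r2),
       portion_of_h2 = 100 * sum(tbl$r2) / h2, h2 = h2,
       categories = categories)
}

#' Union bookkeeping over two trait QTL systems
#'
#' Counts QTL and alleles in the union of two QTL tables, where markers
#' shared between the traits (same SNPLDB id) are counted once, and shared
#' alleles are the allele counts at the shared markers.
#'
#' @param tbl_a,tbl_b QTL summary tables of the two traits.
#' @return list with `shared_markers`, `n_shared`, `n_union_qtl`,
#'   `shared_alleles`, `n_union_alleles`.
#' @export
qtl_system_union <- function(tbl_a, tbl_b) {
  shared <- intersect(tbl_a$marker, tbl_b$marker)
  shared_alleles <- sum(tbl_a$n_alleles[tbl_a$marker %in% shared])
  list(shared_markers = shared, n_shared = length(shared),
       n_union_qtl = nrow(tbl_a) + nrow(tbl_b) - length(shared),
       shared_alleles = shared_alleles,
       n_union_alleles = sum(tbl_a$n_alleles) + sum(tbl_b$n_alleles) -
         shared_alleles)
}
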