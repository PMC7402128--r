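#' Build the accession x locus QTL-allele matrix
#'
#' Organizes the detected QTL and their allele effects into a compact
#' matrix: for every accession and every selected locus, the allele the
#' accession carries and that allele's estimated effect.  The accession's
#' predicted indicator value is the model intercept plus the row sum of
#' effects (covariates held at their population mean).
#'
#' @param model a `stepwise_model`.
#' @param markers the `marker_set` the model was fitted on.
#' @param subpop optional named character vector of subpopulation labels.
#' @return a `qtl_allele_matrix`: list with `alleles` (character matrix of
#'   carried allele strings), `effects` (numeric matrix), `intercept`,
#'   `predicted` (named numeric), `pos_neg` (data.frame of per-accession
#'   positive/negative allele counts), `subpop`, `freq_tables` (per locus,
#'   allele x subpopulation counts).
#' @export
build_matrix <- function(model, markers, subpop = NULL) {
  stopifnot(inherits(model, "stepwise_model"), inherits(markers, "marker_set"))
  loci <- model$loci$id
  if (!all(loci %in% colnames(markers$calls)))
    stop("model loci missing from the marker set", call. = FALSE)
  acc <- model$accessions
  calls <- markers$calls[acc, loci, drop = FALSE]
  alleles <- matrix("", nrow(calls), ncol(calls), dimnames = dimnames(calls))
  effects <- matrix(0, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  for (id in loci) {
    lab <- markers$alleles[[id]][calls[, id]]
    alleles[, id] <- lab
    effects[, id] <- model$allele_effects[[id]][lab]
  }
  predicted <- model$intercept + rowSums(effects)
  pos_neg <- data.frame(accession = acc,
                        positive = rowSums(effects > 0),
                        negative = rowSums(effects < 0),
                        stringsAsFactors = FALSE)
  freq_tables <- NULL
  if (!is.null(subpop)) {
    sp <- subpop[acc]
    freq_tables <- lapply(setNames(loci, loci), function(id)
      table(factor(alleles[, id], levels = markers$alleles[[id]]), sp))
  }
  structure(list(alleles = alleles, effects = effects,
                 intercept = model$intercept,
                 predicted = setNames(predicted, acc),
                 pos_neg = pos_neg,
                 subpop = if (is.null(subpop)) NULL else subpop[acc],
                 allele_effects = model$allele_effects,
                 freq_tables = freq_tables),
            class = "qtl_allele_matrix")
}

#' @export
print.qtl_allele_matrix <- function(x, ...) {
  cat(sprintf("qtl_allele_matrix: %d accessions x %d loci, intercept %.3f\n",
              nrow(x$alleles), ncol(x$alleles), x$intercept))
  invisible(x)
}

#' Chi-square test of allele-frequency differentiation between subpopulations
#'
#' Per locus, a Pearson chi-square test (no continuity correction) on the
#' alleles x subpopulation count table.  Loci with any expected cell below 5
#' are flagged, not dropped.  A Benjamini-Hochberg adjusted p-value column
#' is reported alongside the raw decisions.
#'
#' @param matrix_ a `qtl_allele_matrix` built with subpopulation labels.
#' @param alpha significance level on the raw p-value.
#' @return data.frame per locus: `locus`, `chisq`, `df`, `p`, `p_bh`,
#'   `significant`, `low_expected`.
#' @export
subpop_differentiation <- function(matrix_, alpha = 0.05) {
  stopifnot(inherits(matrix_, "qtl_allele_matrix"))
  if (is.null(matrix_$subpop))
    stop("matrix was built without subpopulation labels", call. = FALSE)
  sp <- factor(matrix_$subpop)
  if (nlevels(sp) < 2 || any(table(sp) == 0))
    stop("need >= 2 non-empty subpopulations", call. = FALSE)
  loci <- colnames(matrix_$alleles)
  if (!length(loci))
    return(data.frame(locus = character(), chisq = numeric(), df = integer(),
                      p = numeric(), p_bh = numeric(), significant = logical(),
                      low_expected = logical()))
  rows <- lapply(loci, function(id) {
    tab <- table(matrix_$alleles[, id], sp)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2) {
      return(data.frame(locus = id, chisq = 0, df = 0, p = 1,
                        low_expected = FALSE, stringsAsFactors = FALSE))
    }
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chisq <- sum((tab - expd)^2 / expd)
    df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
    data.frame(locus = id, chisq = chisq, df = df,
               p = pchisq(chisq, df, lower.tail = FALSE),
               low_expected = any(expd < 5), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p <= alpha
  out[c("locus", "chisq", "df", "p", "p_bh", "significant", "low_expected")]
}

#' Allele turnover between an ancestral and a derived subpopulation
#'
#' An allele is *excluded* if it is carried in the ancestral group but
#' absent from the derived group, and *emerged* in the reverse case.
#' Tallies are split by the sign of the allele effect (exact zeros are
#' neutral), and loci are counted once per any change.
#'
#' @param matrix_ a `qtl_allele_matrix` with subpopulation labels.
#' @param ancestral,derived subpopulation label values.
#' @return list with `excluded` and `emerged` (data.frames: locus, allele,
#'   effect, sign), `tally` (counts by class and sign) and
#'   `n_loci_changed`.
#' @export
allele_turnover <- function(matrix_, ancestral, derived) {
  stopifnot(inherits(matrix_, "qtl_allele_matrix"))
  if (is.null(matrix_$subpop))
    stop("matrix was built without subpopulation labels", call. = FALSE)
  anc <- matrix_$subpop == ancestral
  der <- matrix_$subpop == derived
  if (!any(anc) || !any(der))
    stop("ancestral or derived subpopulation is empty", call. = FALSE)
  excl <- list(); emer <- list()
  for (id in colnames(matrix_$alleles)) {
    a <- matrix_$alleles[, id]
    eff <- matrix_$allele_effects[[id]]
    for (al in names(eff)) {
      in_anc <- any(a[anc] == al); in_der <- any(a[der] == al)
      if (!in_anc && !in_der) next
      sign_lab <- if (eff[[al]] > 0) "positive" else
        if (eff[[al]] < 0) "negative" else "neutral"
      row <- data.frame(locus = id, allele = al, effect = unname(eff[[al]]),
                        sign = sign_lab, stringsAsFactors = FALSE)
      if (in_anc && !in_der) excl[[length(excl) + 1L]] <- row
      if (!in_anc && in_der) emer[[length(emer) + 1L]] <- row
    }
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(locus = character(), allele = character(), effect = numeric(),
               sign = character())
  emerged <- if (length(emer)) do.call(rbind, emer) else
    data.frame(locus = character(), allele = character(), effect = numeric(),
               sign = character())
  tally <- data.frame(
    class = c("excluded", "emerged"),
    n = c(nrow(excluded), nrow(emerged)),
    negative = c(sum(excluded$sign == "negative"),
                 sum(emerged$sign == "negative")),
    positive = c(sum(excluded$sign == "positive"),
                 sum(emerged$sign == "positive")),
    stringsAsFactors = FALSE)
  list(excluded = excluded, emerged = emerged, tally = tally,
       n_loci_changed = length(unique(c(excluded$locus, emerged$locus))))
}
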