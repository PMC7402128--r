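# --- design-matrix helpers -------------------------------------------------

# sum-contrast (unweighted sum-to-zero) dummy block for one multi-allele
# marker; codes are 1..K, the K-th level is the reference
sum_contrast_block <- function(codes, K, prefix) {
  if (K < 2) return(NULL)
  B <- matrix(0, length(codes), K - 1L)
  for (j in seq_len(K - 1L)) B[, j] <- (codes == j) - (codes == K)
  colnames(B) <- sprintf("%s.a%d", prefix, seq_len(K - 1L))
  B
}

fit_rss <- function(y, X) {
  f <- lm.fit(X, y)
  sum(f$residuals^2)
}

# intercept (+ centered covariates) design; safe when C is NULL
base_design <- function(ai) {
  X <- matrix(1, length(ai$y), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(ai$C)) X <- cbind(X, ai$C)
  X
}

align_gwas_inputs <- function(markers, phenotype, covariates) {
  acc <- markers$accessions
  phenotype <- phenotype[!is.na(phenotype)]
  shared <- intersect(acc, names(phenotype))
  if (length(shared) < 3)
    stop("phenotype and markers share fewer than 3 accessions", call. = FALSE)
  shared <- acc[acc %in% shared]          # keep marker (panel) order
  y <- as.numeric(phenotype[shared])
  C <- NULL
  if (!is.null(covariates)) {
    cv <- if (is.list(covariates) && !is.null(covariates$vectors))
      covariates$vectors else as.matrix(covariates)
    if (is.null(rownames(cv)))
      stop("covariates must have accession rownames", call. = FALSE)
    C <- cv[shared, , drop = FALSE]
    C <- sweep(C, 2, colMeans(C))          # center: intercept at covariate mean
    if (qr(cbind(1, C))$rank < ncol(C) + 1L)
      stop("covariate matrix is rank deficient", call. = FALSE)
  }
  list(acc = shared, y = y, C = C,
       calls = markers$calls[shared, , drop = FALSE])
}

# --- stage 1 ----------------------------------------------------------------

#' Stage-one single-locus association scan
#'
#' For each multi-allele marker, fits
#' `phenotype ~ intercept + covariates + marker` (marker as a categorical
#' term) and tests the marker by the partial F test against the
#' covariate-only model.  Markers with `p <= alpha` are pre-selected as
#' candidates for the stepwise stage.  Markers with any allele carried by
#' fewer than `min_carriers` accessions are skipped.
#'
#' @param markers a `marker_set`.
#' @param phenotype named numeric vector of accession trait values (the
#'   accession mean of the membership index).
#' @param covariates eigenvector basis from [top_eigenvectors()] (or a plain
#'   matrix with accession rownames), or `NULL`.
#' @param alpha pre-selection significance level.
#' @param min_carriers minimum carriers per allele.
#' @return a `assoc_scan`: list with `scan` (data.frame: id, n_alleles, F,
#'   p, neglog10p, preselected, skipped) and `preselected` (character ids).
#' @export
stage1_scan <- function(markers, phenotype, covariates = NULL, alpha = 0.05,
                        min_carriers = 3L) {
  ai <- align_gwas_inputs(markers, phenotype, covariates)
  n <- length(ai$y)
  X0 <- base_design(ai)
  rss0 <- fit_rss(ai$y, X0)
  p0 <- ncol(X0)
  ids <- colnames(ai$calls)
  Fv <- pv <- rep(NA_real_, length(ids))
  skipped <- logical(length(ids))
  n_all <- integer(length(ids))
  for (m in seq_along(ids)) {
    codes <- ai$calls[, m]
    tab <- tabulate(codes)
    K <- length(tab)
    n_all[m] <- K
    if (K < 2 || any(tab < min_carriers)) { skipped[m] <- TRUE; next }
    B <- sum_contrast_block(codes, K, ids[m])
    X1 <- cbind(X0, B)
    df2 <- n - ncol(X1)
    if (df2 < 1) { skipped[m] <- TRUE; next }
    rss1 <- fit_rss(ai$y, X1)
    Fv[m] <- ((rss0 - rss1) / (K - 1)) / (rss1 / df2)
    pv[m] <- pf(Fv[m], K - 1, df2, lower.tail = FALSE)
  }
  scan <- data.frame(id = ids, n_alleles = n_all, F = Fv, p = pv,
                     neglog10p = -log10(pv), skipped = skipped,
                     preselected = !skipped & !is.na(pv) & pv <= alpha,
                     stringsAsFactors = FALSE)
  structure(list(scan = scan, preselected = ids[scan$preselected],
                 alpha = alpha, n = n),
            class = "assoc_scan")
}

# --- stage 2 ----------------------------------------------------------------

build_design <- function(ai, loci_ids, K_of) {
  X <- base_design(ai)
  for (id in loci_ids)
    X <- cbind(X, sum_contrast_block(ai$calls[, id], K_of[[id]], id))
  X
}

partial_test <- function(y, X_red, X_full) {
  n <- length(y)
  df1 <- ncol(X_full) - ncol(X_red)
  df2 <- n - ncol(X_full)
  if (df2 < 1 || df1 < 1) return(list(F = NA_real_, p = NA_real_,
                                      ss = NA_real_))
  rss_r <- fit_rss(y, X_red); rss_f <- fit_rss(y, X_full)
  Fv <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE), ss = rss_r - rss_f)
}

#' Stage-two stepwise multi-locus multi-allele selection under an h2 cap
#'
#' Forward selection over the pre-selected markers: at each step the
#' candidate with the smallest partial-F p-value given the current model is
#' added if `p <= alpha_entry` and the model's total genetic contribution
#' (R2 of the selected loci beyond the covariates) stays within `h2_cap`;
#' ties are broken by the larger contribution, then by genomic order.
#' After each addition, any included locus whose partial p-value (given the
#' rest of the model) exceeds `alpha_stay` is eliminated.  The final refit
#' yields the intercept, covariate coefficients and per-allele effects
#' under the unweighted sum-to-zero constraint per locus.
#'
#' @param markers a `marker_set`.
#' @param phenotype named numeric vector of accession values.
#' @param covariates eigenvector basis or matrix, or `NULL`.
#' @param h2_cap heritability cap on the total contribution, in (0, 1].
#' @param alpha_entry,alpha_stay entry and staying significance levels.
#' @param candidates marker ids to consider (normally
#'   `stage1_scan(...)$preselected`).
#' @param min_carriers minimum carriers per allele.
#' @return a `stepwise_model`: list with `loci` (data.frame: id, n_alleles,
#'   r2, neglog10p, in selection order), `allele_effects` (per locus, named
#'   by allele string), `intercept`, `covariate_coef`, `total_r2`,
#'   `unmapped_share`, `h2_cap`, `fitted` (named), `accessions`.
#' @export
stage2_stepwise <- function(markers, phenotype, covariates = NULL,
                            h2_cap = 1, alpha_entry = 0.01, alpha_stay = 0.01,
                            candidates, min_carriers = 3L) {
  if (!(h2_cap >= 0 && h2_cap <= 1))
    stop("h2_cap must lie in [0, 1]", call. = FALSE)
  ai <- align_gwas_inputs(markers, phenotype, covariates)
  y <- ai$y; n <- length(y)
  tss <- sum((y - mean(y))^2)
  K_of <- lapply(setNames(colnames(ai$calls), colnames(ai$calls)),
                 function(id) length(tabulate(ai$calls[, id])))
  ok <- vapply(candidates, function(id) {
    tab <- tabulate(ai$calls[, id])
    length(tab) >= 2 && all(tab >= min_carriers)
  }, logical(1))
  candidates <- candidates[ok]
  genomic_rank <- match(candidates, markers$info$id)

  X_cov <- base_design(ai)
  rss_cov <- fit_rss(y, X_cov)
  selected <- character()
  step_guard <- 0L
  repeat {
    step_guard <- step_guard + 1L
    if (step_guard > 200L) { warning("stepwise selection stopped: step limit"); break }
    X_cur <- build_design(ai, selected, K_of)
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    stats <- lapply(pool, function(id) {
      Xc <- cbind(X_cur, sum_contrast_block(ai$calls[, id], K_of[[id]], id))
      if (n - ncol(Xc) < 1) return(list(p = NA_real_, dr2 = NA_real_,
                                        r2_new = NA_real_, refused = TRUE))
      pt <- partial_test(y, X_cur, Xc)
      list(p = pt$p, dr2 = pt$ss / tss,
           r2_new = (rss_cov - fit_rss(y, Xc)) / tss, refused = FALSE)
    })
    p <- vapply(stats, `[[`, numeric(1), "p")
    dr2 <- vapply(stats, `[[`, numeric(1), "dr2")
    r2n <- vapply(stats, `[[`, numeric(1), "r2_new")
    refused <- vapply(stats, `[[`, logical(1), "refused")
    if (any(refused))
      warning("some candidate additions refused: insufficient residual df")
    eligible <- !refused & !is.na(p) & p <= alpha_entry &
      r2n <= h2_cap + 1e-9
    if (!any(eligible)) break
    ord <- order(p, -dr2, genomic_rank[match(pool, candidates)])
    pick <- ord[eligible[ord]][1]
    selected <- c(selected, pool[pick])
    # backward elimination
    repeat {
      if (length(selected) < 2) break
      X_full <- build_design(ai, selected, K_of)
      pstay <- vapply(selected, function(id) {
        X_red <- build_design(ai, setdiff(selected, id), K_of)
        partial_test(y, X_red, X_full)$p
      }, numeric(1))
      worst <- which.max(pstay)
      if (!is.na(pstay[worst]) && pstay[worst] > alpha_stay) {
        selected <- selected[-worst]
      } else break
    }
  }

  finalize_stepwise(ai, markers, selected, K_of, h2_cap, tss, rss_cov)
}

finalize_stepwise <- function(ai, markers, selected, K_of, h2_cap, tss,
                              rss_cov) {
  y <- ai$y
  X <- build_design(ai, selected, K_of)
  fit <- lm.fit(X, y)
  cf <- fit$coefficients
  if (anyNA(cf)) {
    warning("aliased coefficients set to zero in the final refit")
    cf[is.na(cf)] <- 0
  }
  rss_full <- sum(fit$residuals^2)
  total_r2 <- if (length(selected) && tss > 0) (rss_cov - rss_full) / tss else 0
  stopifnot(total_r2 <= h2_cap + 1e-9)

  allele_effects <- list()
  loci_rows <- list()
  for (id in selected) {
    K <- K_of[[id]]
    idx <- which(startsWith(names(cf), paste0(id, ".a")))
    e <- c(cf[idx], -sum(cf[idx]))
    names(e) <- markers$alleles[[id]][seq_len(K)]
    allele_effects[[id]] <- e
    X_red <- build_design(ai, setdiff(selected, id), K_of)
    pt <- partial_test(y, X_red, X)
    loci_rows[[id]] <- data.frame(id = id, n_alleles = K,
                                  r2 = if (tss > 0) pt$ss / tss else 0,
                                  F = pt$F, p = pt$p,
                                  neglog10p = -log10(pt$p),
                                  stringsAsFactors = FALSE)
  }
  loci <- if (length(loci_rows)) do.call(rbind, loci_rows) else
    data.frame(id = character(), n_alleles = integer(), r2 = numeric(),
               F = numeric(), p = numeric(), neglog10p = numeric())
  rownames(loci) <- NULL
  cov_idx <- if (is.null(ai$C)) integer() else 1L + seq_len(ncol(ai$C))
  structure(list(loci = loci,
                 allele_effects = allele_effects,
                 intercept = unname(cf[1]),
                 covariate_coef = cf[cov_idx],
                 total_r2 = total_r2,
                 unmapped_share = max(0, h2_cap - total_r2),
                 h2_cap = h2_cap,
                 fitted = setNames(fit$fitted.values, ai$acc),
                 accessions = ai$acc),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("stepwise_model: %d loci, total R2 = %.3f (cap %.3f, unmapped %.3f)\n",
              nrow(x$loci), x$total_r2, x$h2_cap, x$unmapped_share))
  invisible(x)
}

#' Per-allele effects of one locus under the sum-to-zero constraint
#'
#' Fits `phenotype ~ covariates + other loci + locus` with sum-contrast
#' coding and returns the locus's per-allele effects: each allele's
#' deviation from the unweighted mean of the allele-group means, adjusted
#' for the other model terms.  In a balanced single-locus design without
#' covariates this reduces to the group means minus the grand mean of the
#' group means.
#'
#' @param markers a `marker_set`.
#' @param phenotype named numeric vector.
#' @param locus marker id.
#' @param covariates optional eigenbasis or matrix.
#' @param others other locus ids held in the model.
#' @return named numeric vector of effects summing to zero.
#' @export
estimate_allele_effects <- function(markers, phenotype, locus,
                                    covariates = NULL, others = character()) {
  ai <- align_gwas_inputs(markers, phenotype, covariates)
  K_of <- lapply(setNames(c(others, locus), c(others, locus)),
                 function(id) length(tabulate(ai$calls[, id])))
  m <- finalize_stepwise(ai, markers, c(others, locus), K_of, 1,
                         sum((ai$y - mean(ai$y))^2),
                         fit_rss(ai$y, base_design(ai)))
  m$allele_effects[[locus]]
}

#' Per-locus and total genetic contribution of a fitted model
#'
#' Per-locus contribution is the partial (order-independent) R2: the sum of
#' squares of the locus given all other selected loci and the covariates,
#' divided by the total phenotypic sum of squares.  The total R2 is the
#' contribution of all selected loci beyond the covariates; the unmapped
#' minor-QTL share is `h2_cap - total R2`.
#'
#' @param model a `stepwise_model`.
#' @return list with `per_locus` (data.frame id, r2, neglog10p),
#'   `total_r2`, `unmapped_share`, `h2_cap`.
#' @export
locus_contribution <- function(model) {
  stopifnot(inherits(model, "stepwise_model"))
  list(per_locus = model$loci[c("id", "r2", "neglog10p")],
       total_r2 = model$total_r2,
       unmapped_share = model$unmapped_share,
       h2_cap = model$h2_cap)
}
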