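#' Relative trait value under stress versus non-stress
#'
#' For each accession and replication, computes the ratio of the stress to
#' the non-stress plot value of one trait.  Pairing is within
#' (accession, replication), the only pairing under which a per-replication
#' relative value is well defined in a split-plot two-regime trial.
#'
#' @param trial tidy trial data.frame with columns `accession`,
#'   `replication`, `regime` (`"stress"`/`"nonstress"`), `trait`, `value`.
#' @param trait trait name to extract (e.g. `"plant_weight"`).
#' @return data.frame with columns `accession`, `replication`, `X`
#'   (stress / non-stress ratio).
#' @export
relative_trait <- function(trial, trait) {
  df <- trial[trial$trait == trait, , drop = FALSE]
  if (!nrow(df)) stop(sprintf("no records for trait '%s'", trait), call. = FALSE)
  s <- df[df$regime == "stress", c("accession", "replication", "value")]
  ns <- df[df$regime == "nonstress", c("accession", "replication", "value")]
  m <- merge(s, ns, by = c("accession", "replication"),
             suffixes = c("_stress", "_nonstress"), all = TRUE)
  miss <- is.na(m$value_stress) | is.na(m$value_nonstress)
  if (any(miss))
    stop(sprintf("missing regime pair for: %s",
                 paste(sprintf("%s/rep%s", m$accession[miss],
                               m$replication[miss])[seq_len(min(5, sum(miss)))],
                       collapse = ", ")), call. = FALSE)
  if (any(m$value_nonstress <= 0))
    stop("non-positive non-stress value; ratio undefined", call. = FALSE)
  data.frame(accession = m$accession, replication = m$replication,
             X = m$value_stress / m$value_nonstress,
             stringsAsFactors = FALSE)
}

#' Membership index of a relative trait
#'
#' Rescales the relative trait value `X_ik` of accession `i` in replication
#' `k` so that the sensitive-check mean maps to 0 and the tolerant-check
#' mean maps to 1, separately in each replication:
#' `M_ik = (X_ik - X_kS) / (X_kT - X_kS)`, where `X_kT` and `X_kS` are the
#' replication-`k` means of the tolerant and sensitive checks.  Larger `M`
#' means stronger tolerance; values outside `[0, 1]` indicate accessions
#' beyond the check range and are retained.  The accession-level indicator
#' (MPW or MPH, depending on the trait) is the mean of `M_ik` over
#' replications.
#'
#' @param X data.frame from [relative_trait()].
#' @param tolerant_ids,sensitive_ids accession ids of the checks.
#' @param min_replications minimum replications required per accession mean.
#' @return a `membership_result`: list with `M` (data.frame accession,
#'   replication, M), `check_means` (data.frame replication, X_kT, X_kS) and
#'   `accession_mean` (named numeric).
#' @export
membership_index <- function(X, tolerant_ids, sensitive_ids,
                             min_replications = 2L) {
  stopifnot(all(c("accession", "replication", "X") %in% names(X)))
  unknown <- setdiff(c(tolerant_ids, sensitive_ids), X$accession)
  if (length(unknown))
    stop(sprintf("unknown check id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (length(intersect(tolerant_ids, sensitive_ids)))
    stop("tolerant and sensitive check sets overlap", call. = FALSE)
  reps <- sort(unique(X$replication))
  XkT <- vapply(reps, function(k)
    mean(X$X[X$replication == k & X$accession %in% tolerant_ids]), numeric(1))
  XkS <- vapply(reps, function(k)
    mean(X$X[X$replication == k & X$accession %in% sensitive_ids]), numeric(1))
  degen <- which(abs(XkT - XkS) < 1e-12)
  if (length(degen))
    stop(sprintf("tolerant and sensitive check means coincide in replication %s",
                 paste(reps[degen], collapse = ", ")), call. = FALSE)
  idx <- match(X$replication, reps)
  M <- data.frame(accession = X$accession, replication = X$replication,
                  M = (X$X - XkS[idx]) / (XkT[idx] - XkS[idx]),
                  stringsAsFactors = FALSE)
  nrep <- tapply(M$M, M$accession, function(v) sum(!is.na(v)))
  means <- tapply(M$M, M$accession, mean, na.rm = TRUE)
  means[nrep < min_replications] <- NA_real_
  structure(list(M = M,
                 check_means = data.frame(replication = reps,
                                          X_kT = XkT, X_kS = XkS),
                 accession_mean = means[order(names(means))]),
            class = "membership_result")
}

#' Broad-sense heritability from a one-way random-effects ANOVA
#'
#' Fits the one-way model `M_ik = mu + g_i + e_ik` (accessions random) by
#' method of moments on the ANOVA mean squares: `sigma2_g = max(0,
#' (MS_accession - MS_error) / r)`, `sigma2_e = MS_error`, and the
#' mean-basis heritability `h2 = sigma2_g / (sigma2_g + sigma2_e / r)`,
#' with `r` the (harmonic mean, for near-balanced data) replication count.
#' Negative variance-component estimates are truncated at zero.
#'
#' @param M data.frame with columns `accession`, `M` (and anything else,
#'   ignored), one row per accession x replication; or a
#'   `membership_result`.
#' @return a `heritability_estimate`: list with `sigma2_g`, `sigma2_e`, `r`,
#'   `h2` (clamped to `[0, 1]`).
#' @export
anova_heritability <- function(M) {
  if (inherits(M, "membership_result")) M <- M$M
  stopifnot(all(c("accession", "M") %in% names(M)))
  M <- M[!is.na(M$M), , drop = FALSE]
  counts <- table(M$accession)
  if (length(counts) < 2) stop("need >= 2 accessions", call. = FALSE)
  if (any(counts < 2)) stop("need >= 2 replications per accession", call. = FALSE)
  fit <- aov(M ~ factor(accession), data = M)
  tab <- suppressWarnings(anova(fit))   # perfect fits warn but are legitimate
  ms_acc <- tab$`Mean Sq`[1]
  ms_err <- tab$`Mean Sq`[2]
  r <- length(counts) / sum(1 / counts)  # harmonic mean, = r when balanced
  sigma2_g <- max(0, (ms_acc - ms_err) / r)
  sigma2_e <- ms_err
  h2 <- if (sigma2_g + sigma2_e / r <= 0) 0 else
    sigma2_g / (sigma2_g + sigma2_e / r)
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, r = r,
                 h2 = min(max(h2, 0), 1)),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.3f (sigma2_g = %.4g, sigma2_e = %.4g, r = %.2f)\n",
              x$h2, x$sigma2_g, x$sigma2_e, x$r))
  invisible(x)
}

#' Summaries, correlation and extreme accessions for the two indicators
#'
#' @param mpw,mph named numeric vectors of accession-level indicator values
#'   (means of the membership index over replications), sharing names.
#' @param subpop optional named character vector of subpopulation labels.
#' @param n_extreme how many top (tolerant) and bottom (sensitive)
#'   accessions to list, ranked by the mean of the two indicators.
#' @return list with `summary` (per population/subpopulation: n, mean, min,
#'   max, range per indicator), `correlation` (estimate, p.value),
#'   `top` and `bottom` accession ids.
#' @export
summarize_indicators <- function(mpw, mph, subpop = NULL, n_extreme = 12L) {
  shared <- intersect(names(mpw), names(mph))
  if (!length(shared)) stop("indicator accession sets are disjoint", call. = FALSE)
  mpw <- mpw[shared]; mph <- mph[shared]
  groups <- list(ALL = shared)
  if (!is.null(subpop))
    groups <- c(groups, split(shared, subpop[shared]))
  one <- function(v, ids, ind, grp) {
    x <- v[ids]
    data.frame(indicator = ind, population = grp, n = length(x),
               mean = mean(x, na.rm = TRUE), min = min(x, na.rm = TRUE),
               max = max(x, na.rm = TRUE),
               range = diff(range(x, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, c(
    lapply(names(groups), function(g) one(mpw, groups[[g]], "MPW", g)),
    lapply(names(groups), function(g) one(mph, groups[[g]], "MPH", g))))
  ct <- suppressWarnings(cor.test(mpw, mph))
  comb <- (mpw + mph) / 2
  ord <- order(comb, decreasing = TRUE)
  list(summary = summ,
       correlation = list(estimate = unname(ct$estimate),
                          p.value = ct$p.value),
       top = shared[ord[seq_len(min(n_extreme, length(ord)))]],
       bottom = shared[rev(ord)[seq_len(min(n_extreme, length(ord)))]])
}
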