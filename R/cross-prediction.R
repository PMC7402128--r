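#' Enumerate all unordered biparental crosses of a panel
#'
#' @param accessions character vector of accession ids (>= 2).
#' @return data.frame with columns `parent1`, `parent2`; `n(n-1)/2` rows.
#' @export
enumerate_crosses <- function(accessions) {
  if (length(accessions) < 2)
    stop("need at least 2 accessions to enumerate crosses", call. = FALSE)
  idx <- combn(length(accessions), 2L)
  data.frame(parent1 = accessions[idx[1, ]], parent2 = accessions[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Simulate derived-line progenies of one biparental cross
#'
#' Progenies are modeled as fully homozygous derived lines: at each locus of
#' the union of the trait matrices' loci, a progeny inherits parent 1's or
#' parent 2's allele with probability 1/2, independently across loci (free
#' recombination).  A locus shared between traits is sampled once per
#' progeny, so the two trait values of a progeny are consistent.  The
#' progeny value for a trait is that trait's model intercept plus the sum
#' of the inherited allele effects over the trait's loci.
#'
#' @param parent1,parent2 accession ids.
#' @param matrices named list of `qtl_allele_matrix` objects, one per trait.
#' @param n number of progenies.
#' @param seed optional seed for reproducible samples.
#' @return a `progeny_sample`: list with `values` (n x traits matrix),
#'   `parents`, `parent_values` (trait x parent predicted values), `n`.
#' @export
simulate_progeny <- function(parent1, parent2, matrices, n = 10000L,
                             seed = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  if (!is.null(seed)) set.seed(seed)
  for (tr in names(matrices)) {
    acc <- rownames(matrices[[tr]]$alleles)
    missing <- setdiff(c(parent1, parent2), acc)
    if (length(missing))
      stop(sprintf("parent %s missing from the %s matrix",
                   paste(missing, collapse = ", "), tr), call. = FALSE)
  }
  all_loci <- unique(unlist(lapply(matrices, function(m) colnames(m$alleles))))
  L <- length(all_loci)
  # one inheritance draw per progeny x locus, shared across traits
  inherit1 <- matrix(stats::runif(n * L) < 0.5, n, L,
                     dimnames = list(NULL, all_loci))
  values <- matrix(NA_real_, n, length(matrices),
                   dimnames = list(NULL, names(matrices)))
  parent_values <- matrix(NA_real_, length(matrices), 2,
                          dimnames = list(names(matrices),
                                          c(parent1, parent2)))
  for (tr in names(matrices)) {
    m <- matrices[[tr]]
    loci <- colnames(m$effects)
    e1 <- m$effects[parent1, loci]
    e2 <- m$effects[parent2, loci]
    sel <- inherit1[, loci, drop = FALSE]
    values[, tr] <- m$intercept +
      as.numeric(sel %*% e1 + (!sel) %*% e2)
    parent_values[tr, ] <- c(m$predicted[parent1], m$predicted[parent2])
  }
  structure(list(values = values, parents = c(parent1, parent2),
                 parent_values = parent_values, n = n),
            class = "progeny_sample")
}

#' Percentile of a progeny sample (linear interpolation between ranks)
#'
#' Uses the linear-interpolation quantile definition (R type 7), pinned
#' here because percentile conventions differ between tools.
#'
#' @param sample numeric vector, or a `progeny_sample` (then per trait).
#' @param q percentile in `[0, 100]`.
#' @return numeric value (or named vector per trait).
#' @export
percentile_summary <- function(sample, q = 95) {
  if (inherits(sample, "progeny_sample"))
    return(apply(sample$values, 2, percentile_summary, q = q))
  if (!length(sample)) stop("empty sample", call. = FALSE)
  quantile(sample, q / 100, type = 7, names = FALSE)
}

#' Heritability-weighted average value over the two indicators
#'
#' `WAV = (w1 * v1 + w2 * v2) / (w1 + w2)` with the trait heritabilities as
#' weights; only the weight ratio matters, so weights may be given on the
#' proportion (0.813) or percentage (81.3) scale.
#'
#' @param value_mpw,value_mph the two indicator values.
#' @param h2_mpw,h2_mph heritability weights.
#' @return the weighted average (unrounded; round to 3 decimals for
#'   display).
#' @export
weighted_average_value <- function(value_mpw, value_mph,
                                   h2_mpw = 0.813, h2_mph = 0.760) {
  if (!all(is.finite(c(value_mpw, value_mph, h2_mpw, h2_mph))))
    stop("weighted_average_value needs finite inputs", call. = FALSE)
  if (h2_mpw <= 0 || h2_mph <= 0) stop("weights must be positive", call. = FALSE)
  (h2_mpw * value_mpw + h2_mph * value_mph) / (h2_mpw + h2_mph)
}

#' Predict and rank optimal crosses by progeny percentile simulation
#'
#' For every cross, simulates `n_progeny` derived lines, takes the `q`-th
#' percentile per trait, and flags the cross optimal when the percentiles
#' of both traits simultaneously (if `joint`) exceed the threshold of the
#' chosen criterion: the maximum observed accession value in the population
#' (`"exceeds_population_max"`) or the cross's own highest parental value
#' (`"exceeds_parental_max"`).  Crosses are ranked by the
#' heritability-weighted average of their trait percentiles.
#'
#' @param crosses data.frame from [enumerate_crosses()] (or any subset).
#' @param matrices named list of `qtl_allele_matrix` per trait (expected
#'   names `plant_weight`-like first trait then second).
#' @param observed named list of numeric vectors of observed accession
#'   values per trait (used for the population-max criterion; defaults to
#'   the matrices' predicted values).
#' @param n_progeny progenies per cross.
#' @param q percentile.
#' @param criterion optimality criterion.
#' @param joint require both traits simultaneously.
#' @param h2 numeric vector of heritability weights per trait (same order
#'   as `matrices`).
#' @param seed integer; per-cross seeds are derived deterministically.
#' @return a `cross_ranking`: data.frame with parents, per-trait parental
#'   predicted values, per-trait `q`-th percentiles, `wav`, `optimal`,
#'   ordered by decreasing `wav`; attributes record the criterion and
#'   thresholds.
#' @export
rank_optimal <- function(crosses, matrices, observed = NULL,
                         n_progeny = 10000L, q = 95,
                         criterion = c("exceeds_population_max",
                                       "exceeds_parental_max"),
                         joint = TRUE, h2 = c(0.813, 0.760), seed = 1L) {
  criterion <- match.arg(criterion)
  traits <- names(matrices)
  stopifnot(length(h2) == length(traits))
  if (is.null(observed))
    observed <- lapply(matrices, function(m) m$predicted)
  pop_max <- vapply(observed, max, numeric(1))

  nc <- nrow(crosses)
  pct <- matrix(NA_real_, nc, length(traits), dimnames = list(NULL, traits))
  pv1 <- pv2 <- matrix(NA_real_, nc, length(traits),
                       dimnames = list(NULL, traits))
  for (i in seq_len(nc)) {
    ps <- simulate_progeny(crosses$parent1[i], crosses$parent2[i], matrices,
                           n = n_progeny,
                           seed = (seed + i * 7919) %% 2147483647)
    pct[i, ] <- percentile_summary(ps, q)
    pv1[i, ] <- ps$parent_values[, 1]
    pv2[i, ] <- ps$parent_values[, 2]
  }
  thresh <- switch(criterion,
                   exceeds_population_max =
                     matrix(pop_max, nc, length(traits), byrow = TRUE),
                   exceeds_parental_max = pmax(pv1, pv2))
  exceed <- pct > thresh
  optimal <- if (joint) rowSums(exceed) == length(traits) else
    rowSums(exceed) > 0
  wav <- as.numeric(pct %*% h2 / sum(h2))
  out <- data.frame(crosses, stringsAsFactors = FALSE)
  for (tr in traits) {
    out[[paste0(tr, "_p1")]] <- pv1[, tr]
    out[[paste0(tr, "_p2")]] <- pv2[, tr]
    out[[paste0(tr, "_pct")]] <- pct[, tr]
  }
  out$wav <- wav
  out$optimal <- optimal
  ord <- order(-out$wav, out$parent1, out$parent2)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "criterion") <- criterion
  attr(out, "joint") <- joint
  attr(out, "q") <- q
  attr(out, "population_max") <- pop_max
  class(out) <- c("cross_ranking", "data.frame")
  out
}
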