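#' Genetic similarity matrix on multi-allele markers
#'
#' Similarity between two accessions is the fraction of markers at which
#' they carry the identical allele code (simple matching over multi-allele
#' markers); the diagonal is exactly 1.  Computed as a sparse one-hot
#' crossproduct, so it scales to thousands of markers.
#'
#' @param markers a `marker_set`.
#' @return symmetric numeric matrix (accession x accession) with entries in
#'   `[0, 1]`.
#' @export
genetic_similarity <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  calls <- markers$calls
  if (!ncol(calls)) stop("empty marker set", call. = FALSE)
  n <- nrow(calls); m <- ncol(calls)
  offsets <- c(0L, cumsum(apply(calls, 2, max)))[seq_len(m)]
  j <- as.integer(sweep(calls, 2, offsets, `+`))
  Z <- Matrix::sparseMatrix(i = rep(seq_len(n), times = m), j = j, x = 1)
  S <- as.matrix(Matrix::tcrossprod(Z)) / m
  dimnames(S) <- list(rownames(calls), rownames(calls))
  S
}

#' Top eigenvectors of the genetic similarity matrix
#'
#' Symmetric eigendecomposition; the top `k` eigenvectors (by eigenvalue)
#' serve as fixed population-structure covariates in the association scan.
#' Each vector's sign is fixed so its largest-magnitude entry is positive,
#' making the basis reproducible.
#'
#' @param sim similarity matrix from [genetic_similarity()].
#' @param k number of eigenvectors (default 10; capped at `n - 1` with a
#'   warning for small panels).
#' @return list with `vectors` (n x k matrix) and `values` (decreasing
#'   eigenvalues).
#' @export
top_eigenvectors <- function(sim, k = 10L) {
  n <- nrow(sim)
  if (k > n) stop(sprintf("k = %d exceeds the panel size %d", k, n),
                  call. = FALSE)
  if (k > n - 1L) {
    warning(sprintf("k reduced to n - 1 = %d for a panel of %d accessions",
                    n - 1L, n))
    k <- n - 1L
  }
  e <- eigen(sim, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- rownames(sim)
  colnames(vec) <- sprintf("EV%d", seq_len(k))
  list(vectors = vec, values = e$values[seq_len(k)])
}
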