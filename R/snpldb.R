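snp_maf <- function(calls_row) {
  hom <- calls_row[calls_row %in% c(0L, 1L)]
  if (!length(hom)) return(0)
  f <- mean(hom == 1L)
  min(f, 1 - f)
}

#' SNP quality control
#'
#' Removes SNPs whose combined missing + heterozygous call rate exceeds
#' `max_missing_het` or whose minor allele frequency (computed on homozygous
#' calls) is below `min_maf`; remaining heterozygous calls are then
#' converted to missing, since in a selfing panel residual hets are treated
#' as call errors.
#'
#' @param geno a [genotype_matrix].
#' @param max_missing_het maximum tolerated missing+het fraction per SNP.
#' @param min_maf minimum minor allele frequency per SNP.
#' @return list with `geno` (filtered [genotype_matrix]) and `report`
#'   (counts: n_input, n_removed_missing_het, n_removed_maf, n_kept,
#'   n_het_set_missing).
#' @export
qc_filter_snps <- function(geno, max_missing_het = 0.30, min_maf = 0.01) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!nrow(geno$calls)) stop("empty genotype matrix", call. = FALSE)
  n <- ncol(geno$calls)
  mh_rate <- rowMeans(is.na(geno$calls) | geno$calls == 2L)
  maf <- apply(geno$calls, 1, snp_maf)
  drop_mh <- mh_rate > max_missing_het
  drop_maf <- !drop_mh & maf < min_maf
  keep <- !(drop_mh | drop_maf)
  if (!any(keep))
    warning("all SNPs removed by QC; downstream steps will see an empty matrix")
  calls <- geno$calls[keep, , drop = FALSE]
  n_het <- sum(calls == 2L, na.rm = TRUE)
  calls[calls == 2L] <- NA_integer_
  out <- genotype_matrix(calls, geno$snps[keep, , drop = FALSE], geno$accessions)
  list(geno = out,
       report = list(n_input = nrow(geno$calls),
                     n_removed_missing_het = sum(drop_mh),
                     n_removed_maf = sum(drop_maf),
                     n_kept = sum(keep),
                     n_het_set_missing = n_het))
}

#' Deterministic major-allele imputation
#'
#' Replaces every missing call by the SNP's major allele (ties go to the
#' reference allele).  Deterministic; the imputed fraction is returned.
#'
#' @param geno a post-QC [genotype_matrix] (no heterozygous calls).
#' @return list with `geno` (complete matrix) and `imputed_fraction`.
#' @export
impute_missing <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  calls <- geno$calls
  if (any(calls == 2L, na.rm = TRUE))
    stop("heterozygous calls present; run qc_filter_snps first", call. = FALSE)
  n_miss <- sum(is.na(calls))
  if (n_miss) {
    all_missing <- rowSums(!is.na(calls)) == 0L
    if (any(all_missing))
      stop(sprintf("SNP %s has no observed calls; cannot impute",
                   geno$snps$id[which(all_missing)[1]]), call. = FALSE)
    major <- ifelse(rowMeans(calls == 1L, na.rm = TRUE) > 0.5, 1L, 0L)
    idx <- which(is.na(calls), arr.ind = TRUE)
    calls[idx] <- major[idx[, 1]]
  }
  list(geno = genotype_matrix(calls, geno$snps, geno$accessions),
       imputed_fraction = n_miss / length(calls))
}

#' D-prime and its likelihood-grid confidence interval for one SNP pair
#'
#' Treats each inbred accession's homozygous calls as one haplotype, builds
#' the 2x2 haplotype count table, and computes the normalized LD coefficient
#' `D' = |D| / Dmax`.  The confidence bounds on `|D'|` come from the
#' multinomial likelihood of the count table evaluated on a grid of
#' `D'` values in `[0, 1]` (marginal allele frequencies fixed at their
#' estimates): the bounds are the grid points where the cumulative
#' normalized likelihood reaches the lower and upper tail probabilities
#' (5th and 95th percentiles for `confidence = 0.95`).
#'
#' @param snp_a,snp_b integer call vectors (codes 0/1, NA allowed).
#' @param confidence confidence level for the interval.
#' @param grid_step grid resolution on `D'`.
#' @return list with `dprime`, `ci_low`, `ci_high`, `n_informative`.
#' @export
dprime_ci <- function(snp_a, snp_b, confidence = 0.95, grid_step = 0.005) {
  ok <- snp_a %in% c(0L, 1L) & snp_b %in% c(0L, 1L)
  a <- snp_a[ok]; b <- snp_b[ok]
  n <- length(a)
  if (!n || length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("dprime_ci requires two polymorphic SNPs with overlapping calls",
         call. = FALSE)
  n11 <- sum(a == 0L & b == 0L); n12 <- sum(a == 0L & b == 1L)
  n21 <- sum(a == 1L & b == 0L); n22 <- sum(a == 1L & b == 1L)
  pA <- (n11 + n12) / n; pB <- (n11 + n21) / n
  D <- n11 / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax <= 0) 0 else abs(D) / dmax
  dprime <- min(dprime, 1)

  grid <- seq(0, 1, by = grid_step)
  sgn <- if (D >= 0) 1 else -1
  eps <- 1e-12
  loglik <- vapply(grid, function(d) {
    p11 <- pA * pB + sgn * d * dmax
    p12 <- pA - p11; p21 <- pB - p11; p22 <- 1 - pA - pB + p11
    p <- pmax(c(p11, p12, p21, p22), eps)
    sum(c(n11, n12, n21, n22) * log(p))
  }, numeric(1))
  lik <- exp(loglik - max(loglik))
  cum <- cumsum(lik) / sum(lik)
  lo_tail <- 1 - confidence             # one-sided 5% / 95% bounds
  ci_low <- grid[which(cum >= lo_tail)[1]]
  ci_high <- grid[which(cum >= 1 - lo_tail)[1]]
  list(dprime = dprime, ci_low = ci_low, ci_high = ci_high, n_informative = n)
}

# classify one pair: 1 strong LD, 2 strong recombination, 3 uninformative
classify_pair <- function(snp_a, snp_b, strong_ld_low, strong_ld_high,
                          recomb_high) {
  st <- tryCatch(dprime_ci(snp_a, snp_b), error = function(e) NULL)
  if (is.null(st)) return(3L)
  if (st$ci_low > strong_ld_low && st$ci_high >= strong_ld_high) return(1L)
  if (st$ci_high < recomb_high) return(2L)
  3L
}

#' Detect LD blocks with the confidence-interval pair-classification rule
#'
#' For every SNP pair closer than `max_dist`, the `|D'|` confidence interval
#' classifies the pair as strong LD (`ci_low > strong_ld_low` and
#' `ci_high >= strong_ld_high`), strong recombination
#' (`ci_high < recomb_high`) or uninformative.  Candidate intervals are SNP
#' ranges whose outermost pair is strong LD; they are accepted greedily from
#' the longest genomic span to the shortest, without overlap, whenever the
#' fraction of strong-LD pairs among informative pairs inside the interval
#' is at least `frac_strong`.  SNPs below `min_maf` never enter a block.
#'
#' @param geno an imputed, complete [genotype_matrix].
#' @param max_dist maximum pairing distance in bp.
#' @param min_maf minimum minor allele frequency for a SNP to be paired.
#' @param strong_ld_low,strong_ld_high CI bounds defining strong LD.
#' @param recomb_high CI upper bound defining strong recombination.
#' @param frac_strong required strong-LD fraction among informative pairs.
#' @return data.frame of blocks: `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   plus a list-column `snp_rows` of global SNP row indices.
#' @export
find_ld_blocks <- function(geno, max_dist = 200000, min_maf = 0.01,
                           strong_ld_low = 0.70, strong_ld_high = 0.98,
                           recomb_high = 0.90, frac_strong = 0.95) {
  stopifnot(inherits(geno, "genotype_matrix"))
  maf <- apply(geno$calls, 1, snp_maf)
  res <- list()
  for (ch in unique(geno$snps$chrom)) {
    rows <- which(geno$snps$chrom == ch & maf >= min_maf)
    m <- length(rows)
    if (m < 2) next
    pos <- geno$snps$pos[rows]
    cls <- matrix(0L, m, m)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (pos[j] - pos[i] > max_dist) break
        cls[i, j] <- classify_pair(geno$calls[rows[i], ], geno$calls[rows[j], ],
                                   strong_ld_low, strong_ld_high, recomb_high)
      }
    }
    cand <- which(cls == 1L, arr.ind = TRUE)
    cand <- cand[cand[, 2] > cand[, 1], , drop = FALSE]
    if (!nrow(cand)) next
    span <- pos[cand[, 2]] - pos[cand[, 1]]
    ord <- order(-span, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    used <- logical(m)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (any(used[i:j])) next
      sub <- cls[i:j, i:j]
      n_sl <- sum(sub == 1L); n_sr <- sum(sub == 2L)
      if (n_sl + n_sr == 0) next
      if (n_sl / (n_sl + n_sr) >= frac_strong) {
        used[i:j] <- TRUE
        res[[length(res) + 1L]] <-
          data.frame(chrom = ch, start_bp = pos[i], end_bp = pos[j],
                     n_snps = j - i + 1L, stringsAsFactors = FALSE,
                     snp_rows = I(list(rows[i:j])))
      }
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      snp_rows = I(list())))
  out <- do.call(rbind, res)
  out[order(match(out$chrom, unique(geno$snps$chrom)), out$start_bp), ,
      drop = FALSE]
}

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# merge haplotypes rarer than `floor` into the most similar frequent one
merge_rare_haplotypes <- function(hapstrings, floor) {
  freq <- table(hapstrings) / length(hapstrings)
  frequent <- names(freq)[freq >= floor]
  if (!length(frequent)) frequent <- names(freq)[which.max(freq)]
  remap <- setNames(names(freq), names(freq))
  for (h in setdiff(names(freq), frequent)) {
    d <- vapply(frequent, hamming_str, numeric(1), a = h)
    best <- frequent[d == min(d)]
    if (length(best) > 1) {                       # ties: higher-frequency target
      f <- freq[best]
      best <- best[f == max(f)]
      best <- sort(best)[1]                       # then lexicographic
    }
    remap[h] <- best
  }
  remap[hapstrings]
}

#' Assemble multi-allele SNPLDB markers from LD blocks
#'
#' SNPs inside each detected block are collapsed into one multi-allele
#' marker whose alleles are the observed haplotype strings; haplotypes
#' rarer than `rare_allele_floor` are merged into the most similar frequent
#' haplotype (Hamming distance; ties resolved toward the higher-frequency
#' target, then lexicographically).  Every polymorphic SNP outside a block
#' becomes a two-allele single-SNP marker.  Multi-SNP markers are named
#' `<chrom>_BLOCK<k>` with `k` the rank of the block on its chromosome;
#' single-SNP markers are named `<chrom>_<pos>`.
#'
#' @param geno an imputed, complete [genotype_matrix].
#' @param blocks block table from [find_ld_blocks()].
#' @param rare_allele_floor frequency below which haplotypes are merged.
#' @return a `marker_set`: list with `info` (id, chrom, start_bp, end_bp,
#'   n_snps, n_alleles, type), `alleles` (list of allele strings, ordered by
#'   descending frequency), `freqs` (list of allele frequencies),
#'   `snp_rows` (list of member SNP row indices) and `calls`
#'   (accession x marker integer allele codes).
#' @export
build_snpldb_markers <- function(geno, blocks, rare_allele_floor = 0.01) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (any(is.na(geno$calls)) || any(geno$calls == 2L))
    stop("marker assembly needs a complete homozygous matrix; impute first",
         call. = FALSE)
  n_acc <- ncol(geno$calls)
  in_block <- unlist(blocks$snp_rows)
  if (length(in_block) && any(!in_block %in% seq_len(nrow(geno$calls))))
    stop("block references SNP rows outside the genotype matrix", call. = FALSE)

  entries <- list()
  # multi-SNP markers, numbering blocks per chromosome in genomic order
  if (nrow(blocks)) {
    blocks <- blocks[order(match(blocks$chrom, unique(geno$snps$chrom)),
                           blocks$start_bp), , drop = FALSE]
    per_chrom <- ave(seq_len(nrow(blocks)), blocks$chrom, FUN = seq_along)
    for (b in seq_len(nrow(blocks))) {
      rows <- blocks$snp_rows[[b]]
      haps <- apply(geno$calls[rows, , drop = FALSE], 2, paste, collapse = "")
      haps <- merge_rare_haplotypes(haps, rare_allele_floor)
      freq <- sort(table(haps) / n_acc, decreasing = TRUE)
      if (length(freq) < 2) next                    # monomorphic after merge
      codes <- match(haps, names(freq))
      entries[[length(entries) + 1L]] <- list(
        id = sprintf("%s_BLOCK%d", blocks$chrom[b], per_chrom[b]),
        chrom = blocks$chrom[b], start_bp = blocks$start_bp[b],
        end_bp = blocks$end_bp[b], n_snps = length(rows),
        type = "block", alleles = names(freq), freqs = as.numeric(freq),
        snp_rows = rows, codes = codes)
    }
  }
  # singleton markers
  single_rows <- setdiff(seq_len(nrow(geno$calls)), in_block)
  for (rw in single_rows) {
    v <- geno$calls[rw, ]
    if (length(unique(v)) < 2) next
    freq <- sort(table(as.character(v)) / n_acc, decreasing = TRUE)
    codes <- match(as.character(v), names(freq))
    entries[[length(entries) + 1L]] <- list(
      id = sprintf("%s_%d", geno$snps$chrom[rw], geno$snps$pos[rw]),
      chrom = geno$snps$chrom[rw], start_bp = geno$snps$pos[rw],
      end_bp = geno$snps$pos[rw], n_snps = 1L, type = "snp",
      alleles = names(freq), freqs = as.numeric(freq),
      snp_rows = rw, codes = codes)
  }
  if (!length(entries)) stop("no polymorphic markers could be assembled",
                             call. = FALSE)
  info <- data.frame(
    id = vapply(entries, `[[`, character(1), "id"),
    chrom = vapply(entries, `[[`, character(1), "chrom"),
    start_bp = vapply(entries, function(e) as.integer(e$start_bp), integer(1)),
    end_bp = vapply(entries, function(e) as.integer(e$end_bp), integer(1)),
    n_snps = vapply(entries, `[[`, integer(1), "n_snps"),
    n_alleles = vapply(entries, function(e) length(e$alleles), integer(1)),
    type = vapply(entries, `[[`, character(1), "type"),
    stringsAsFactors = FALSE)
  ord <- order(match(info$chrom, unique(geno$snps$chrom)), info$start_bp)
  entries <- entries[ord]; info <- info[ord, , drop = FALSE]
  rownames(info) <- NULL
  calls <- vapply(entries, `[[`, integer(n_acc), "codes")
  dimnames(calls) <- list(geno$accessions, info$id)
  structure(list(info = info,
                 alleles = setNames(lapply(entries, `[[`, "alleles"), info$id),
                 freqs = setNames(lapply(entries, `[[`, "freqs"), info$id),
                 snp_rows = setNames(lapply(entries, `[[`, "snp_rows"), info$id),
                 calls = calls,
                 accessions = geno$accessions),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers (%d blocks, %d single SNPs), %d accessions\n",
              nrow(x$info), sum(x$info$type == "block"),
              sum(x$info$type == "snp"), length(x$accessions)))
  cat(sprintf("  alleles per marker: %d-%d\n",
              min(x$info$n_alleles), max(x$info$n_alleles)))
  invisible(x)
}

#' Write marker definitions and the accession x marker allele matrix
#'
#' @param markers a `marker_set`.
#' @param def_path path for the marker definition TSV.
#' @param calls_path path for the accession x marker allele-code TSV.
#' @param header_lines optional comment lines.
#' @return invisibly, the two paths.
#' @export
write_marker_set <- function(markers, def_path, calls_path,
                             header_lines = character()) {
  def <- markers$info
  def$alleles <- vapply(markers$alleles[def$id], paste, character(1),
                        collapse = ",")
  def$allele_freqs <- vapply(markers$freqs[def$id], function(f)
    paste(sprintf("%.4f", f), collapse = ","), character(1))
  write_tsv_atomic(def, def_path, header_lines)
  calls <- data.frame(accession = markers$accessions,
                      as.data.frame(markers$calls), check.names = FALSE)
  write_tsv_atomic(calls, calls_path, header_lines)
  invisible(c(def_path, calls_path))
}
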