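test_that("QC removes high-missing-het and low-MAF SNPs and logs counts", {
  set.seed(8)
  n <- 100
  good <- matrix(rbinom(5 * n, 1, 0.4), 5, n)       # clean polymorphic
  noisy <- matrix(rbinom(n, 1, 0.4), 1, n)          # 35% missing+het
  bad_idx <- sample(n, 35)
  noisy[1, bad_idx[1:20]] <- NA
  noisy[1, bad_idx[21:35]] <- 2L
  rare <- matrix(0L, 1, n); rare[1, 1] <- 1L        # MAF 1% < default? equals
  rare0 <- matrix(0L, 1, n)                         # monomorphic, MAF 0
  g <- toy_geno(rbind(good, noisy, rare, rare0))
  qc <- qc_filter_snps(g, max_missing_het = 0.30, min_maf = 0.02)
  expect_equal(qc$report$n_removed_missing_het, 1)
  expect_equal(qc$report$n_removed_maf, 2)
  expect_equal(qc$report$n_kept, 5)
  expect_false(any(qc$geno$calls == 2L, na.rm = TRUE))
})

test_that("het calls are converted to missing after filtering", {
  g <- toy_geno(matrix(c(0, 1, 2, 0, 1, 0, 1, 0, 1, 1), 2, 5, byrow = TRUE))
  qc <- qc_filter_snps(g, max_missing_het = 0.5, min_maf = 0.01)
  expect_true(is.na(qc$geno$calls[1, 3]))
  expect_equal(qc$report$n_het_set_missing, 1)
})

test_that("imputation fills the major allele deterministically", {
  g <- toy_geno(matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1), 1, 10))
  expect_identical(impute_missing(g)$geno$calls, g$calls)  # nothing missing
  calls <- g$calls; calls[1, 2] <- NA
  g2 <- genotype_matrix(calls, g$snps, g$accessions)
  imp <- impute_missing(g2)
  expect_equal(imp$geno$calls[1, 2], 0L)                  # 90% ref -> ref
  expect_equal(imp$imputed_fraction, 0.1)
  calls[1, ] <- NA
  expect_error(impute_missing(genotype_matrix(calls, g$snps, g$accessions)),
               "no observed calls")
})

test_that("imputation accuracy equals the major-allele baseline", {
  study <- small_study(seed = 19, n = 120, n_chrom = 1, snps = 30, n_qtl = 2)
  truth <- study$panel$geno
  noisy <- inject_call_noise(truth, missing_rate = 0.05, seed = 20)
  holdout <- which(is.na(noisy$calls))
  imp <- impute_missing(noisy)
  acc <- mean(imp$geno$calls[holdout] == truth$calls[holdout])
  major <- ifelse(rowMeans(noisy$calls == 1L, na.rm = TRUE) > 0.5, 1L, 0L)
  baseline <- mean(major[arrayInd(holdout, dim(truth$calls))[, 1]] ==
                     truth$calls[holdout])
  expect_gte(acc, baseline - 1e-9)
})

test_that("D-prime matches hand computation and the independence case", {
  # perfect LD: identical columns over 100 haplotypes
  a <- rep(c(0L, 1L), each = 50)
  st <- dprime_ci(a, a)
  expect_equal(st$dprime, 1)
  expect_gte(st$ci_high, 0.98)
  expect_gt(st$ci_low, 0.9)
  expect_equal(st$n_informative, 100)
  # independence: counts 25/25/25/25
  b <- rep(c(0L, 1L, 0L, 1L), each = 25)
  a2 <- rep(c(0L, 0L, 1L, 1L), each = 25)
  expect_equal(dprime_ci(a2, b)$dprime, 0)
  expect_error(dprime_ci(rep(0L, 10), rep(c(0L, 1L), 5)), "polymorphic")
})

test_that("D-prime CI agrees with a brute-force fine-grid likelihood oracle", {
  # counts {AB:40, Ab:10, aB:10, ab:40}: D = 0.4 - 0.25 = 0.15, Dmax = 0.25
  a <- rep(c(0L, 0L, 1L, 1L), times = c(40, 10, 10, 40))
  b <- rep(c(0L, 1L, 0L, 1L), times = c(40, 10, 10, 40))
  st <- dprime_ci(a, b)
  expect_equal(st$dprime, 0.6, tolerance = 1e-12)
  # oracle: same definition on a 10x finer grid
  grid <- seq(0, 1, by = 5e-4)
  loglik <- vapply(grid, function(d) {
    p11 <- 0.25 + d * 0.25
    p <- pmax(c(p11, 0.5 - p11, 0.5 - p11, p11), 1e-12)
    sum(c(40, 10, 10, 40) * log(p))
  }, numeric(1))
  lik <- exp(loglik - max(loglik))
  cum <- cumsum(lik) / sum(lik)
  expect_lt(abs(st$ci_low - grid[which(cum >= 0.05)[1]]), 0.01)
  expect_lt(abs(st$ci_high - grid[which(cum >= 0.95)[1]]), 0.01)
})

test_that("the distance rule vetoes far-apart pairs", {
  set.seed(30)
  col <- rbinom(200, 1, 0.5)
  calls <- rbind(col, col)                       # perfect LD
  snps <- data.frame(chrom = "Chr01", pos = c(1L, 300001L), ref = "A",
                     alt = "T", stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, snps, sprintf("A%03d", 1:200))
  expect_equal(nrow(find_ld_blocks(g, max_dist = 200000)), 0)
  # same pair within range is a block
  snps2 <- snps; snps2$pos <- c(1L, 150001L)
  g2 <- genotype_matrix(calls, snps2, sprintf("A%03d", 1:200))
  expect_equal(nrow(find_ld_blocks(g2, max_dist = 200000)), 1)
})

test_that("a shared-haplotype block is detected as one block", {
  set.seed(31)
  pool <- matrix(c(0, 0, 0, 0, 0,
                   1, 1, 0, 1, 1,
                   1, 0, 1, 0, 1), 3, 5, byrow = TRUE)
  hap <- sample(1:3, 200, replace = TRUE, prob = c(0.4, 0.35, 0.25))
  calls <- t(pool[hap, ])
  snps <- data.frame(chrom = "Chr01", pos = as.integer(seq(1, 50001, length.out = 5)),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, snps, sprintf("A%03d", 1:200))
  blocks <- find_ld_blocks(g)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_snps, 5)
  expect_equal(blocks$start_bp, 1)
  expect_equal(blocks$end_bp, 50001)
})

test_that("independent SNPs almost never form blocks", {
  found <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    calls <- matrix(rbinom(10 * 150, 1, 0.5), 10, 150)
    g <- toy_geno(calls, spacing = 5000L)
    nrow(find_ld_blocks(g))
  }, numeric(1))
  expect_gte(mean(found == 0), 0.95)
})

test_that("block detection is invariant to accession order and allele labels", {
  study <- small_study(seed = 23, n = 120, n_chrom = 1, snps = 20, n_qtl = 2,
                       haplotypes_per_block = 3, dirichlet_conc = c(5, 5))
  g <- study$panel$geno
  b0 <- find_ld_blocks(g)
  # permute accessions
  perm <- sample(ncol(g$calls))
  gp <- genotype_matrix(g$calls[, perm], g$snps, g$accessions[perm])
  bp <- find_ld_blocks(gp)
  expect_equal(bp[c("chrom", "start_bp", "end_bp", "n_snps")],
               b0[c("chrom", "start_bp", "end_bp", "n_snps")])
  # flip ref/alt at a few SNPs
  gf <- g; flip <- c(1, 4, 7)
  gf$calls[flip, ] <- 1L - gf$calls[flip, ]
  gf <- genotype_matrix(gf$calls, g$snps, g$accessions)
  bf <- find_ld_blocks(gf)
  expect_equal(bf[c("chrom", "start_bp", "end_bp", "n_snps")],
               b0[c("chrom", "start_bp", "end_bp", "n_snps")])
})

test_that("exact block recovery on noiseless balanced panels", {
  for (s in 1:3) {
    cfg <- sim_config(n_accessions = 250, n_chromosomes = 2,
                      snps_per_chromosome = 40, haplotypes_per_block = 3,
                      dirichlet_conc = c(5, 5), n_qtl = 2, seed = 1100 + s)
    p <- simulate_founder_genotypes(cfg)
    maf <- apply(p$geno$calls, 1, function(v) min(mean(v == 1), mean(v == 0)))
    det <- find_ld_blocks(p$geno)
    truth_sets <- lapply(seq_len(nrow(p$truth$blocks)), function(b) {
      tb <- p$truth$blocks[b, ]
      rows <- which(p$geno$snps$chrom == tb$chrom &
                    p$geno$snps$pos >= tb$start_bp &
                    p$geno$snps$pos <= tb$end_bp)
      rows[maf[rows] >= 0.01]
    })
    truth_sets <- Filter(function(r) length(r) >= 2, truth_sets)
    expect_length(det$snp_rows, length(truth_sets))
    expect_true(all(mapply(identical, lapply(det$snp_rows, as.integer),
                           lapply(truth_sets, as.integer))))
  }
})

test_that("marker assembly enumerates haplotype alleles and merges rare ones", {
  # 3 haplotypes at >= 5% each -> 3 alleles
  pool <- matrix(c(0, 0, 0, 1, 1, 0, 1, 0, 1), 3, 3, byrow = TRUE)
  hap <- rep(1:3, times = c(100, 60, 40))
  g <- toy_geno(t(pool[hap, ]), spacing = 1000L)
  blocks <- data.frame(chrom = "Chr01", start_bp = 1000L, end_bp = 3000L,
                       n_snps = 3L, snp_rows = I(list(1:3)))
  mk <- build_snpldb_markers(g, blocks)
  expect_equal(mk$info$n_alleles, 3)
  expect_equal(mk$info$id, "Chr01_BLOCK1")
  expect_equal(sum(mk$freqs[[1]]), 1, tolerance = 1e-12)
  # a 0.5% haplotype one mismatch away from a 60% haplotype merges into it
  hap2 <- c(rep(1, 119), rep(2, 80), 3)
  pool2 <- matrix(c(1, 1, 0,
                    0, 0, 0,
                    1, 1, 1), 3, 3, byrow = TRUE)  # hap3 near hap1
  g2 <- toy_geno(t(pool2[hap2, ]), spacing = 1000L)
  mk2 <- build_snpldb_markers(g2, blocks)
  expect_equal(mk2$info$n_alleles, 2)
  expect_equal(sort(round(mk2$freqs[[1]], 3)), c(0.4, 0.6))
  expect_true("110" %in% mk2$alleles[[1]])
})

test_that("markers recover the constructed allele counts", {
  hits <- total <- 0
  for (k in 2:6) {
    cfg <- sim_config(n_accessions = 300, n_chromosomes = 1,
                      snps_per_chromosome = 40, haplotypes_per_block = k,
                      dirichlet_conc = c(8, 8), n_qtl = 2, seed = 1200 + k)
    p <- simulate_founder_genotypes(cfg)
    # true blocks as given, no detection noise
    tb <- p$truth$blocks
    rows_of <- lapply(seq_len(nrow(tb)), function(b)
      which(p$geno$snps$chrom == tb$chrom[b] &
            p$geno$snps$pos >= tb$start_bp[b] &
            p$geno$snps$pos <= tb$end_bp[b]))
    blocks <- data.frame(chrom = tb$chrom, start_bp = tb$start_bp,
                         end_bp = tb$end_bp, n_snps = tb$n_snps,
                         snp_rows = I(rows_of))
    mk <- build_snpldb_markers(p$geno, blocks)
    realized <- apply(p$truth$hap_assign, 1, function(h) length(unique(h)))
    blk <- mk$info[mk$info$type == "block", ]
    idx <- match(blk$start_bp, tb$start_bp)
    hits <- hits + sum(blk$n_alleles == realized[idx])
    total <- total + nrow(blk)
  }
  expect_gte(hits / total, 0.95)
})

test_that("every accession has exactly one allele per marker", {
  study <- small_study(seed = 29, n = 100, n_chrom = 2, snps = 25, n_qtl = 2)
  qc <- qc_filter_snps(study$panel$geno)
  imp <- impute_missing(qc$geno)
  mk <- build_snpldb_markers(imp$geno, find_ld_blocks(imp$geno))
  expect_false(any(is.na(mk$calls)))
  for (id in mk$info$id) {
    expect_true(all(mk$calls[, id] %in% seq_along(mk$alleles[[id]])))
    expect_equal(sum(mk$freqs[[id]]), 1, tolerance = 1e-9)
  }
  # naming conventions
  expect_true(all(grepl("^Chr\\d+_(BLOCK\\d+|\\d+)$", mk$info$id)))
})
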