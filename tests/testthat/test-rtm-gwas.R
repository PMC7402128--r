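test_that("stage-one F statistic equals a direct linear-model oracle", {
  set.seed(70)
  n <- 30
  codes <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  calls <- cbind(M1 = codes)
  rownames(calls) <- sprintf("a%02d", 1:n)
  mk <- toy_marker_set(calls)
  cov <- matrix(rnorm(2 * n), n, 2,
                dimnames = list(rownames(calls), c("EV1", "EV2")))
  y <- setNames(as.numeric(0.5 * (codes == 1) + cov %*% c(0.3, -0.2) +
                             rnorm(n, 0, 0.5)), rownames(calls))
  s1 <- stage1_scan(mk, y, cov, alpha = 0.05)
  fit <- lm(y ~ cov + factor(codes))
  oracle <- anova(fit)["factor(codes)", ]          # marker fitted last
  expect_equal(s1$scan$F, oracle$`F value`, tolerance = 1e-8)
  expect_equal(s1$scan$p, oracle$`Pr(>F)`, tolerance = 1e-8)
})

test_that("a marker that generates the phenotype has the smallest p", {
  set.seed(71)
  n <- 80
  calls <- matrix(sample(1:2, n * 10, replace = TRUE), n, 10)
  calls[, 4] <- sample(1:3, n, replace = TRUE)
  rownames(calls) <- sprintf("a%02d", 1:n)
  mk <- toy_marker_set(calls)
  y <- setNames(c(-0.5, 0.1, 0.9)[calls[, 4]], rownames(calls))
  s1 <- stage1_scan(mk, y, NULL)
  expect_equal(which.min(s1$scan$p), 4L)
})

test_that("stage-one preselection rate is near alpha under the null", {
  set.seed(72)
  n <- 200
  calls <- matrix(sample(1:2, n * 1000, replace = TRUE), n, 1000)
  rownames(calls) <- sprintf("a%03d", 1:n)
  mk <- toy_marker_set(calls)
  y <- setNames(rnorm(n), rownames(calls))
  s1 <- stage1_scan(mk, y, NULL, alpha = 0.05)
  rate <- mean(s1$scan$preselected[!s1$scan$skipped])
  band <- 2.58 * sqrt(0.05 * 0.95 / sum(!s1$scan$skipped))
  expect_lt(abs(rate - 0.05), band + 1e-12)
})

test_that("rank-deficient covariates are refused", {
  set.seed(73)
  n <- 40
  calls <- matrix(sample(1:2, n * 3, replace = TRUE), n, 3)
  rownames(calls) <- sprintf("a%02d", 1:n)
  mk <- toy_marker_set(calls)
  cov <- cbind(a = rnorm(n), b = 0)
  rownames(cov) <- rownames(calls)
  cov[, 2] <- 2 * cov[, 1]
  y <- setNames(rnorm(n), rownames(calls))
  expect_error(stage1_scan(mk, y, cov), "rank deficient")
})

test_that("a zero heritability cap selects no loci", {
  set.seed(74)
  n <- 60
  calls <- matrix(sample(1:2, n * 5, replace = TRUE), n, 5)
  dimnames(calls) <- list(sprintf("a%02d", 1:n), sprintf("M%d", 1:5))
  mk <- toy_marker_set(calls)
  y <- setNames(c(-1, 1)[calls[, 1]] + rnorm(n, 0, 0.3), rownames(calls))
  m <- stage2_stepwise(mk, y, NULL, h2_cap = 0, candidates = colnames(calls))
  expect_equal(nrow(m$loci), 0)
  expect_equal(m$total_r2, 0)
  expect_equal(m$unmapped_share, 0)
})

test_that("stepwise matches exhaustive best-subset search on small instances", {
  for (s in 1:3) {
    set.seed(80 + s)
    n <- 120
    calls <- matrix(sample(1:2, n * 6, replace = TRUE), n, 6)
    calls[, 2] <- sample(1:3, n, replace = TRUE)
    dimnames(calls) <- list(sprintf("a%03d", 1:n), sprintf("M%d", 1:6))
    mk <- toy_marker_set(calls)
    y <- setNames(c(-1, 1)[calls[, 1]] + c(-0.8, 0, 0.8)[calls[, 2]] +
                    rnorm(n, 0, 0.4), rownames(calls))
    m <- stage2_stepwise(mk, y, NULL, h2_cap = 1,
                         candidates = colnames(calls))
    # exhaustive oracle over all pairs: minimize RSS of the two-locus model
    pairs <- combn(colnames(calls), 2)
    rss <- apply(pairs, 2, function(pr) {
      X <- model.matrix(~ factor(calls[, pr[1]]) + factor(calls[, pr[2]]))
      sum(lm.fit(X, y)$residuals^2)
    })
    best <- sort(pairs[, which.min(rss)])
    expect_identical(sort(m$loci$id[1:2]), best)
  }
})

test_that("biallelic effects are symmetric and balanced designs close-form", {
  # biallelic: effects are (e, -e)
  set.seed(90)
  n <- 50
  calls <- cbind(M1 = sample(1:2, n, replace = TRUE))
  rownames(calls) <- sprintf("a%02d", 1:n)
  mk <- toy_marker_set(calls)
  y <- setNames(rnorm(n) + 0.8 * (calls[, 1] == 1), rownames(calls))
  e <- estimate_allele_effects(mk, y, "M1")
  expect_equal(sum(e), 0, tolerance = 1e-10)
  expect_equal(e[[1]], -e[[2]], tolerance = 1e-10)
  # balanced 3-allele design with hand-set group means
  codes <- rep(1:3, each = 12)
  calls3 <- cbind(M1 = codes)
  rownames(calls3) <- sprintf("b%02d", seq_along(codes))
  mk3 <- toy_marker_set(calls3)
  mu <- c(2, 5, 11)
  y3 <- setNames(mu[codes], rownames(calls3))
  e3 <- estimate_allele_effects(mk3, y3, "M1")
  expect_equal(unname(e3), mu - mean(mu), tolerance = 1e-10)
  # identical group means in an orthogonal design -> all zero
  y0 <- setNames(rep(1, length(codes)), rownames(calls3))
  expect_equal(unname(estimate_allele_effects(mk3, y0, "M1")), rep(0, 3),
               tolerance = 1e-10)
})

test_that("locus contribution equals eta-squared for a single locus", {
  set.seed(91)
  n <- 90
  codes <- sample(1:3, n, replace = TRUE)
  calls <- cbind(M1 = codes, M2 = sample(1:2, n, replace = TRUE))
  rownames(calls) <- sprintf("a%02d", 1:n)
  mk <- toy_marker_set(calls)
  y <- setNames(c(-1, 0, 1)[codes] + rnorm(n, 0, 0.6), rownames(calls))
  m <- stage2_stepwise(mk, y, NULL, h2_cap = 1, candidates = "M1")
  aovt <- anova(aov(y ~ factor(codes)))
  eta2 <- aovt$`Sum Sq`[1] / sum(aovt$`Sum Sq`)
  expect_equal(m$loci$r2, eta2, tolerance = 1e-10)
  expect_equal(m$total_r2, eta2, tolerance = 1e-10)
  lc <- locus_contribution(m)
  expect_equal(lc$unmapped_share, 1 - eta2, tolerance = 1e-10)
  # orthogonal two-locus design: partial R2 sums to total R2
  codes_a <- rep(1:2, each = 40); codes_b <- rep(rep(1:2, each = 20), 2)
  calls2 <- cbind(A = codes_a, B = codes_b)
  rownames(calls2) <- sprintf("c%02d", 1:80)
  mk2 <- toy_marker_set(calls2)
  y2 <- setNames(0.9 * codes_a - 0.7 * codes_b + rnorm(80, 0, 0.3),
                 rownames(calls2))
  m2 <- stage2_stepwise(mk2, y2, NULL, h2_cap = 1, candidates = c("A", "B"))
  expect_equal(sum(m2$loci$r2), m2$total_r2, tolerance = 1e-10)
})

test_that("the total contribution never exceeds the cap", {
  set.seed(92)
  n <- 100
  calls <- matrix(sample(1:2, n * 8, replace = TRUE), n, 8)
  dimnames(calls) <- list(sprintf("a%03d", 1:n), sprintf("M%d", 1:8))
  mk <- toy_marker_set(calls)
  y <- setNames(c(-1, 1)[calls[, 1]] + c(-1, 1)[calls[, 2]] +
                  0.5 * c(-1, 1)[calls[, 3]] + rnorm(n, 0, 0.5),
                rownames(calls))
  for (cap in c(0.2, 0.4, 0.6)) {
    m <- stage2_stepwise(mk, y, NULL, h2_cap = cap,
                         candidates = colnames(calls))
    expect_lte(m$total_r2, cap + 1e-9)
  }
})

test_that("statistics are invariant to accession permutation", {
  set.seed(93)
  study <- small_study(seed = 41, n = 100, n_chrom = 1, snps = 25, n_qtl = 3)
  mem <- indicator_means(study)
  imp <- impute_missing(qc_filter_snps(study$panel$geno)$geno)
  mk <- build_snpldb_markers(imp$geno, find_ld_blocks(imp$geno))
  S <- genetic_similarity(mk)
  eig <- top_eigenvectors(S, 4)
  y <- mem$accession_mean
  s1a <- stage1_scan(mk, y, eig)
  s1b <- stage1_scan(mk, y[sample(length(y))], eig)
  expect_lt(max(abs(s1a$scan$F - s1b$scan$F), na.rm = TRUE), 1e-10)
})

test_that("true QTL and their allele effects are recovered on synthetic panels", {
  top_recovered <- effect_cor <- numeric(0)
  for (s in 1:5) {
    cfg <- sim_config(n_accessions = 400, n_chromosomes = 4,
                      snps_per_chromosome = 60, n_qtl = 20, effect_sd = 0.15,
                      seed = 1300 + s)
    study <- simulate_panel_study(cfg)
    mem <- indicator_means(study)
    h2 <- anova_heritability(mem)$h2
    imp <- impute_missing(qc_filter_snps(study$panel$geno)$geno)
    mk <- build_snpldb_markers(imp$geno, find_ld_blocks(imp$geno))
    eig <- top_eigenvectors(genetic_similarity(mk), 10)
    s1 <- stage1_scan(mk, mem$accession_mean, eig)
    mod <- stage2_stepwise(mk, mem$accession_mean, eig, h2_cap = h2,
                           candidates = s1$preselected)
    truth <- study$models$plant_weight
    tb <- study$panel$truth$blocks
    # rank true QTL by realized genotypic variance
    gvar <- vapply(truth$qtl_blocks, function(b) {
      var(truth$allele_effects[[as.character(b)]][
        study$panel$truth$hap_assign[b, ]])
    }, numeric(1))
    top10 <- truth$qtl_blocks[order(gvar, decreasing = TRUE)][1:10]
    sel <- mk$info[mk$info$id %in% mod$loci$id, ]
    hit <- vapply(top10, function(b) {
      any(sel$chrom == tb$chrom[b] &
            sel$start_bp <= tb$end_bp[b] + 260000 &
            sel$end_bp >= tb$start_bp[b] - 260000)
    }, logical(1))
    top_recovered <- c(top_recovered, mean(hit))
    # effect recovery at exactly identified loci
    est <- tr <- numeric(0)
    for (b in truth$qtl_blocks) {
      id <- mk$info$id[mk$info$chrom == tb$chrom[b] &
                         mk$info$start_bp == tb$start_bp[b] &
                         mk$info$type == "block"]
      if (length(id) != 1 || !(id %in% mod$loci$id)) next
      hap_strings <- apply(study$panel$truth$pools[[b]], 1, paste,
                           collapse = "")
      e_hat <- mod$allele_effects[[id]]
      keep <- names(e_hat) %in% hap_strings
      est <- c(est, e_hat[keep])
      e_true <- truth$allele_effects[[as.character(b)]]
      tr <- c(tr, e_true[match(names(e_hat)[keep], hap_strings)])
    }
    effect_cor <- c(effect_cor, if (length(est) > 3) cor(est, tr) else NA)
  }
  expect_gte(mean(top_recovered), 0.8)
  expect_gt(mean(effect_cor, na.rm = TRUE), 0.8)
})
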