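#' Configuration for the synthetic germplasm panel generator
#'
#' Bundles every knob of the synthetic-population module.  The defaults
#' emulate the study design the pipeline targets: a 564-accession inbred
#' soybean panel split into a landrace-like and a released-cultivar-like
#' subpopulation, genotyped at SNPs organized in LD blocks carrying 2--12
#' haplotype alleles, phenotyped in a replicated two-regime (stress /
#' non-stress) trial with five replications and five tolerant plus five
#' sensitive check accessions, with a membership-index heritability around
#' 0.8.
#'
#' @param n_accessions number of inbred accessions.
#' @param n_subpops number of subpopulations.
#' @param subpop_proportions fractions per subpopulation, summing to 1.
#' @param n_chromosomes number of chromosomes.
#' @param snps_per_chromosome SNPs simulated per chromosome.
#' @param snps_per_block SNPs per LD block (generator granularity; the last
#'   block on a chromosome absorbs any remainder).
#' @param block_length_bp genomic span of one LD block in bp.  Blocks are
#'   separated by gaps larger than the default 200 kb pairing distance so
#'   true block boundaries are identifiable.
#' @param haplotypes_per_block number of distinct haplotypes in each block's
#'   founder pool (capped at `2^snps_per_block`).  The realistic range is
#'   2--12; the value 1 is accepted only to build degenerate monomorphic
#'   panels for testing.
#' @param dirichlet_conc Dirichlet concentration per subpopulation used to
#'   draw block haplotype frequencies; unequal values produce drifted allele
#'   frequencies between subpopulations.
#' @param n_qtl number of causal blocks.
#' @param effect_sd standard deviation of per-allele QTL effects before
#'   centering (trait-ratio scale).
#' @param target_h2 mean-basis broad-sense heritability targeted for the
#'   membership index, in (0, 1].
#' @param n_replications replications of the two-regime trial.
#' @param n_checks_tolerant,n_checks_sensitive numbers of tolerant and
#'   sensitive check accessions.
#' @param seed integer seed controlling the whole generation.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_accessions = 564,
                       n_subpops = 2,
                       subpop_proportions = c(0.57, 0.43),
                       n_chromosomes = 20,
                       snps_per_chromosome = 150,
                       snps_per_block = 5,
                       block_length_bp = 50000,
                       haplotypes_per_block = 4,
                       dirichlet_conc = c(0.5, 2.0),
                       n_qtl = 15,
                       effect_sd = 0.1,
                       target_h2 = 0.8,
                       n_replications = 5,
                       n_checks_tolerant = 5,
                       n_checks_sensitive = 5,
                       seed = 1L) {
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_subpops = as.integer(n_subpops),
              subpop_proportions = as.numeric(subpop_proportions),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              snps_per_block = as.integer(snps_per_block),
              block_length_bp = as.integer(block_length_bp),
              haplotypes_per_block = as.integer(haplotypes_per_block),
              dirichlet_conc = as.numeric(dirichlet_conc),
              n_qtl = as.integer(n_qtl),
              effect_sd = as.numeric(effect_sd),
              target_h2 = as.numeric(target_h2),
              n_replications = as.integer(n_replications),
              n_checks_tolerant = as.integer(n_checks_tolerant),
              n_checks_sensitive = as.integer(n_checks_sensitive),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why), call. = FALSE)
  }
  if (cfg$n_accessions < 2) bad("n_accessions", "need at least 2 accessions")
  if (cfg$n_subpops < 1) bad("n_subpops", "must be >= 1")
  if (length(cfg$subpop_proportions) != cfg$n_subpops)
    bad("subpop_proportions", "length must equal n_subpops")
  if (abs(sum(cfg$subpop_proportions) - 1) > 1e-9)
    bad("subpop_proportions", "must sum to 1")
  if (any(cfg$subpop_proportions <= 0)) bad("subpop_proportions", "must be positive")
  if (cfg$n_chromosomes < 1) bad("n_chromosomes", "must be >= 1")
  if (cfg$snps_per_chromosome < 1) bad("snps_per_chromosome", "must be >= 1")
  if (cfg$snps_per_block < 1) bad("snps_per_block", "must be >= 1")
  if (cfg$block_length_bp <= 0) bad("block_length_bp", "must be positive")
  if (cfg$haplotypes_per_block < 1) bad("haplotypes_per_block", "must be >= 1")
  if (length(cfg$dirichlet_conc) != cfg$n_subpops)
    bad("dirichlet_conc", "length must equal n_subpops")
  if (any(cfg$dirichlet_conc <= 0)) bad("dirichlet_conc", "must be positive")
  if (cfg$n_qtl < 0) bad("n_qtl", "must be >= 0")
  if (cfg$effect_sd <= 0) bad("effect_sd", "must be positive")
  if (!(cfg$target_h2 > 0 && cfg$target_h2 <= 1))
    bad("target_h2", "must lie in (0, 1]")
  if (cfg$n_replications < 1) bad("n_replications", "must be >= 1")
  if (cfg$n_checks_tolerant < 1) bad("n_checks_tolerant", "must be >= 1")
  if (cfg$n_checks_sensitive < 1) bad("n_checks_sensitive", "must be >= 1")
  invisible(cfg)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# distinct random haplotypes of s biallelic SNPs, encoded as 0/1 rows
draw_haplotype_pool <- function(n_hap, s) {
  n_hap <- min(n_hap, 2^s)
  codes <- sample.int(2^s, n_hap) - 1L
  pool <- matrix(0L, nrow = n_hap, ncol = s)
  for (j in seq_len(s)) {
    pool[, j] <- codes %% 2L
    codes <- codes %/% 2L
  }
  pool
}

#' Simulate founder genotypes of an inbred panel with LD-block structure
#'
#' Generates fully homozygous SNP genotypes for `n_accessions` inbred
#' accessions.  SNPs are organized in contiguous blocks; within each block
#' every accession carries one haplotype drawn from a per-block pool of
#' `haplotypes_per_block` distinct haplotypes, with pool frequencies drawn
#' independently per subpopulation from a Dirichlet distribution (so
#' subpopulations drift).  Blocks are separated by gaps larger than the
#' default 200 kb LD pairing distance, and draws are independent between
#' blocks.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; defaults to `config$seed`.
#' @return a `sim_panel`: list with `geno` (a [genotype_matrix]), `subpop`
#'   (character vector of labels `"LR"`/`"RC"`/... per accession), and
#'   `truth` with the block table, haplotype pools, subpopulation haplotype
#'   frequencies, and the block-by-accession haplotype assignment matrix.
#' @export
simulate_founder_genotypes <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_accessions
  acc_ids <- sprintf("ACC%04d", seq_len(n))
  pop_sizes <- diff(round(cumsum(c(0, config$subpop_proportions)) * n))
  pop_sizes[config$n_subpops] <- n - sum(pop_sizes[-config$n_subpops])
  pop_names <- if (config$n_subpops == 2) c("LR", "RC") else
    sprintf("POP%d", seq_len(config$n_subpops))
  subpop <- rep(pop_names, times = pop_sizes)

  gap_bp <- max(250000L, 2L * config$block_length_bp)
  blocks <- list(); snp_chrom <- list(); snp_pos <- list()
  geno_cols <- list(); pools <- list(); freqs <- list(); assign_rows <- list()
  bi <- 0L
  for (ch in seq_len(config$n_chromosomes)) {
    chrom <- sprintf("Chr%02d", ch)
    m <- config$snps_per_chromosome
    nb <- m %/% config$snps_per_block
    sizes <- rep(config$snps_per_block, nb)
    rem <- m - sum(sizes)
    if (rem > 0) sizes <- c(sizes, rem)
    start_bp <- 1L
    for (b in seq_along(sizes)) {
      s <- sizes[b]
      bi <- bi + 1L
      pos <- if (s == 1L) start_bp else
        start_bp + as.integer(round(seq(0, config$block_length_bp, length.out = s)))
      pool <- draw_haplotype_pool(config$haplotypes_per_block, s)
      f <- vapply(seq_len(config$n_subpops), function(j)
        rdirichlet1(rep(config$dirichlet_conc[j], nrow(pool))), numeric(nrow(pool)))
      f <- matrix(f, nrow = nrow(pool))
      hap_of <- integer(n)
      for (j in seq_len(config$n_subpops)) {
        idx <- which(subpop == pop_names[j])
        hap_of[idx] <- sample.int(nrow(pool), length(idx), replace = TRUE,
                                  prob = f[, j])
      }
      geno_cols[[bi]] <- t(pool[hap_of, , drop = FALSE])  # s x n
      blocks[[bi]] <- data.frame(block = bi, chrom = chrom, block_on_chrom = b,
                                 start_bp = pos[1], end_bp = pos[s],
                                 n_snps = s, n_haplotypes = nrow(pool))
      snp_chrom[[bi]] <- rep(chrom, s)
      snp_pos[[bi]] <- pos
      pools[[bi]] <- pool
      freqs[[bi]] <- f
      assign_rows[[bi]] <- hap_of
      start_bp <- pos[s] + gap_bp
    }
  }
  calls <- do.call(rbind, geno_cols)
  snps <- data.frame(chrom = unlist(snp_chrom), pos = unlist(snp_pos),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  snps$id <- paste0(snps$chrom, "_", snps$pos)
  geno <- genotype_matrix(calls, snps, acc_ids)
  truth_blocks <- do.call(rbind, blocks)
  structure(list(geno = geno,
                 subpop = setNames(subpop, acc_ids),
                 truth = list(blocks = truth_blocks,
                              pools = pools,
                              freqs = freqs,
                              hap_assign = do.call(rbind, assign_rows))),
            class = "sim_panel")
}

#' Inject missing and heterozygous call noise into a panel
#'
#' Uniformly replaces a fraction of calls by missing (`NA`) and another
#' fraction by heterozygous calls, to exercise the QC path.
#'
#' @param geno a [genotype_matrix].
#' @param missing_rate,het_rate fractions in `[0, 1)`.
#' @param seed optional seed.
#' @return a [genotype_matrix] with noise injected.
#' @export
inject_call_noise <- function(geno, missing_rate = 0, het_rate = 0, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  calls <- geno$calls
  ncell <- length(calls)
  u <- runif(ncell)
  calls[u < missing_rate] <- NA_integer_
  calls[u >= missing_rate & u < missing_rate + het_rate] <- 2L
  genotype_matrix(calls, geno$snps, geno$accessions)
}

#' Assign additive multi-allele QTL effects to a simulated panel
#'
#' Picks `n_qtl` distinct polymorphic blocks as causal loci and draws one
#' additive effect per pool haplotype from `N(0, effect_sd^2)`, then centers
#' effects to sum to zero within each locus.
#'
#' @param panel a `sim_panel` from [simulate_founder_genotypes()].
#' @param config the [sim_config()] used to build the panel.
#' @param intercept baseline of the genotypic value (stress/non-stress ratio
#'   scale).
#' @param subpop_shift additive offset per subpopulation (default all zero).
#' @param seed optional seed.
#' @return a `true_qtl_model`: list with `qtl_blocks` (block indices),
#'   `allele_effects` (per locus, named numeric vector over pool
#'   haplotypes), `intercept` and `subpop_shift`.
#' @export
assign_qtl_effects <- function(panel, config, intercept = 0.6,
                               subpop_shift = NULL, seed = NULL) {
  stopifnot(inherits(panel, "sim_panel"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(subpop_shift)) subpop_shift <- rep(0, config$n_subpops)
  n_blocks <- nrow(panel$truth$blocks)
  poly <- which(vapply(seq_len(n_blocks), function(b)
    length(unique(panel$truth$hap_assign[b, ])) >= 2L, logical(1)))
  if (length(poly) < config$n_qtl)
    stop(sprintf("cannot assign %d QTL: only %d polymorphic blocks in panel",
                 config$n_qtl, length(poly)), call. = FALSE)
  loci <- sort(sample(poly, config$n_qtl))
  eff <- lapply(loci, function(b) {
    k <- nrow(panel$truth$pools[[b]])
    e <- rnorm(k, sd = config$effect_sd)
    e <- e - mean(e)
    names(e) <- sprintf("hap%d", seq_len(k))
    e
  })
  names(eff) <- as.character(loci)
  structure(list(qtl_blocks = loci, allele_effects = eff,
                 intercept = intercept, subpop_shift = subpop_shift),
            class = "true_qtl_model")
}

#' True genotypic value of each accession under a simulated QTL model
#'
#' @param panel a `sim_panel`.
#' @param model a `true_qtl_model`.
#' @return named numeric vector: intercept + summed carried-allele effects +
#'   subpopulation shift, per accession.
#' @export
true_genotypic_value <- function(panel, model) {
  stopifnot(inherits(panel, "sim_panel"), inherits(model, "true_qtl_model"))
  n <- length(panel$subpop)
  g <- rep(model$intercept, n)
  for (b in model$qtl_blocks) {
    hap <- panel$truth$hap_assign[b, ]
    g <- g + model$allele_effects[[as.character(b)]][hap]
  }
  pops <- unique(panel$subpop)
  g <- g + model$subpop_shift[match(panel$subpop, pops)]
  setNames(as.numeric(g), names(panel$subpop))
}

#' Simulate a replicated two-regime (stress / non-stress) trial
#'
#' Produces tidy plot-level trait values for a split-plot-style trial with
#' `n_replications` replications and two water regimes.  Non-stress values
#' are a trait baseline times a replication effect times lognormal noise;
#' stress values are the non-stress value times a per-plot stress/non-stress
#' ratio that is a monotone (affine, standardized) map of the accession's
#' true genotypic value plus Gaussian noise.  The noise standard deviation
#' is calibrated from the mean-basis heritability identity
#' `sigma2_e = sigma2_g * r * (1 - h2) / h2` so that the membership index
#' computed downstream has heritability close to `target_h2`.  The
#' tolerant (sensitive) checks are the accessions with the highest (lowest)
#' combined genotypic value, so the tolerant-check mean exceeds the
#' sensitive-check mean in every replication with high probability.
#'
#' @param panel a `sim_panel`.
#' @param model a single `true_qtl_model` (used for both traits, with
#'   independent noise) or a named list
#'   `list(plant_weight = ..., plant_height = ...)`.
#' @param config the [sim_config()].
#' @param ratio_base,ratio_scale center and genotypic standard deviation of
#'   the stress/non-stress ratio after standardization.
#' @param seed optional seed.
#' @return a `sim_trial`: list with `trial` (data.frame: accession,
#'   replication, regime, trait, value), `checks` (data.frame: accession,
#'   role), and `truth` (per-trait ratio-scale genotypic values and the
#'   calibrated noise sd).
#' @export
simulate_drought_trial <- function(panel, model, config,
                                   ratio_base = 0.6, ratio_scale = 0.12,
                                   seed = NULL) {
  stopifnot(inherits(panel, "sim_panel"))
  if (!is.null(seed)) set.seed(seed)
  if (!(config$target_h2 > 0 && config$target_h2 <= 1))
    stop("target_h2 must lie in (0, 1]", call. = FALSE)
  models <- if (inherits(model, "true_qtl_model"))
    list(plant_weight = model, plant_height = model) else model
  stopifnot(all(c("plant_weight", "plant_height") %in% names(models)))

  acc <- names(panel$subpop)
  n <- length(acc)
  r <- config$n_replications
  h2 <- config$target_h2

  ratio_true <- lapply(models, function(mod) {
    g <- true_genotypic_value(panel, mod)
    s <- sd(g)
    if (s < 1e-12) rep(ratio_base, n) else
      ratio_base + ratio_scale * (g - mean(g)) / s
  })

  combined <- rowMeans(do.call(cbind, ratio_true))
  ord <- order(combined, decreasing = TRUE)
  tol <- acc[ord[seq_len(config$n_checks_tolerant)]]
  sen <- acc[rev(ord)[seq_len(config$n_checks_sensitive)]]
  checks <- data.frame(accession = c(tol, sen),
                       role = rep(c("tolerant_check", "sensitive_check"),
                                  c(length(tol), length(sen))),
                       stringsAsFactors = FALSE)

  # Per-trait plot noise, calibrated so the *membership index* heritability
  # lands on target_h2.  The membership transform rescales each replication
  # by the noisy check means, so beyond the closed form
  # sigma2_e = sigma2_g * r * (1 - h2) / h2 the one-way ANOVA error also
  # absorbs (i) the sensitive-check anchor noise (variance sigma2_e / n_S,
  # shared within a replication) and (ii) the scale noise of the
  # tolerant-sensitive spread interacting with each accession's distance
  # from the anchor.  Dividing by the factor c below corrects for both.
  sigma_e <- vapply(names(models), function(tr) {
    rt <- ratio_true[[tr]]
    if (h2 >= 1) return(0)
    sg2 <- var(rt)
    if (sg2 < 1e-16) return(0)
    B <- mean(rt[match(tol, acc)]) - mean(rt[match(sen, acc)])
    d <- mean(rt) - mean(rt[match(sen, acc)])
    nT <- config$n_checks_tolerant; nS <- config$n_checks_sensitive
    c_anchor <- 1 + 1 / nS + ((sg2 + d^2) / B^2) * (1 / nT + 1 / nS)
    sqrt(sg2 * r * (1 - h2) / h2 / c_anchor)
  }, numeric(1))

  baselines <- c(plant_weight = 100, plant_height = 80)
  out <- vector("list", 2L * r * length(models))
  i <- 0L
  for (trait in names(models)) {
    for (k in seq_len(r)) {
      rep_eff <- rlnorm(1, 0, 0.05)
      nonstress <- baselines[[trait]] * rep_eff * rlnorm(n, 0, 0.10)
      ratio <- pmax(ratio_true[[trait]] + rnorm(n, 0, sigma_e[[trait]]), 0.01)
      stress <- nonstress * ratio
      i <- i + 1L
      out[[i]] <- data.frame(accession = acc, replication = k,
                             regime = "nonstress", trait = trait,
                             value = nonstress, stringsAsFactors = FALSE)
      i <- i + 1L
      out[[i]] <- data.frame(accession = acc, replication = k,
                             regime = "stress", trait = trait,
                             value = stress, stringsAsFactors = FALSE)
    }
  }
  structure(list(trial = do.call(rbind, out),
                 checks = checks,
                 truth = list(ratio_true = ratio_true, sigma_e = sigma_e)),
            class = "sim_trial")
}

#' Generate a complete synthetic study (panel, two QTL models, trial)
#'
#' Convenience wrapper: founder genotypes, one true QTL model per trait
#' (plant weight and plant height, drawn independently so the two indicator
#' genetic systems differ), and the replicated two-regime trial.
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `models` (named list of `true_qtl_model`),
#'   `trial` (a `sim_trial`), and the `config`.
#' @export
simulate_panel_study <- function(config = sim_config()) {
  panel <- simulate_founder_genotypes(config)   # seeds the stream
  models <- list(plant_weight = assign_qtl_effects(panel, config),
                 plant_height = assign_qtl_effects(panel, config))
  trial <- simulate_drought_trial(panel, models, config)
  list(panel = panel, models = models, trial = trial, config = config)
}
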