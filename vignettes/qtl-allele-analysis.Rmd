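---
title: "Membership-index phenotyping, SNPLDB markers and QTL-allele analysis"
author: "qtlallele"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membership-index phenotyping, SNPLDB markers and QTL-allele analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlallele)
```

This vignette is the package's own account of the models it implements,
the assumptions behind them, the parameters that matter, and the design
choices made where the methodology left them open.

## The analysis in one paragraph

An inbred germplasm panel — say a few hundred soybean accessions spanning
landraces and released cultivars — is phenotyped for a stress-tolerance
trait in a replicated two-regime trial and genotyped at genome-wide SNPs.
The package converts plot values into a *membership index* anchored at
tolerant and sensitive checks, collapses SNPs in strong linkage
disequilibrium into *multi-allele haplotype-block markers* (SNPLDBs),
scans those markers with a *restricted two-stage* association procedure
whose total genetic contribution is capped at the trait heritability,
organizes the detected QTL-alleles into an accession × locus matrix, and
uses that matrix to test subpopulation differentiation and to predict
which biparental crosses could yield transgressive progeny.

## Membership-index phenotyping

For one trait, the relative value under stress is `X_ik =
stress/non-stress` within accession *i* and replication *k*; pairing
within (accession, replication) is the only pairing under which the ratio
is well defined per replication in a split-plot layout. The membership
index

$$M_{ik} = \frac{X_{ik} - \bar X_{kS}}{\bar X_{kT} - \bar X_{kS}}$$

anchors the sensitive-check mean at 0 and the tolerant-check mean at 1,
separately per replication — an affine per-replication normalization, so
`M` is exactly invariant to shifting or rescaling all `X` values of a
replication. Values outside [0, 1] are legitimate (accessions beyond the
check range) and are retained. The accession-level indicator is the
unweighted mean of `M_ik` over replications (at least two required); the
alternative convention — computing `M` on replication-averaged `X` — is
not used, and this choice is deliberate: it keeps the per-replication
anchoring exact and lets the ANOVA below see replication-level residuals.

Heritability is estimated from the one-way random-effects ANOVA on
`M_ik` with accessions as the factor: `σ²_g = max(0, (MS_acc − MS_err)/r)`,
`σ²_e = MS_err`, and mean-basis `h² = σ²_g/(σ²_g + σ²_e/r)`. A one-way
model rather than the full split-plot decomposition is used because the
estimate is consumed downstream only as a cap and a weight; negative
method-of-moments components are truncated at zero, and for near-balanced
data `r` is the harmonic-mean replication count.

## SNPLDB marker assembly

Quality control removes SNPs with a combined missing + heterozygous call
rate above 0.30 or a minor allele frequency below 0.01, then converts
residual heterozygous calls to missing — in a selfing species, residual
hets at this rate are treated as call errors. Missing calls are imputed
deterministically to the SNP's major allele. This plain imputer replaces
model-based haplotype imputation by design: at the missingness rates the
QC admits, major-allele imputation is transparent, deterministic, and
exactly reproducible, and the imputation accuracy equals the major-allele
frequency by construction (a property the tests verify).

Because the panel is inbred, each accession's homozygous genotype *is* a
haplotype. For a SNP pair, the 2×2 haplotype count table gives
`D′ = |D|/D_max`; the confidence interval of |D′| is computed from the
multinomial likelihood of the table on a grid over D′ ∈ [0, 1] with
marginal frequencies fixed at their estimates, the bounds being the grid
points where the cumulative normalized likelihood passes 5 % and 95 %.
Pairs are classified as *strong LD* (CI low > 0.70 and CI high ≥ 0.98),
*strong recombination* (CI high < 0.90) or uninformative; candidate
intervals whose outermost pair is strong LD are accepted greedily from
longest genomic span to shortest, without overlap, whenever strong-LD
pairs make up at least 95 % of the informative pairs inside — with a hard
200 kb cap on pairing distance and a 0.01 MAF floor. These are the
standard Haploview-style defaults with the distance and MAF settings the
study design calls for; all thresholds are exposed as arguments.

Two numerical notes. First, the CI is a likelihood-grid variant (grid
step 0.005); published tools differ in the exact CI recipe, so the
package validates its CI only against a finer-grid oracle of the same
definition. For perfectly correlated SNP pairs at a few hundred
haplotypes the lower bound sits near 0.94 — comfortably above the 0.70
rule — rather than at 1, which is the honest width of the likelihood at
that sample size. Second, within a block that carries four or more
haplotypes, a SNP pair can exhibit all four gametes, making D′ genuinely
below 1; the fraction rule tolerates some such pairs, but block splits on
rich blocks are correct behavior of the CI method, not a defect. Exact
block recovery is therefore guaranteed (and tested) on blocks with at
most three haplotypes and balanced frequencies.

Each accepted block becomes one marker whose alleles are the observed
haplotype strings; haplotypes rarer than 1 % are merged into the most
similar frequent haplotype by Hamming distance (ties resolved toward the
higher-frequency target, then lexicographically) — merging to the nearest
haplotype keeps alleles interpretable, unlike an "other" bucket. SNPs
outside blocks are carried as two-allele markers. Multi-SNP markers are
named `<chrom>_BLOCK<k>` by their rank on the chromosome; single-SNP
markers are `<chrom>_<pos>` (1-based, VCF convention).

## Population structure and the two-stage scan

Genetic similarity between accessions is the fraction of SNPLDB markers
at which they carry the identical allele — a simple-matching coefficient
over multi-allele markers, unweighted by allele frequency (the weighting
hook exists as an argument surface but the plain coefficient is the
default and the tested path). The top `k = 10` eigenvectors of this
matrix (sign-fixed so each vector's largest-magnitude entry is positive)
enter both stages as fixed covariates; one shared basis serves both
traits. For small panels `k` is capped at `n − 1` with a warning.

Stage one fits, per marker, `phenotype ~ covariates + marker` with the
marker as a categorical term and tests it by a partial F test against the
covariate-only model; markers at p ≤ 0.05 are pre-selected. The
phenotype is the accession mean of the membership index — fitting
replication-level data instead is a defensible alternative, but means
keep the model honest to what the indicator is. Markers with any allele
carried by fewer than 3 accessions are skipped to guard singular fits
(upstream rare-allele merging makes this rare).

Stage two is forward–backward stepwise selection: at each step the
candidate with the smallest partial-F p-value enters if p ≤ 0.01 *and*
the model's total genetic contribution (R² of the selected loci beyond
the covariates) stays within the heritability cap; after each entry, any
included locus whose partial p rises above 0.01 is eliminated. Ties in
candidate p-values break by larger contribution, then by genomic order,
so selection is deterministic. The entry/staying level of 0.01 is
consistent with the smallest per-locus significances such scans report
(−log10 p ≈ 2.2); the originally described experiment-wise significance
partitioning is not reproducible from the available description, so a
fixed per-step α under the h² cap is the implemented surrogate — both are
arguments. The cap is enforced as a hard assertion: the total R² never
exceeds `h2_cap` and the remainder `h2_cap − R²` is reported as the
unmapped minor-QTL share.

Allele effects use sum-contrast coding, so each locus's effects sum to
zero unweighted, and each effect is the allele group's adjusted deviation
from the unweighted mean of the allele means. Per-locus contribution is
partial (Type-III-style) R² — the locus's sum of squares given all other
selected loci and covariates over the total phenotypic sum of squares —
because per-QTL contributions should not depend on selection order.

## QTL-allele matrix, differentiation and turnover

The matrix stores, per accession and selected locus, the carried allele
and its effect; the accession's predicted indicator value is the model
intercept plus its row sum (covariates are centered before fitting, so
the intercept already sits at the covariate mean, and the row-sum
identity against fitted values is tested to 1e-8). Subpopulation
differentiation is a per-locus Pearson χ² on the alleles × subpopulation
counts without continuity correction, reported at raw p ≤ 0.05 — no
multiple-testing correction is applied to match the headline convention,
but a Benjamini–Hochberg column is emitted alongside; loci with expected
cells below 5 are flagged, not dropped. Allele turnover between an
ancestral and a derived subpopulation lists alleles with nonzero
frequency in one and zero in the other, split by effect sign; an exactly
zero effect counts as neutral rather than being forced into a sign class.

## Cross prediction

Progenies of a biparental cross are modeled as fully homozygous derived
lines: at each locus of the union of the trait matrices' loci the progeny
inherits either parent's allele with probability ½, independently across
loci (free recombination — no linkage map exists at the QTL-allele matrix
level, and this is a documented limitation), and a locus shared between
traits is sampled once per progeny so the two trait values stay
consistent. The progeny value is the trait intercept plus the inherited
effects, putting progeny on the indicator scale so they can be compared
with observed phenotypic maxima; no residual polygenic noise is added,
so progeny distributions reflect the mapped loci only. Percentiles use
linear interpolation between closest ranks (R quantile type 7), pinned
because percentile conventions differ across tools. Both optimality
criteria are implemented — 95th percentiles exceeding the population
maximum, or exceeding the cross's own best parent, on both indicators
simultaneously — with the population-maximum form as the default, and the
report records which was used. Crosses are ranked by the weighted
average value `WAV = (h²_MPW·v_MPW + h²_MPH·v_MPH)/(h²_MPW + h²_MPH)`.

The pipeline ranks crosses among the top parents by predicted weighted
value (default 25, i.e. 300 crosses); exhaustive enumeration of all
`n(n−1)/2` crosses is a one-liner with `enumerate_crosses()` +
`rank_optimal()` for users who want the full table.

## The synthetic-population generator

The generator is first-class code, not a fixture: it emulates the data
structure the analysis assumes so that every stage is testable against
ground truth. Its defaults mirror the motivating study design: 564
accessions in two subpopulations (landrace-like 57 %, cultivar-like
43 %), five replications, five tolerant and five sensitive checks, and a
target membership-index heritability of 0.8 (the study's two indicators
sat at 0.81 and 0.76). Panels are fully homozygous — in a selfing
species a genotype is a haplotype — with SNPs in contiguous blocks drawn
from per-block pools of 2–12 haplotypes; subpopulation frequencies are
independent Dirichlet draws (concentrations 0.5 and 2.0 by default,
giving detectable drift), blocks are separated by gaps larger than the
200 kb pairing distance, and heterozygosity or missingness enter only via
an explicit noise injector for QC tests. Block sizes and haplotype
counts are configuration, not constants, because no genome-wide
distribution for them is prescribed.

QTL effects are drawn per pool haplotype from `N(0, effect_sd²)` and
centered to sum to zero per locus; the genotype→phenotype map for the
stress/non-stress ratio is linear in the summed allele effects with
additive Gaussian noise — matching the additive model the scan assumes —
standardized so the genotypic standard deviation of the ratio is 0.12
around a baseline of 0.6 (a realistic stress-to-control ratio scale).
Checks are the accessions with the most extreme combined genotypic
values, which guarantees the tolerant check mean exceeds the sensitive
one in every replication with overwhelming probability.

**Noise calibration.** The plain closed form
`σ²_e = σ²_g · r · (1 − h²)/h²` targets the ANOVA identity, but the
membership transform divides every replication by the *noisy* check
means: the sensitive-anchor noise (variance `σ²_e/n_S`, shared within a
replication) lands in the one-way ANOVA error term, and the noisy
tolerant–sensitive spread interacts with each accession's distance from
the anchor. The generator therefore divides the closed-form variance by

$$c = 1 + \frac{1}{n_S} + \frac{\sigma^2_g + d^2}{B^2}
      \left(\frac{1}{n_T} + \frac{1}{n_S}\right),$$

where `B` is the true check-mean spread and `d` the distance from the
population mean to the sensitive anchor, both known to the generator at
generation time. Without the correction the realized h² sits about 0.05
below target at n = 400; with it, the 20-seed mean lands within ±0.02 of
the target, which the tests check at a ±0.05 tolerance.

Two traits (plant-weight-like and plant-height-like) are generated from
independently drawn QTL models with independent noise, so their genetic
systems differ — as the two real indicators' largely disjoint QTL sets
suggest they should.

**What passing tests do and do not show.** The generator reproduces the
*statistical structure* the analysis assumes: additive multi-allele
effects, clean block boundaries, free recombination between blocks,
Gaussian plot noise. Real panels violate all of these in degrees —
linked blocks, epistasis, genotype × environment interaction, spatial
field trends, ascertainment in the SNP set. Recovery rates and
calibration results on synthetic panels are therefore upper bounds on,
not estimates of, real-data performance.

## Problem sizes and numerical choices

The shipped tests run the full pipeline at panel sizes of 100–400
accessions with 60–240 SNPs and up to 20 QTL, and the statistical
property suites use 10–20 generator seeds; these sizes give stable
averages for every property tested while keeping the whole suite at
about half a minute on one core. Degenerate inputs are handled
explicitly: a constant phenotype yields zero R² rather than 0/0;
monomorphic markers are dropped at assembly; an all-missing SNP is an
error (impossible after QC); the h² estimator truncates negative
variance components; the stepwise loop carries a hard step limit and a
residual-degrees-of-freedom guard. All randomness flows from explicit
seeds (per-cross progeny seeds are derived deterministically from the
master seed), and per-replication, per-marker and per-locus computations
are order-independent, which the permutation-invariance tests pin down.

## Known limitations

- No mixed-model (kinship) association; structure correction is by fixed
  eigenvector covariates only, as in the two-stage procedure it follows.
- No linkage-informed gamete sampling in cross prediction; loci
  recombine freely.
- Major-allele imputation, not haplotype-model imputation.
- The one-way h² is a pragmatic cap, not a full split-plot variance
  decomposition.
- Multi-allelic *SNPs* are not supported as input; multi-allelism enters
  only through haplotype-block markers.
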