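---
title: "Models and methods behind epigp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epigp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigp)
```

## The problem

In livestock genetic evaluation, genomic prediction usually targets breeding
values (additive effects), but dominance and epistatic effects also contribute
to phenotypes. `epigp` implements the whole analysis chain needed to ask two
questions about a population genotyped for genome-wide SNPs: how much
phenotypic variance do non-additive components explain, and does modelling
them actually improve phenotype prediction? A companion subsampling experiment
probes a subtler question: whether variance *components* and genetic
*effect estimates* are equally stable when the phenotyped population shrinks.

## Marker codings and kernels

Genotypes are biallelic dosages $x \in \{0,1,2\}$. Codings follow the natural
and orthogonal interactions (NOIA) parameterisation, built from the
*observed* genotype frequencies $(p_0, p_1, p_2)$ of the analysed animals:

* additive: $w_A(x) = x - (p_1 + 2 p_2)$, the centred allele count;
* dominance: $w_D(0) = -2 p_1 p_2 / d$, $w_D(1) = 4 p_0 p_2 / d$,
  $w_D(2) = -2 p_0 p_1 / d$ with $d = p_0 + p_2 - (p_0 - p_2)^2$.

Under these frequencies the two codings have mean zero and are exactly
orthogonal per SNP, so the additive effect keeps its least-squares
(statistical) meaning even when dominance is in the model. Because the
frequencies are population-bound, codings are recomputed whenever the animal
set changes (e.g. inside the subsampling experiment).

Relationship kernels are $A = W_A W_A^\top$ and $D = W_D W_D^\top$, each
scaled so the trace equals the number of animals $n$; epistatic kernels are
trace-scaled Hadamard products $AA = A \odot A$, $AD = A \odot D$,
$DD = D \odot D$. Scaling is applied *after* the product (the alternative —
scaling before — is not distinguishable from the published description; the
post-product choice keeps every kernel on the same trace-$n$ scale and only
changes variance components by a scalar). The Hadamard AA contains same-SNP
squares and counts each SNP pair twice; the exact pairwise form
$\big((W W^\top) \odot (W W^\top) - (W \odot W)(W \odot W)^\top\big)/2$
sums each unordered pair once. The package provides both, and the acceptance
suite confirms the two agree (off-diagonal correlation > 0.999) at realistic
SNP densities, which justifies using the cheap Hadamard form.

Monomorphic SNPs are excluded from both codings. SNPs whose dominance
denominator $d$ is numerically degenerate (e.g. all heterozygotes) are
excluded from $W_D$ only: their additive information is still valid.

## Mixed model and REML

For one trait, $y = X\beta + \sum_k u_k + e$ with
$u_k \sim N(0, K_k \sigma^2_k)$ over a chosen kernel list and
$e \sim N(0, I\sigma^2_E)$. Model names encode the kernel list: A (additive
only), D (+dominance), AA (+additive-by-additive), AD, Full
(all five), and AA2 (additive + AA without dominance).

Variance components are estimated by average-information (AI) REML:

* the restricted log-likelihood is profiled over $\beta$;
* an AI step solves the average-information system; components pushed below
  zero are pinned at the boundary through an active-set re-solve, so free
  components still take an accurate Newton-type step (naive whole-step
  halving can freeze all components when one sits on the boundary — this was
  observable as premature convergence and is caught by a grid-search oracle
  test);
* a step is accepted only if the likelihood does not decrease; otherwise the
  AI system is re-solved under increasing Levenberg–Marquardt damping (plain
  step-halving zig-zags in the flat additive-by-additive-versus-residual
  likelihood valley typical of half-sib panels), with a monotone EM update as
  the last resort; components decaying below 1e-6 of the phenotypic variance
  snap to exactly zero;
* convergence requires relative log-likelihood change < 1e-8 and maximum
  relative parameter change < 1e-6, within 200 iterations;
* standard errors come from the inverse AI matrix; components pinned at zero
  report `NA` (the AI matrix is invalid on the boundary);
* the residual variance is bounded below at `1e-8 * var(y)` to keep $V$
  invertible; a Cholesky failure adds diagonal jitter `1e-8 * mean(diag(V))`
  with a warning;
* starting values split the phenotypic variance equally across components.

AIC is $-2\,\mathrm{logLik}_{REML} + 2k$ with $k$ the number of variance
components including the residual; fixed effects are profiled out and not
counted (packaged fitters differ on this, hence the explicit statement).

BLUPs for *all* animals, phenotyped or not, use
$\hat u_k = \hat\sigma^2_k K_k[\cdot, obs]\, V^{-1}(y - X\hat\beta)$ — the
standard GBLUP extrapolation through kernel covariances. Proportions of
phenotypic variance are $\hat\sigma^2_k / \sum_j \hat\sigma^2_j$ with
delta-method standard errors from the AI covariance matrix.

## Fixed effects and directional dominance

The design contains categorical factors (sex, farm, slaughter date),
continuous covariates (age, and the percentage of heterozygous SNPs per
animal), with covariates standardised before fitting and factor levels
smaller than `min_level_size` (default 10 animals) merged into a single
fallback level. The heterozygosity covariate captures directional dominance:
a non-zero mean of dominance effects manifests as a linear phenotype–
heterozygosity relationship (inbreeding depression when positive). Because
the covariate is standardised, the slope is reported on both the
per-SD and the per-percentage-point scale (coefficient divided by the SD of
`het_percent`), since either convention is defensible for reporting.

## Cross-validation

Predictive ability uses 10-fold cross-validation with the constraint that
every farm and slaughter-date level is represented in every training set
(random assignment plus deterministic repair). Accuracy is the Pearson
correlation between phenotypes adjusted for fixed effects and predicted
total genotypic values (the sum of all genetic components); bias is the slope
of predictions regressed on adjusted phenotypes. Two conventions are
deliberate:

* adjusted phenotypes use fixed effects estimated from the *full* data with
  the same model used for prediction, accepting a mild information leak; a
  strict fold-wise adjustment is available via `adjust = "fold"`;
* the single reported accuracy pools all test predictions (each animal
  predicted exactly once) rather than averaging per-fold correlations;
  per-fold values are also returned. The published analyses do not state
  which aggregation they used; pooling was chosen because it uses every
  prediction once with no weighting ambiguity.

Test-fold genotypes (kernel rows) participate in prediction; only their
phenotypes are masked — that is what "predicting unphenotyped animals" means
in GBLUP.

## Subsampling stability

The experiment refits an intercept-only model with A and AA kernels on random
subsamples of the phenotyped animals, using phenotypes pre-adjusted for fixed
effects from the full-data AA2 fit, then correlates effect estimates with the
full-data estimates separately for sampled (phenotyped) and unsampled
animals. Sizes default to the canonical 500/1000/5000/8865 schedule scaled by
$n/9850$ when $n$ differs. Two kernel-handling modes exist because the
published description does not fix one: `recompute` (default) rebuilds NOIA
codings from the subsample's own genotype frequencies and applies them to all
animals; `slice` reuses the full-data kernels rescaled so the sampled block
has mean diagonal one. Ten replicates per size (the original figures show
single draws; replication exposes the variability they describe
qualitatively).

The expected pattern, which the acceptance suite reproduces on synthetic
data, is the decoupling of the two kinds of estimate: variance components at
the largest sub-size agree with the full-data fit within two standard errors,
while correlations of *unsampled* animals' AA effects stay far below those of
their additive effects. The mechanism is visible in `offdiagonal_summary()`:
off-diagonal AA relationships are the element-wise squares of sub-unit
additive relationships, hence much closer to zero, so AA effects of animals
without phenotypes are barely connected to the data.

## The synthetic world

`simulate_genotypes()` emulates a progeny-testing population: paternal
half-sib families (default 20–100 sires, ~20–25 offspring each), dam
haplotypes drawn independently per offspring (no maternal sibs; a
`full_sibs` flag exists but is off by default), biallelic SNPs with
population MAF uniform on (0.05, 0.5] and post-hoc pruning at observed
MAF ≥ 0.05. Haplotype alleles follow a latent Gaussian AR(1) chain with one
parameter `ld_rho` (default 0.9), giving a tunable adjacent-SNP $r^2$
distribution; sire gametes recombine with per-interval switch probability
0.01. A single-parameter chain reproduces a realistic median adjacent $r^2$
but not the full quantile shape of array data (which mixes strong local LD
with recombination hotspots); LD realism beyond adjacent-pair summaries is
explicitly out of scope.

`simulate_effects()` draws SNP additive effects i.i.d. normal, dominance
effects normal with mean `directional_shift` (directional dominance), and
additive-by-additive effects on sampled unordered SNP pairs
(default `2 * n_snps` pairs, a polygenic-epistasis choice). Each component is
rescaled so its empirical variance over animals *exactly* equals the
requested fraction of the target phenotypic variance — this makes
parameter-recovery tests sharp. Two epistasis modes matter:

* `"pairs"` (default) gives a kernel-independent ground truth for
  effect-prediction experiments;
* `"kernel"` draws $u_{AA} \sim N(0, AA\,\sigma^2)$, matching the model's own
  covariance assumption.

The modes are not interchangeable for variance-component recovery: with a
finite pair architecture only the part of the realized covariance that
projects onto the $AA$ kernel is attributed to $\sigma^2_{AA}$; the remainder
is absorbed by the residual, so pairs-mode recovery is biased downward
(observed: ~0.08 recovered from a 0.15 target at n = 2000, 3000 SNPs, 6000
pairs). This is a property of the kernel approximation, not of the REML
engine, so the engine's recovery criterion uses the `"kernel"` mode; the
pairs mode remains the default for prediction experiments where an
model-independent truth is the point. A green recovery test therefore
establishes correctness of the estimator under its own model, not that a
pair-level architecture yields unbiased AA components.

`simulate_phenotypes()` adds balanced categorical factors (defaults emulate
sex/farm/slaughter-date), small covariate effects, and an i.i.d. normal
residual at `1 - sum(fractions)` of the target variance. Factor effects are
kept small (SD 0.1 of the phenotypic SD) so realized variance fractions stay
near their targets; farm assignment is random, which understates any real
confounding between family and farm. Heterozygosity is never added as an
explicit effect — any phenotype–heterozygosity slope emerges from the
directional dominance in the effects object, which is what makes the
directional-dominance estimator testable.

## Numerical and policy choices

* Genotype frequencies for codings are always the observed frequencies of
  the analysed animal set, never HWE-expected ones.
* SNP-density thinning samples `round(fraction * block)` SNPs from each
  consecutive block of 8 (genome order within chromosome); a final partial
  block is sampled proportionally.
* The kernel text format stores 12 significant digits and round-trips at
  that precision.
* Multi-allelic VCF records are skipped with a count; missing genotypes
  fail by default (`missing = "impute"` imputes the per-SNP mode).
* Cross-validation requires every stratification level to have at least two
  animals; singleton levels are an error directing the user to merge
  upstream (the design builder's `min_level_size` does this for farms).
* Time-budget scale-downs in the test suite: the "little gain"
  cross-validation contrast runs at n = 1000 and the training-size
  monotonicity check at sizes 250/500/1000; both are noted in the test files.

## Known limitations

* LD model is first-order; no coalescent-grade haplotype structure,
  no imputation.
* Single-trait models with homogeneous residual variance only; no pedigree
  or single-step matrices; no Bayesian estimation.
* Delta-method SEs of variance proportions are asymptotic; near boundaries
  they are reported as `NA` rather than extrapolated.
* The AA2/AD model choice for cross-validation is configuration, not
  automated model selection (AIC is reported but known to favour complex
  models here).
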