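---
title: "Multi-trait genomic prediction and corrected accuracy estimation"
author: "mtgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genomic prediction and corrected accuracy estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtgp)
```

## The problem

A wheat breeding program phenotypes a large first-year yield trial (YT, the
*previous cycle*) and wants to predict the performance of the following
season's elite yield trial (EYT, the *current cycle*) before those lines are
phenotyped, using genome-wide markers. Two questions are entangled in
practice:

1. **Prediction**: how well can a multi-trait genomic model transfer
   information from the previous cycle (plus a small, quickly-phenotyped 10%
   of the current cycle) to the remaining 90%?
2. **Evaluation**: the quantity breeders care about is the *true accuracy*
   `Cor(g, ghat)` between unobservable genetic values and their predictions,
   but what is measurable is the correlation with noisy phenotypes. How should
   that measurement be corrected?

`mtgp` implements both: the Bayesian multi-trait genomic mixed model with its
Gibbs sampler, and the four accuracy estimators (PC1--PC4) evaluated in the
two-cycle cross-validation, together with a synthetic data generator whose
known true breeding values make every estimator's bias directly measurable.

## The model

For environments `i = 1..I`, lines `j = 1..J` and traits `t = 1..nT`, the
phenotype matrix `Y` (records x traits) follows

    Y = 1 mu' + X_E beta_E + Z_L b1 + Z_LE b2 + e

* `mu` — per-trait grand means; `beta_E` — environment main effects
  (corner-point constrained: the first environment's effect is zero, since
  `mu` absorbs it; Pearson metrics are shift-invariant so the constraint is
  purely an identifiability device);
* `b1 ~ MN(0, G, Sigma_T)` — line main effects, matrix-normal with row
  covariance the genomic relationship matrix `G` (VanRaden method 1) and
  column covariance the trait x trait genetic covariance `Sigma_T`. `G` is
  what lets information flow across cycles: current-cycle lines are
  predicted purely through their marker-derived relatedness to phenotyped
  lines;
* `b2 ~ MN(0, I (x) G, Sigma_TE)` — genotype x environment effects,
  independent across environments, G-structured within each;
* `e` — i.i.d. residual rows with unstructured trait covariance `R`.

Priors are flat on `(mu, beta_E)` and inverse-Wishart on each covariance:
`Sigma_T ~ IW(nu_T, S_T)`, `Sigma_TE ~ IW(nu_TE, S_TE)`, `R ~ IW(nu_R, S_R)`.
Defaults are `nu = nT + 2` and `S = 0.5 I` — weak, centered near the
magnitude of a standardized trait. The model is often written with a single
symbol for the trait covariance of both random terms; `mtgp` keeps
`Sigma_T` and `Sigma_TE` as separate sampled matrices with identical default
priors, which is strictly more general (they can be tied by fixing one).

### The sampler

`fit_multitrait()` is a Gibbs sampler over full conditionals. The key
computational device is the one-time eigendecomposition `G = U D U'`: when
every line contributes exactly one record per environment (always true for
two-cycle line-mean data), each trait's conditional for `b1` (and per
environment for `b2`) becomes *diagonal* in the eigenbasis, so a sweep costs
two `J x J` matrix-vector products per trait instead of a dense solve. A
dense-Cholesky fallback covers unbalanced designs at small `J`.

Missing phenotype cells — including deliberately masked testing lines, whose
records stay in the design — are data-augmented from their conditional
Gaussian each sweep. This is how partially observed multi-trait records
contribute exactly the information they carry, and how prediction of
unphenotyped lines arises naturally: their `b1` rows are sampled from the
`G`-conditional given everything observed.

Settings that matter (defaults): `n_iter = 12000`, `burn_in = 2000`,
`thin = 5`; a ridge of `1e-6` stabilizes `G` before factorization;
`seed` fixes the entire draw stream. Effective sample sizes of the variance
components are reported, not enforced.

Two design choices deserve a note:

* **Heritability.** `estimate_heritability()` fits the single-trait model on
  the whole two-cycle data and returns the posterior mean of
  `sigma_g2 / (sigma_g2 + sigma_ge2 + sigma_e2)` — the line main-effect
  variance over total phenotypic variance. Excluding the G x E variance is a
  flag (`gxe_in_denominator = FALSE`); with each line phenotyped in a single
  environment the two definitions differ only through the weakly identified
  `sigma_ge2`.
* **Fixed-effects estimability.** An environment with no observed records has
  an improper flat-prior posterior; the fitter refuses such data. This is
  precisely why the two-cycle cross-validation adds 10% of the current cycle
  to training.

## The four accuracy estimators

Write the testing-set phenotype as `Y = mu + g + eps` with `Cov(ghat, eps) = 0`
(predictions are built from training data only). Then

    Cor(ghat, Y) = Cor(ghat, g) * sqrt(h2),      h2 = Var(g) / Var(Y).

* **PC1** (`pc1()`), *predictive ability*: the plain Pearson correlation of
  observed phenotypes with predicted breeding values. By the identity above
  it *underestimates* the true accuracy by the factor `sqrt(h2)`.
* **PC2** (`pc2()`), *predictive accuracy*: `PC1 / sqrt(h2)`, the
  nonparametric correction; `h2` is estimated once from the whole dataset.
* **PC3** (`pc3()` on a `fit_bivariate_accuracy()` result): a parametric
  estimate. Observed and predicted values of the testing lines are modeled as
  a two-trait system with genetic covariance matrix `Sigma` (2 x 2, line
  covariance `G`) and *diagonal* residual covariance — the residual cross
  term is fixed at zero because predictions share no non-genetic source with
  the testing phenotypes. Per posterior draw,

      PC3 = [sigma_gop / sqrt(sigma_go2 * sigma_gp2)] * sqrt(h2_p),
      h2_p = sigma_gp2 / (sigma_gp2 + sigma_ep2),

  the genetic correlation attenuated by the prediction channel's own
  reliability; when `sigma_ep2 = 0` (predictions fully G-structured, as
  posterior means essentially are) it reduces to the genetic correlation.
  The ratio is averaged over draws (not evaluated at posterior means), which
  makes it invariant to per-draw scale reparameterization. The prediction
  channel's residual prior scale is small (0.01) for the same reason.
* **PC4** (`pc4()`): `PC3 * sqrt(h2)` — the parametric estimate mapped back
  to the phenotypic scale, comparable with PC1.

Two exact identities follow: `PC1 = PC2 * sqrt(h2)`, `PC4 = PC3 * sqrt(h2)`,
and hence the relative difference between corrected and uncorrected versions
is identically `100 (1/sqrt(h2) - 1)` percent. The error metrics `msep()`
and `maape()` complete the report; MAAPE's zero-denominator convention is
`arctan(Inf) = pi/2` for a missed zero and `0` for an exactly matched zero.

## The two-cycle cross-validation

`make_partitions()` draws five independent random selections of
`round-half-up(10%)` of the current-cycle lines (five 10% draws cannot tile
the data, so these are selections, not disjoint folds). For each partition,
`run_dataset_cv()`:

1. estimates `h2` per trait once from the whole data (shared across
   partitions);
2. fits the multi-trait model on previous-cycle + augmentation lines with
   *all* traits of the testing lines masked;
3. fits the single-trait model for the focal trait with the same predictors
   and the same partitions (a paired comparison);
4. scores testing-line predictions with PC1--PC4, MSEP, MAAPE per trait, and
   aggregates means and SDs into a tidy report (`write_report()`).

All randomness is derived from one master seed; two runs with the same seed
produce byte-identical report files.

## The synthetic data generator

`simulate_dataset()` draws the model's own generative process: binomial
genotypes at linkage equilibrium (allele frequencies uniform on a stated
range), `G` from those markers, `b1`, per-environment `b2`, and i.i.d.
residuals, with cycle-1 lines phenotyped only in environment 1 and cycle-2
lines only in environment 2. Defaults mirror a representative season of the
breeding program being emulated: 1,386 training lines, 509 testing lines,
14 traits, genetic variance 0.5 with compound-symmetric correlation 0.3,
G x E variance 0.1, residual variance 0.4 (so `h2 = 0.5` per trait);
2,000 markers, which is ample because the model consumes markers only
through `G`. Lines are unreplicated within an environment (line-mean data);
no linkage disequilibrium and no selection between cycles are simulated.

What this emulates — and what it does not: real GBS panels have missing-call
structure, allele-frequency spectra and LD that the generator omits, and real
cycles are connected by pedigree and selection, not only by marker sampling.
Tests passing on this generator therefore validate the *estimators and the
pipeline machinery* under the model's own assumptions; they do not certify
real-data accuracy magnitudes.

The generator records the true genetic values `g = b1 + b2` per line in its
own environment, so `true_accuracy()` computes the otherwise unobservable
`Cor(g, ghat)` directly, and the implied heritability
`sigma_T[t,t] / (sigma_T[t,t] + sigma_TE[t,t] + residual_cov[t,t])` is exposed
as `true_h2`.

## Marker quality control

`filter_markers()` applies the standard GBS panel filters with strict
inequalities: minor allele frequency above 0.05, missing fraction below 0.5,
heterozygote fraction below 0.05 (inbred wheat lines; heterozygous calls
indicate error). Frequencies for both filtering and `G`-centering are
computed on the combined two-cycle panel, since the model needs a single `G`
covering all lines. `impute_missing()` offers marker-mean imputation
(default, and sufficient for `G` at these tolerances) and a soft-impute-style
low-rank EM.

## Numerical choices and degenerate inputs

* Ridge `1e-6` on `G` before any factorization; eigenvalues floored at
  `ridge/1000`.
* Inverse-Wishart draws via `rWishart` on the inverted scale
  (`riw()`), symmetrized; every sampled covariance is positive definite by
  construction.
* Zero-variance phenotypes, traits with no observations, environments with no
  observations, fully missing markers, monomorphic panels and mismatched IDs
  are all rejected with explicit errors rather than propagating `NaN`.
* Corrected correlations above 1 (finite-sample artifact) are kept, with a
  warning.

## Calibration at finite sample size

With everything known by construction, the generator makes the estimators'
behavior checkable, and the package's tests do so at the study's sizes
(500 training / 200 current-cycle lines, `h2 = 0.5`, 30 replicates; reduced
MCMC settings of 1,500 sweeps for the main fits and 2,500 for the bivariate
fits, sizes chosen as a desk-scale compromise that keeps Monte-Carlo error
inside the tolerances): mean PC1 falls below the mean true accuracy by about
the predicted `sqrt(h2)` factor, while mean PC2 and mean PC3 land within
0.05 of it.

One idealized limit deserves honesty: on *noiseless* data the heritability
posterior does not reach 1 at these sample sizes. Small eigenvalues of a
finite-marker `G` let genetic signal trade off against residual variance, so
the exact posterior (computable by direct numerical integration in the
single-trait case) keeps some mass at `sigma_e2 > 0`; the package's test
verifies the sampler against that exact answer rather than against the
idealization. Relatedly, the Gibbs chain mixes slowly in this corner — the
centered parameterization's known weakness — which is why near-noiseless
checks use longer chains.

## Known limitations

* The sampler's fast path assumes one record per line per environment;
  replicated plot-level data must be pre-aggregated to line means.
* `Sigma_TE` is weakly identified when every line appears in a single
  environment (it is separated from `R` only through `G`-structure);
  heritability estimation is run with and without it as a flag.
* REML / maximum-likelihood fitting is out of scope by design (the Bayesian
  route avoids the convergence problems such multi-trait fits are known for),
  as are marker-effect (SNP-BLUP) parameterizations and non-Gaussian traits.
* PC3 requires a reasonable testing-set size; below 30 lines the bivariate
  variance components are poorly resolved and the function warns.
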