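---
title: "Multi-trait kernel prediction of hybrid performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait kernel prediction of hybrid performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The statistical model

`hybridgp` predicts the performance of wheat hybrids — crosses between a
small set of male testers and a large set of female lines — for several
correlated traits at once. The observation unit is a hybrid × year BLUE
(best linear unbiased estimate from the field-trial analysis, which this
package takes as given). Collecting the n observations for T traits into a
matrix Y, the model is a sum of kernel-structured random effects:

Y = Z_E β_E + Z_M g_M + Z_F g_F + Z_H h + u_M + u_F + u_H + X_AC β_AC + ε

* **Year main effects** β_E (one row per year) carry an isotropic
  matrix-variate normal prior MN(0, σ²_E I, I_T): a single scalar variance
  shared across traits. Because responses are centered per trait
  internally (the model has no grand mean; trait means are restored in
  predictions), this term only absorbs year deviations.
* **General combining ability (GCA)**: g_M ~ MN(0, G_M, Σ_M) and
  g_F ~ MN(0, G_F, Σ_F) are male and female additive contributions. The row
  covariances G_M, G_F are marker kernels; the column covariances Σ are
  unstructured T × T trait covariances, so information is shared both
  across relatives and across traits.
* **Specific combining ability (SCA)**: h ~ MN(0, H, Σ_H) with the
  hybrid-level Hadamard kernel H = (Z_M G_M Z_M') ⊙ (Z_F G_F Z_F'),
  positive semi-definite by the Schur product theorem. This captures
  cross-specific deviation from the sum of parental GCAs — the model's
  only marker-driven non-additive term.
* **Kernel × year interactions** u_M, u_F, u_H with observation-level row
  covariances V = (Z G Z') ⊙ (Z_E Z_E'): genetic similarity is retained
  within a year and zeroed across years, the usual device for
  genotype-by-environment interaction with environments as years.
* **Parental covariates** X_AC β_AC (optional): two columns per trait,
  an additive mid-parent covariate (P_M + P_F)/2 and a dominance-style
  half absolute difference |P_M − P_F|/2, built either from parental
  phenotypes directly (*Pmean*) or from estimated parental breeding values
  (*BV*); the *NO_Cov* strategy omits the term. All 2T columns enter the
  model for every response trait with a full coefficient matrix, so
  covariates of correlated traits also contribute.
* **Residual** rows ε_i ~ N(0, R) with unstructured T × T covariance.

Parental breeding values for the BV strategy come from the single-trait
model P = 1μ + g + e with g ~ N(0, σ²_g G) over all phenotyped parents,
fitted by the same sampler; parents observed in several years are averaged
across years first (the parent model carries no year term).

### Kernels

Kernel choice applies to the parental similarity matrices G_M and G_F, and
through them to the SCA and interaction kernels:

* **linear**: the VanRaden matrix G = WW'/p from centered, unit-variance
  markers — the GBLUP baseline.
* **Gaussian (GK)**: K(x_i, x_j) = exp(−γ d²_ij / mean(d²)), with squared
  Euclidean distances scaled by their off-diagonal mean. On that scale
  γ = 1 (the default) is the standard bandwidth choice in genomic
  prediction; γ is configurable and no marginal-likelihood tuning is
  attempted. The diagonal is exactly 1.
* **Arc-cosine (AC_1 … AC_4)**: the infinite-width neural-network kernel
  with ramp activation (degree 1, configurable to 0 or 2). The base layer
  is k(x, y) = (1/π)‖x‖‖y‖ J₁(θ) with J₁(θ) = sin θ + (π − θ) cos θ;
  deeper layers iterate the same map on the normalized kernel. The final
  matrix is rescaled to mean diagonal 1 so that variance priors are
  comparable across all six kernels.

## The Gibbs sampler

`mtgp()` samples all parameters from their full conditionals in a fixed
order (effects, covariate coefficients, trait covariances, residual
covariance, masked responses), which makes runs bit-reproducible given a
seed.

The computational core: each observation-level kernel K_k is
eigendecomposed **once** per fit, K_k = U D U'. Rotating the working
residual into that basis makes the rows of the rotated effect matrix
conditionally independent, with row i having prior N(0, d_i Σ_k) and
likelihood N(row, R). Per iteration, the pair (Σ_k, R) is jointly
diagonalized (a T × T generalized eigenproblem), after which every row
update is an elementwise shrinkage — the whole effect matrix is sampled
with two matrix products and no per-row loop. Trait covariances get
inverse-Wishart conditionals; the year scalar variance a scaled-inverse-χ²
conditional; the covariate coefficient matrix a qT-dimensional Gaussian
conditional (q = number of covariate columns).

Missing and held-out responses are re-imputed each iteration from the
conditional normal of the current fit (data augmentation), grouped by
missingness pattern. This matches the "untested hybrids in tested years"
design — whole rows of test hybrids are masked — and keeps every
conditional conjugate.

### Priors and defaults

The paper trail for this class of models rarely reports chain settings, so
the package uses explicit, weakly informative defaults, all overridable:

* Each Σ and R: inverse-Wishart with df₀ = T + 2 and scale chosen so the
  prior expectation gives every term (and the residual) an equal share of
  the observed per-trait phenotypic variance.
* Year variance: scaled-inverse-χ² with df₀ = 5 and the analogous share.
* Covariate coefficients: independent N(0, 100²) on standardized
  covariates — effectively flat. Covariate columns are standardized by
  default because traits are measured in different units (days vs t/ha).
* Chains: `niter = 10000, burnin = 5000, thin = 5` as conservative
  defaults for final analyses. The test-suite and acceptance runs use
  shorter chains (300–2 500 iterations for cross-validation fits, 25 000
  for the closed-form oracle comparison), sizes chosen so that the whole
  suite completes in minutes on one CPU; these are stated here as the
  package's own protocol choices.

### Numerical choices

* Kernel eigenvalues below 1e−10 of the maximum are truncated; those
  effect directions stay at their prior mean of zero. This handles the
  deliberately rank-deficient expanded kernels (e.g. a year kernel of rank
  = number of years).
* `ensure_psd()` repairs indefinite kernels by escalating diagonal jitter
  (start 1e−8, ×10, at most 6 times), failing loudly otherwise. The PSD
  tolerance is −1e−8 on the minimum eigenvalue throughout.
* Cosines feeding `acos` are clamped to [−1, 1]; zero-norm marker rows are
  an error naming the individual.
* Marker standardization uses the population SD (divisor n), which makes
  mean(diag G) = 1 an exact identity used in tests. Monomorphic columns
  are dropped with a warning, never an error. Missingness and MAF
  thresholds are strict (<) and configurable; imputation is the continuous
  column mean (= 2 × observed allele frequency), not rounded — kernels do
  not need integer dosages.
* Inverse-Wishart draws go through `rWishart` on the inverted scale
  matrix; symmetry is re-imposed after every linear-algebra step that can
  lose it to rounding.

## Cross-validation and metrics

Folds partition **hybrids**, not observations: all year-records of a test
hybrid are masked together, every year stays represented in training, and
a guard inside the cross-validation loop asserts on every fold that no
test-hybrid response is visible to the training fit. Parents are never
masked — the scheme predicts untested crosses, not untested parents — so
Pmean covariates and BV estimates are fold-invariant; breeding values are
therefore computed once per dataset rather than re-estimated per fold
(the refits would be identical).

NRMSE is RMSE divided by the mean of the observed test values. The
normalizer is not standard across the literature; mean-normalization is
the package default (sensible for strictly positive BLUEs), with SD- and
range-normalization available via a flag. Per-fold NRMSE values are
averaged over folds within trait × year; `Global` is the unweighted mean
of the per-year values (pooling across years is the other defensible
choice; averaging was fixed here). Relative efficiency is
RE = NRMSE_x / NRMSE_ref with companion gain (NRMSE_ref/NRMSE_x − 1)×100.

## The synthetic trial generator

`simulate_hybrid_trial()` is first-class, tested code, not a fixture: it
draws every term of the model above from its stated distribution, so the
generator and the fitted model agree by construction. It emulates the
structure of a large hybrid wheat program at desk scale:

* Default design: 12 males × 120 females, 3 crosses per female (360
  hybrids), 500 SNPs, 3 years in which roughly half the hybrids appear,
  with 30% of a year's set carried over from the previous year — an
  incomplete factorial with partially overlapping year sets, like real
  multi-year trials. The desk scale keeps a full seven-fold
  cross-validation in the minutes range.
* Inbred parents are coded 0/2 with per-marker allele frequencies uniform
  on [0.1, 0.5]; hybrids are the deterministic parental mean (F1 of
  inbreds); 3% of parental marker cells are set missing to exercise QC.
* Terms are generated on a standardized trait scale and mapped to trait
  units (GY: mean 6 t/ha, SD 0.8; DTF/DTH: means 80/85 days, SD 5), so
  variance budgets read as shares of phenotypic variance. Defaults: GCA
  male 0.25, GCA female 0.20, SCA 0.15 (broad-sense heritability 0.60),
  year 0.05, interactions 0.04/0.03/0.03, residual 0.25. Genetic trait
  correlations default to strongly coupled phenology (DTF–DTH 0.9) and
  mildly negative yield–phenology (−0.3, −0.25), typical magnitudes for
  spring wheat; residual correlations 0.1/0.1/0.6.
* Parental phenotypes are the parent's GCA plus noise at heritability
  0.7 — informative about, but not identical to, the breeding values the
  BV strategy estimates.
* With `parental_signal = TRUE` the generator adds X_AC β_AC to the hybrid
  responses, with default coefficient 0.4 on each trait's own additive
  covariate (≈ 14% extra variance): the setting in which parental
  covariates demonstrably help, used by the directional tests.

What the generator does **not** emulate: linkage disequilibrium and
recombination (markers are independent), selection across cycles,
trial-design noise below the BLUE level, heterogeneous year sizes, and
non-Gaussian trait architecture. Passing tests therefore demonstrate
internal consistency of estimation and prediction under the model's own
assumptions — not performance on real wheat data, where kernel and
strategy rankings can differ.

## Design decisions on open points

* The symmetric SCA kernel H uses Z_F in both factors' expansions; the
  asymmetric variant that sometimes appears in print is dimensionally
  inconsistent and was treated as a typographical slip.
* Whether nonlinear kernels should apply to the SCA term as well as the
  GCA terms is ambiguous in the literature; they are applied uniformly
  here, so "kernel = linear" reproduces classical GBLUP exactly and the
  nonlinear kernels replace G everywhere.
* BV estimation always uses the linear VanRaden kernel over all parents
  (combined male + female standardization): it is covariate
  preprocessing, kept fixed so that kernel comparisons differ only in the
  hybrid model. Eq.-style parent models are fitted across years.
* Whether covariates should enter raw or standardized is unreported in
  this literature; standardized is the default so that one prior scale
  fits traits in different units.
* Per-trait intercepts are implemented by centering rather than sampling,
  avoiding an extra fixed effect confounded with the year term.

## Known limitations

* A single chain with fixed update order; convergence diagnostics beyond
  Monte Carlo standard errors (multi-chain R̂, effective sample size) are
  out of scope.
* With few male testers (the realistic regime: ~12–18), the trait
  correlations of the male-GCA covariance Σ_M are weakly identified — the
  realized correlation of a dozen correlated male effects scatters around
  the generating parameter with a spread of ~0.2, so point recovery of
  Σ_M correlations to tight tolerances is not achievable at this design
  size for any estimator; the female-side covariance (hundreds of lines)
  and the per-trait male effects themselves are recovered much more
  precisely. The parameter-recovery test in the suite documents this
  boundary deliberately.
* No REML/frequentist path, no kernel hyperparameter optimization, no
  low-rank approximations, no VCF/PLINK parsing (CSV dosage matrices
  only), and no significance testing between strategies.
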