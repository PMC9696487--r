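---
title: "Data-driven path analysis of post-COVID pain cohorts: models and methods"
author: "painpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven path analysis of post-COVID pain cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painpath)
```

## The problem and the modelling strategy

Persistent pain is common after COVID-19 hospitalisation, and its clinical
picture mixes sensory variables (pain intensity, central-sensitization
symptoms, neuropathic pain screens), psychological variables (anxiety,
depression, sleep quality) and cognitive variables (catastrophizing,
kinesiophobia). With no settled theory of how these variables influence one
another, a defensible structural model can be learned from the data itself:

1. **Structure learning.** A Gaussian Bayesian network is learned by greedy
   hill climbing on a decomposable BIC score, with the biological constraint
   that nothing can cause body-mass index or sex (a blacklist on all arcs
   into `BMI` and `Sex`). Because a single greedy search is unstable at
   cohort sizes of a few hundred, the data are bootstrap-resampled (`B`
   replicates), a network is learned on each, and a consensus DAG keeps
   only arcs appearing in more than 70% of replicates, oriented by
   majority direction.
2. **Parameter estimation.** The consensus DAG is then treated as an
   observed-variable path model `x = Bx + e` and fitted by maximum
   likelihood, minimising the Wishart discrepancy
   `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`. Model adequacy is judged
   by RMSEA, CFI, NNFI and SRMR, and inference (standard errors, CIs, a
   model-test p-value) uses the Bollen-Stine bootstrap, which transforms
   the data so the fitted model is exactly true in the resampling
   population.
3. **Mediation.** Serial indirect effects along directed chains are
   product-of-coefficients estimates with nonparametric-bootstrap and
   delta-method uncertainty.

The package implements each stage as a separate module (`hill_climb()`,
`bootstrap_strength()`, `averaged_network()`, `fit_path_model()`,
`bollen_stine()`, `indirect_effect_inference()`) and chains them in
`run_pipeline()`.

## The cohort data model

Twelve variables are modelled (`default_schema()`): BMI and Sex as
exogenous, and ten patient-reported outcomes as endogenous — pain intensity
(NPRS, 0–10), anxiety and depression (HADS-A/HADS-D, 0–21), sleep quality
(PSQI, 0–21), the neuropathic screens PainDETECT (−1–38) and S-LANSS
(0–24), central-sensitization symptoms (CSI, 0–100), catastrophizing (PCS,
0–52), kinesiophobia (TSK-11, 11–44), and health-related quality of life
(EQ-5D, 0–1). Sex is coded female = 0, male = 1; this sign convention makes
a negative Sex coefficient mean "males score lower".

Cohorts are plain CSV files with a header row; empty cells, `NA` and `NaN`
are missing. Before analysis every continuous variable is z-scored with the
sample SD (n − 1 denominator); the O(1/n) difference from the population SD
is immaterial at cohort scale. Sex keeps its 0/1 coding through the data
step — a *fully* standardized solution (every variable unit-variance,
including Sex) is produced analytically at reporting time from the implied
covariance, which is what the coefficient table prints.

## The synthetic cohort generator

No patient-level data ship with the package. Instead,
`default_generating_model()` encodes the linear-Gaussian recursive model
the analysis assumes, calibrated so that the whole pipeline is testable:

- the 16-arc DAG over the 12 variables with its standardized path
  coefficients (e.g. depression → pain 0.241, anxiety → depression 0.745,
  CSI → PainDETECT 0.406);
- an exogenous covariance of 0.073 between BMI and Sex;
- residual covariances among the four sink variables (Pain, S-LANSS,
  Catastrop, EQ-5D) at their fitted values, drawn jointly from a
  multivariate normal so the implied covariance reproduces them;
- endogenous residual variances completed by
  `complete_standardized_residuals()` so every variable's implied variance
  is exactly 1 — this completion reproduces the reported residual
  variances (0.445 for depression, 0.591 for CSI, …) to three decimals,
  which is the package's primary deterministic calibration check;
- raw scales restored affinely from the cohort descriptives (pain
  5.6 ± 1.7, CSI 33.9 ± 17.2, BMI 29.25 ± 5.2, …) and a 54.5% female
  fraction, the cohort's reported composition.

Sex is drawn Bernoulli and enters the recursion scaled to unit variance so
that standardized coefficients apply exactly; BMI is built as
`0.073 * Sex_z + sqrt(1 - 0.073^2) * noise`. Missingness is injected MCAR
at 3% per cell by default (the source cohort reports "less than 5%", with
no stated mechanism; MCAR is the weakest assumption compatible with that
statement), never masking BMI or Sex.

What the generator does *not* emulate: bounded, discrete questionnaire
scores (values are Gaussian on the raw scale; `clip = TRUE` truncates at
instrument bounds but is off by default because truncation distorts the
covariance structure the tests rely on), item-level response behaviour,
MAR/MNAR missingness, and any longitudinal structure. Passing tests
therefore demonstrate correctness of the *algorithms* under the stated
linear-Gaussian model, not robustness to violations of it.

```{r generator}
gm <- default_generating_model()
gm
round(diag(gm$model$Psi), 3)
```

## Imputation

`impute_chained()` is classic chained-equations imputation: random draws
from observed values initialise the missing cells, then each incomplete
variable is re-imputed in schema order from a model on all other
variables, for `max_iter` sweeps, independently `m` times from distinct
sub-seeds (defaults m = 20, max_iter = 30, matching the source analysis;
that analysis then carried a single completed dataset forward, so
`select_imputed(result, 1)` is the default downstream input). Three
engines are provided: a Bayesian linear-regression posterior predictive
(`normal`), predictive mean matching with 5 donors (`pmm`), and the
default `random_forest`, which grows a 10-tree forest and draws from the
observed values sharing the missing case's terminal node in a randomly
chosen tree. Binary variables use a logistic draw. Observed cells are
never altered.

## Numerical choices

- **BIC convention.** Node score `logL - (k/2) log n` with
  `k = |parents| + 2` (intercept and residual variance counted). Any
  per-node constant cancels in move comparisons; the per-parent penalty is
  what drives sparsity. A node that is an exact linear function of its
  parents scores `-Inf` rather than erroring inside the search.
- **Hill climbing.** Start graph is the whitelist (empty by default); moves
  are single-arc additions, deletions and reversals; only strictly
  improving moves (delta > 1e-10) are taken; candidate enumeration order is
  fixed and ties keep the first-found best move, so the search is fully
  deterministic given the data. Internally parent sets are bitmasks with a
  memoised score cache and cycle checks use a transitive-closure matrix,
  which keeps a 1000-replicate bootstrap on a 146-subject cohort to tens
  of seconds.
- **Consensus threshold.** Strictly greater than 0.70, per the reported
  procedure. If majority orientations ever produce a cycle the
  lowest-presence arc in each cycle is dropped until the result is acyclic.
- **ML fit.** Free parameters are one coefficient per arc, one residual
  variance per endogenous node, and one residual covariance per declared
  pair; exogenous moments are fixed at sample values and excluded from the
  free-parameter count (degrees of freedom
  `p(p+1)/2 - n_free - n_exo_moments`). For models with no free residual
  covariances the per-equation least-squares solution *is* the ML optimum
  (asserted against the numerical optimizer in the tests) and is returned
  directly; otherwise BFGS minimises the discrepancy from that warm start
  with an analytic gradient, relative tolerance 1e-14, max 500 iterations,
  and the fit records the final gradient norm. Negative residual-variance
  estimates (Heywood cases) are flagged with a warning, not silently
  truncated.
- **Residual-covariance policy.** By default all pairs among endogenous
  sink nodes (out-degree 0) are freed — for the default network exactly
  the six Pain/S-LANSS/Catastrop/EQ-5D pairs of the reported solution.
  The learned DAG alone cannot supply these; freeing the sink pairs is the
  specification that reproduces the reported parameter set, and it is
  overridable (`residual_pairs = "none"` or an explicit pair list).
- **Test statistic.** `T = (n - 1) * F` (Wishart convention), configurable
  to `n` for cross-checks against tools that use the other convention.
  RMSEA uses `sqrt(max(T - df, 0)/(df (n - 1)))`; CFI clamps at [0, 1];
  NNFI is deliberately *not* capped (well-fitting models can exceed 1);
  SRMR includes diagonal terms (benign here, since free residual variances
  fit the diagonal exactly). With df = 0, RMSEA and NNFI are reported as
  `NA`.
- **Bollen-Stine.** The centred data are transformed by
  `S^{-1/2} Sigma-hat^{1/2}` (symmetric square roots), making the fitted
  model exactly true in the resampling population; the model p-value is
  `(#{T* >= T} + 1)/(B + 1)`. Refits warm-start from the full-sample
  estimates; failed refits are counted and more than 10% of failures is an
  error, not a silent omission.
- **Mediation p-values.** Sign-based two-sided bootstrap p,
  `2 (min(#{<=0}, #{>=0}) + 1)/(B + 1)` capped at 1; the delta-method SE
  uses the first-order product-variance formula with the bootstrap
  covariance of the chain coefficients.
- **Seeds.** Every stochastic stage takes an explicit integer seed;
  `run_pipeline()` derives per-stage sub-seeds by hashing (master seed,
  stage name), so stages are individually reproducible and insensitive to
  reordering.

## Default mediation chains

Four serial chains are evaluated by default, matching the hypothesised
pathways of the motivating analysis: `Anx → Dep → CSI`,
`Dep → CSI → Fear → Sleep`, `Sex → CSI → PainDETECT → S-LANSS`, and
`Dep → CSI → Fear → Catastrop`. On the default generating model their
products reproduce the reported values:

```{r mediation}
sapply(default_mediation_chains(), function(ch)
  round(indirect_effect(default_generating_model(), ch), 3))
```

## What the tests compute, and at what scale

The test suite exercises each module against independent oracles: the node
score against `lm()` likelihoods; hill climbing against exhaustive
enumeration of all 25 three-node DAGs (exact score equality) and all 543
four-node DAGs (at least 99% of the score gap over the empty graph); the
ML fit against per-equation OLS for diagonal-residual models; fit indices
against an independently coded formula evaluation; the Bollen-Stine
transform identity to 1e-10. Distributional properties use reduced but
still informative sizes chosen to keep the default suite in the
one-to-two-minute range: bootstrap-null uniformity of the Bollen-Stine
p-value over 80 replicates of n = 300 with B = 149 (Kolmogorov-Smirnov at
the 1% level), mediation type-I error over 120 replicates of n = 500 with
B = 199 against Binomial 99% bounds, parameter recovery of all 16
generating coefficients within 0.01 from one n = 200,000 cohort, skeleton
recovery (F1 > 0.8) from n = 10,000 with B = 200, and covariance
convergence at n = 200,000. `scripts/acceptance.R` re-derives the
deterministic residual-variance completions and the large-n recovery of
the depression → pain coefficient from a fresh simulation.

## Known limitations

- Hill climbing identifies structure only up to Markov equivalence;
  reported arc directions within an equivalence class are a consequence of
  the search order and the blacklist, and should not be read causally. The
  consensus network reports learned directions with this caveat.
- The cross-sectional, observational character of the modelled cohort
  means fitted paths are associations; the package computes, it does not
  adjudicate causality.
- The generator's Gaussianity makes questionnaire floor/ceiling effects
  invisible to the test suite.
- Whether the motivating analysis learned structure on standardized or
  raw-scale data is not stated; the pipeline standardizes first (for the
  Gaussian BIC the choice affects only per-node constants, not move
  comparisons, so the learned structure is unchanged).
- Rubin's-rules pooling across imputations is out of scope: the pipeline
  deliberately analyses a single completed dataset, mirroring the
  procedure it re-implements.
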