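---
title: "Estimating binary symptom networks: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating binary symptom networks: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The models

### Cross-sectional: the Ising network

For p binary symptoms coded x ∈ {0,1}^p, the package assumes a pairwise
Markov random field

P(x) ∝ exp( τᵀx + ½ xᵀWx ),

with symmetric zero-diagonal interaction matrix W and thresholds τ. The
{0,1} coding (rather than ±1) is deliberate: under it the full conditionals
are exactly logistic regressions,

P(x_j = 1 | x_{−j}) = logistic( τ_j + Σ_{i≠j} W_ij x_i ),

so the estimator — nodewise ℓ1-penalised logistic regression — targets the
same parameters the generator uses, and parameter recovery is a
like-for-like test.

Estimation (`fit_ising()`): each node is regressed on the other p−1 items
along a log-spaced λ grid descending from λ_max (the smallest penalty that
zeroes every slope, max_j |x_jᵀ(y − ȳ)|/n). Every grid point is scored with
the extended BIC,

EBIC(λ) = −2ℓ + k log n + 2γ k log(p−1),

where k counts active slopes (never the unpenalised intercept) and γ = 0.5
by default — the conventional sparsity/fit compromise for symptom networks.
Ties in EBIC resolve toward larger λ (the sparser model). The two directed
estimates per pair are symmetrised by the **AND rule**: an edge survives
only if both coefficients are nonzero, and its weight is their average; the
OR rule (average with the missing direction as zero) is available. Node
thresholds are the selected intercepts.

### Longitudinal: the cross-lagged panel network

The CLPN fits, for each Wave-2 item j, one lasso logistic regression on all
ten Wave-1 items. Coefficients are taken at **λ_1SE**: ten-fold
cross-validation estimates out-of-sample binomial deviance on the full-data
λ grid; λ_min minimises the mean curve, and λ_1SE is the largest λ whose
mean deviance is within one standard error (SD of fold deviances/√10) of
that minimum. The resulting matrix B is directed: entry (i, j) is the
log-odds effect of item i at Wave 1 on item j at Wave 2, with
autoregressive effects on the diagonal. Out-EI (in-EI) of a node is the
signed sum of its outgoing (incoming) off-diagonal effects; the
autoregressive loop is excluded because these indices quantify influence on
*other* symptoms (a flag restores the loops).

Fold assignment is stratified by the outcome: with ~20% prevalence items
and k = 10, unstratified folds risk a held-out fold with no cases. Folds
are a seeded permutation within each class; a degenerate fold triggers a
logged refold with a derived sub-seed.

### Stability, accuracy, and comparison

* `bootstrap_edges()` / `bootstrap_centrality_diff()` — nonparametric case
  bootstrap; 95% empirical-quantile CIs; two edges (or nodes) "differ" when
  the bootstrap CI of their difference excludes zero.
* `cs_coefficient()` — case-dropping subsampling **without** replacement
  (the convention for correlation-stability analysis): for each drop
  proportion q ≤ 0.75, B subsamples of size n(1−q) are re-estimated and
  their centrality is correlated (Pearson; Spearman optional) with the
  full-sample centrality. CS is the largest q at which r ≥ 0.7 holds with
  ≥ 95% probability; the 0.75 cap is the largest reportable value.
  Benchmarks: below 0.25 unstable, above 0.5 comfortably stable.
* `edge_replicability()` — φ is the Pearson correlation of the two binary
  edge-presence vectors over the 45 unique pairs ("present" means an exact
  nonzero after selection — the lasso/AND pipeline produces exact zeros, so
  no ε threshold is needed); ρ is the Spearman correlation of the weights.
* `invariance_test()` — observed M = max|e₁ − e₂| and ΔS = |S₁ − S₂| with
  S = Σ|W_ij|, against a permutation null. Two schemes: *unpaired* shuffles
  group labels over the pooled rows — the conventional network-comparison
  test, and the default because it is what readers of such analyses expect —
  and *paired* swaps each subject's two rows with probability ½, which is
  the exchangeability-correct null when the two datasets are the same
  subjects at two waves. For same-sample wave comparisons the paired mode
  is statistically preferable and the analysis script reports both.
  p-values use the add-one convention p = (1 + #{perm ≥ obs})/(1 + n_perm),
  so p ∈ [1/(n_perm+1), 1] and the test is never anticonservative at 0.

## Synthetic data and what it does (not) show

`two_wave_preset()` fixes a 10-item ground truth designed to resemble
binary CESD-10 panels from large ageing cohorts: 12 Wave-1 edges with
|W| ∈ [0.5, 1.5] (strongest for hopelessness–lack-of-happiness,
loneliness–inertia, bothered–depressed-mood; one negative edge for sign
coverage), thresholds calibrated so endorsement rates match a realistic
0.20–0.67 band, autoregressive effects in [0.5, 1.2] with restless sleep
the most persistent, and five cross-lagged effects of which four radiate
from a designated "driver" (lack of happiness), giving it the largest true
out-EI by construction.

Calibration is exact rather than simulated: Wave-1 marginals come from full
2^10 enumeration, and thresholds are solved by damped fixed point on the
exact marginals (τ ← τ + 0.9·(logit target − logit current), tolerance
1e−8); Wave-2 intercepts are solved per item by `uniroot` on the exact
Wave-1 distribution. The preset is deterministic given its seed.

`sample_ising_gibbs()` runs one independent chain per observation (fair-coin
starts, full sweeps of the logistic conditionals, compiled, seeded through
R's RNG), so rows are independent draws; because chains are independent,
classical thinning does not apply and `thin` simply adds sweeps after the
default 1000-sweep burn-in. Sampler correctness is validated against exact
enumeration (total-variation distance of the 16-state distribution < 0.02
at 50,000 draws) rather than assumed.

What passing tests do **not** show about real data: the generator draws
Wave-2 items conditionally independently given Wave 1 (the CLPN
likelihood's own implicit assumption; a contemporaneous-dependence option
exists but is off by default), has no covariate heterogeneity, no survey
design effects, and no missingness mechanism beyond the reader's listwise
deletion. Recovery results on the preset therefore validate the estimation
machinery, not the substantive claims one might draw from any particular
cohort.

## Numerical choices

* **Optimizer.** The ℓ1 logistic path is IRLS with cyclic coordinate
  descent on the weighted working response, warm-started along the grid;
  convergence when the largest coefficient change falls below `thresh`
  (1e−9 default) in both the inner sweep and across an IRLS pass. Each λ
  iterates the active set to convergence, then confirms with a full sweep.
  Because all predictors are binary, observations are collapsed onto the
  ≤ 2^p distinct row patterns (sufficient statistics; exact, not an
  approximation), which makes the per-fit cost nearly independent of n.
  The tests verify KKT conditions on the full data at every grid point and
  coefficient agreement with glmnet (~5e−7 on matched grids).
* **Grid.** 100 λ values, λ_min/λ_max = 0.01 by default; both configurable.
  Resampling-heavy internals may use shorter grids (documented per call).
* **No predictor standardisation** by default: the items are binary, so raw
  coefficients are log-odds per endorsement; a `standardize` option mirrors
  common package behaviour.
* **Degenerate inputs.** A constant item cannot be an outcome: the node is
  isolated with a warning and its threshold is the continuity-corrected
  log-odds qlogis((Σy + ½)/(n + 1)). Degenerate bootstrap replicates are
  counted, never dropped. Fully disconnected graphs switch closeness to the
  harmonic variant, flagged in the output.
* **Percentages** are computed at full precision and rounded (2 decimals)
  only in reporting layers.

## Problem sizes used by the validation suite

Chosen to exercise each property at meaningful power on a single core:
sampler fidelity at 50,000 draws; Ising recovery at n = 5000 over 20 seeds
(mean edge sensitivity ≥ 0.9, false-positive rate ≤ 0.1); CLPN recovery at
n = 5000 over 20 replicates (≥ 80% signed recovery of true cross-lagged
effects; driver node first on out-EI in ≥ 90%); type-I calibration of the
permutation M test with 100 simulated same-model pairs (n = 1000/group) at
60 permutations each with a 30-point λ grid — the add-one p-value keeps the
nominal level at 3/61 ≈ 0.049, and the observed rejection rate is required
to fall in [0.01, 0.12]; CS-coefficients with B = 20 subsamples per drop
proportion over the full 0.05–0.75 grid and 20 seeds (structured data at
n = 5000 must reach CS ≥ 0.5, pure noise at n = 200 must stay ≤ 0.25, each
in ≥ 75% of seeds). Production analyses should use the defaults
(B = 1000 bootstraps, 1000 permutations), as `pipeline_defaults()` does.

## Known limitations

* Two waves only; no random-intercept or continuous-time dynamics.
* The Ising stage assumes the binary recode; ordinal/Gaussian graphical
  models on the raw Likert scale are out of scope.
* Closeness/betweenness are reported but flagged exploratory: shortest-path
  metrics are unstable in cross-sectional psychopathology networks.
* The unpaired comparison test treats dependent waves as independent
  groups — retained as the conventional default, with the paired
  alternative provided (see above).
* φ is undefined (reported NA) when either network is edge-complete or
  edge-empty.
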