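---
title: "Methods: strategic slicing and the SLODR criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strategic slicing and the SLODR criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slodr)
```

## The question the package operationalizes

Two structural-equation criteria are commonly used to diagnose Spearman's
law of diminishing returns (SLODR): a negatively skewed latent ability
factor, and a positive correlation between latent ability and
within-individual residual variance. (A third criterion, quadratic factor
loadings, is deliberately out of scope: models including it are
notoriously non-convergent, and this package follows the two-criterion
design.) Both criteria can be driven by a statistical dependency that has
nothing to do with ability differentiation: the correlation between a
person's mean performance across measures (WIM) and their variability
across measures (WISD). The package manipulates that correlation
experimentally — by slicing a sample into stripes of the (WIM, WISD)
plane — and measures how the two criteria respond.

## Pipeline

1. **Preprocessing.** Scores are oriented so higher = better
   (`reverse_scores()` for response times, `times_to_speed()` for running
   events), optionally trimmed at pooled percentiles
   (`percentile_trim()`), restricted to complete cases
   (`complete_cases()`), and standardized per column to mean 0 / sample
   SD 1 (`standardize()`). Standardization happens **once, globally**;
   sliced subsamples are analyzed on the globally standardized scores
   without re-standardization, so a stripe's covariance reflects its
   position in the full sample. Whether within-cell re-standardization
   would be preferable is genuinely open; the global choice keeps the
   cells commensurable and is the one implemented.
2. **Profiles.** `wim_wisd()` computes each person's mean and sample SD
   (denominator p − 1) over the p measures. The denominator is a
   convention choice — the sample SD matches common statistical software
   defaults, and nothing downstream is sensitive to the constant factor.
3. **Slicing.** `slice_cells()` orders persons by a slicing score and
   cuts the ordered list into k contiguous groups whose sizes differ by
   at most one (remainder to the lowest-score groups; ties broken by
   stable input order, so the partition is deterministic).
4. **Per-cell model.** `fit_single_factor()` fits
   `Σ(Λ, θ) = ΛΛᵀ + diag(θ)` by maximum likelihood;
   `factor_scores()` and `predicted_and_residuals()` yield each person's
   latent estimate and mean squared prediction error.
5. **Criteria.** `evaluate_cell()` computes the moment skewness of the
   latent scores with D'Agostino's z-test, the Pearson correlation
   between latent scores and log residual variance with the
   t-approximation p-value, and the significance-and-sign flags;
   `weighted_probability()` aggregates the size-weighted share of cells
   meeting both criteria. `run_sweep()` orchestrates all of it for every
   direction and every k up to `k_max`.

## The slicing geometry

The slicing score is the coordinate along which stripes are stacked:

| direction    | score          | induced within-stripe r(WIM, WISD) |
|--------------|----------------|------------------------------------|
| antidiagonal | `zWIM − zWISD` | positive                           |
| diagonal     | `zWIM + zWISD` | negative                           |
| horizontal   | `zWISD`        | near zero                          |

The sign pattern is geometric, not empirical: conditioning on a narrow
band of the score removes variation along it, leaving within-stripe
covariation perpendicular to it. A band of `zWIM + zWISD` leaves the
(1, −1) direction free, hence negative correlation; a band of
`zWIM − zWISD` leaves (1, 1) free, hence positive; a band of `zWISD`
leaves WIM free while WISD is nearly constant, hence roughly none. The
test suite verifies this on an independent bivariate-normal cloud
(n = 2000, k = 8), where every antidiagonal cell is positive and every
diagonal cell negative.

WIM and WISD are z-scored before the score is formed, because the two
axes have different natural scales; `zscore = FALSE` gives raw-scale
slicing. Cuts are equal-count, not equal-width: "approximately equally
sized subsamples" is taken literally, which also keeps per-cell power
comparable. Both choices should be reported alongside results.

## The factor model and its numerics

On standardized scores, fixing the factor variance at 1 makes Λ directly
the standardized loadings (the first-loading-fixed parameterization is
ML-equivalent; this one reads off the reported metric). The discrepancy

```
F = ln|Σ| + tr(S Σ⁻¹) − ln|S| − p
```

is minimized by BFGS on (Λ, ln θ) with analytic gradients
(`dF/dΣ = Σ⁻¹(Σ − S)Σ⁻¹`), from a principal-axis start plus three
seeded random restarts; convergence tolerance is 1e-8 on F. The log
parameterization keeps θ positive; estimates are floored at θ ≥ 1e-4 and
a solution pinned at that bound is a **Heywood case**, reported as
non-converged rather than hidden (the sweep records such cells with
status `"heywood"` and excludes them from the weighted probability by
default; `count_failures = TRUE` keeps them in the denominator).

* χ² = n · F at the optimum, with S the ML (denominator-n) covariance —
  the convention of the major SEM packages, stated here so external
  cross-checks can align; df = p(p+1)/2 − 2p.
* The independence baseline uses Σ_b = diag(S); NFI, CFI, and RMSEA
  follow their standard formulas, with a just-identified model (p = 3,
  df = 0) reporting RMSEA 0 under an explicit flag.
* The factor sign is fixed by ΣΛ > 0, so higher latent score = better
  performance. The skewness criterion's sign depends on this, so it is
  enforced and covered by a test (negating every input column leaves the
  reported solution unchanged).
* Factor scores use the regression method, `f̂ = Λᵀ Σ̂⁻¹ x`, with the
  model-implied covariance — the default for continuous indicators in
  standard SEM software.
* Residual variance divides by p ("mean squared difference"), not p − 1;
  zero residual variances (possible only for degenerate inputs) are
  floored at 1e-12 before the log, and floor events are counted.

Two behaviors of ML factor analysis are worth knowing. On data with *no*
common factor, the ML solution does not shrink all loadings to zero; it
degenerates onto a single indicator (so does `factanal`). The meaningful
"no common variance" check is that the implied off-diagonal covariances
are tiny, and that is what the test suite asserts. And cells barely above
the minimum size (the sweep skips cells below n = p + `min_cell_margin`,
default p + 5) can produce improper solutions — which is precisely why
skipped and Heywood cells are first-class statuses rather than silent
omissions: attempted = converged + skipped + failed always holds.

## Statistical choices for the criteria

* **Skewness:** moment-based g1 = m₃/m₂^{3/2} with D'Agostino's
  normalizing z-transformation (n ≥ 8). The original analyses do not name
  their skewness test; this one is the standard choice, implemented from
  the published formulas and cross-checked against an independent
  implementation with frozen expected values. Results sensitive to the
  test choice should say so.
* **Correlation:** Pearson between f̂ and ln(residual variance) — the log
  is what makes a linear correlation reasonable for a positive,
  right-skewed quantity; under Spearman (available via
  `corr_method = "spearman"`) the log is immaterial, which the suite
  checks. P-values use the t approximation on n − 2 df; the Spearman
  variant uses mid-ranks for ties.
* **α = .05** for both criteria, with no multiplicity correction — the
  criteria are descriptive flags per cell, not a family of confirmatory
  tests. `evaluate_cell()` is monotone in α.
* **Percentile trimming** pools all trimmed columns into one distribution
  (per-column mode behind a flag), uses the linear-interpolation quantile
  convention, and happens before reversal and complete-case filtering.
  Whether multi-site response-time data should be trimmed per site is
  unknowable from the outside; pooled is the default, and a per-group
  trim can be composed manually by splitting the matrix.

## What the generator emulates — and what it does not

`simulate_scores()` draws

```
a_i ~ N(0, 1)            σ_i = σ0 · exp(c · a_i)
x_ij = λ_j a_i + σ_i ε_ij,   ε_ij ~ N(0, 1)
```

with optional person-level disturbance `x_ij − d_i b_ij`
(`d_i ~ Exp(rate)`, `b_ij ~ U(0,1)`: most persons score near their
level, a minority well below it — the classic negatively skewing
mechanism), optional monotone skewing `y = (e^{βx} − 1)/β` (identity at
β = 0; concave for β < 0, compressing the upper tail like a ceiling),
and optional hard censoring at empirical per-column quantiles (a literal
floor/ceiling). Skewing and censoring are offered separately because
score skewness and floor/ceiling effects are distinct links in the causal
chain from measurement artifact to apparent SLODR. The exponential
disturbance emulates the qualitative mechanism only; no claim of
equivalence to any particular published simulation design is made.

The log-linear coupling `σ_i = σ0 e^{c a_i}` is the simplest mechanism
that keeps σ positive and makes the WIM–WISD correlation monotone in a
single parameter of either sign; c is the only knob the mechanism tests
turn (±0.4). Defaults — n = 2000 persons, p = 10 measures, loadings 0.7,
σ0 = 0.714 (unit column variance at c = 0), c = β = 0, no
censoring/disturbance — describe a neutral, moderately saturated battery
of realistic study size.

What the generator does **not** emulate: multidimensional ability
structure (real batteries are never unifactorial — the single-factor fit
indices on real data are expectedly poor, and that is immaterial to the
slicing argument, but synthetic fits look much cleaner than real ones);
measure-specific reliabilities and scale types; trial-level reaction-time
dynamics; panel structure, inflation, or selection in income data;
repeated participation of the same athlete. Passing tests on synthetic
data therefore show that the pipeline's mechanics and the
slicing-dependence of the criteria are correct, not that any particular
real dataset will show a given effect size.

All simulation draws come from a dedicated, seed-scoped RNG stream: the
global `.Random.seed` is saved and restored, identical configurations
give bit-identical matrices, and the ground truth (a_i, σ_i) travels with
the simulated matrix for recovery tests.

## Problem sizes and determinism

The test suite and acceptance script run at the study sizes the analyses
are designed around: full samples of n = 2000 × p = 10 for the mechanism
checks (20 replicate seeds per coupling sign), a k_max = 10 sweep
(165 cells) for the antagonism property, n = 5000 for loading-recovery
and χ²-calibration checks (200 replicates), and the four-dataset slicing
plan (k_max = 7, 20, 15, 30) for the 2469-cell cardinality. A full sweep
rerun with the same `run_config()` — same input, seed, and toggles —
reproduces its outputs bit-for-bit; `emit_report()` writes the resolved
configuration next to the results so a run documents itself.

## Known limitations

* The decathlon/intelligence/RT/income arms require the corresponding
  source datasets; only the decathlon recipe is fully automated
  (`analyze_decathlon()`), and none of the data ship with the package.
* The single-factor model is fitted unconditionally; no FIML for missing
  data (complete cases only), no multi-factor or bifactor alternatives.
* Heywood-prone tiny cells are excluded rather than regularized; a
  Bayesian or ridge-stabilized fit would retain them at the cost of a
  different estimand.
* The D'Agostino test assumes approximately independent observations
  within a cell; slicing-induced selection makes cells truncated samples,
  which is exactly the point of the exercise but means per-cell p-values
  are descriptive, not confirmatory.
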