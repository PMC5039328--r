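---
title: "Thermal reaction norms: model, fitting, and bootstrap trait inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal reaction norms: model, fitting, and bootstrap trait inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermnorm)
```

## The scientific problem

Phytoplankton growth responds to temperature along a unimodal, left-skewed
thermal performance curve: growth rises slowly with temperature up to an
optimum `T_opt` and collapses quickly above it, crossing zero at the maximum
persistence temperature `T_max`. Experimental-evolution studies ask whether
these curve attributes shift when replicate populations are propagated for
hundreds to thousands of asexual generations under different selection
temperatures, possibly crossed with other global-change drivers such as
seawater pCO₂.

`thermnorm` analyzes the endpoint assay of such an experiment: a factorial
design of 2 selection temperatures (15.0 and 26.3 °C) × 3 pCO₂ levels
(400 / 1100 / 2200 μatm) × 5 replicate populations, each assayed at six
temperatures (15, 18, 22, 24, 26, 27 °C), with specific daily growth rates
μ = (ln N_d − ln N₀)/d measured per batch cycle from cell counts.

## The reaction-norm model

Each replicate's growth–temperature relationship is modelled as

$$f(T) = a\,e^{bT}\left[1 - \left(\frac{T-z}{w/2}\right)^2\right]$$

with four parameters: `w` (> 0) is the thermal niche width — the curve is
positive exactly on `(z − w/2, z + w/2)` — while `z`, `a` (> 0) and `b`
jointly set the location, height and skew of the curve and carry no
individual biological meaning. For `b > 0` the curve is left-skewed:
growth declines faster above the optimum than below it.

Two traits derive from the fitted curve:

* `T_opt`, the maximizer of `f`, found by bounded scalar optimization on
  `[z − w/2, z + w/2]`. Every call is validated against the closed-form
  stationarity condition `b(1 − u²) − (4/w)u = 0`,
  `u = (T − z)/(w/2)`, whose admissible root is
  `u* = 2b / (4/w + sqrt((4/w)² + 4b²))` — a disagreement beyond
  10⁻⁴ °C is an error, not a silent fallback.
* `T_max = z + w/2`, the upper zero, found by bracketed root-finding on
  `(T_opt, z + w/2 + ε]` and validated the same way.

The third trait, `mu_max`, is deliberately *not* read off the fitted curve:
it is the highest growth rate actually measured in the assay, because peak
height is the feature these curve fits estimate least reliably from six
points. Ties are broken toward the lowest qualifying assay temperature so
results are deterministic.

## Censoring no-growth records at 27 °C

The assays cannot measure negative growth: a culture that shrinks is
recorded as rate 0, an overestimate. Whenever a replicate shows no growth
(rate ≤ 0) at 26 *or* 27 °C, the 27 °C record is flagged censored and
excluded from fitting. The OR reading is the default
(`censor_no_growth(mode = "or")`); an AND variant is provided because the
narrower reading — censor only when both temperatures show no growth — is
also defensible. Assay setpoints wander, so records within ±0.5 °C of
26/27 °C (configurable) count as those measurements. Censoring only sets a
flag and writes an audit log; no row is ever silently dropped.

## Fitting

The Gaussian likelihood with constant error variance is maximized per
replicate; its maximizer is the nonlinear least-squares solution, computed
by Levenberg–Marquardt (`minpack.lm::nls.lm`) with an analytic Jacobian.
The residual scale `sigma` is the MLE `sqrt(SSE/n)`.

The surface has local optima, so fits restart from a fixed grid: 5 values
of `z` across the observed temperature range × `w ∈ {10, 20, 30}` °C ×
`b ∈ {0.01, 0.05, 0.1, 0.2}` /°C, with `a` seeded from the highest
observed rate (60 starts). Box constraints keep the search biologically
meaningful: `w ∈ (1, 60)` °C, `a ∈ (10⁻⁶, 10)` /day, `b ∈ (−1, 1)` /°C,
`z` within the observed range ± 20 °C. The best converged sum of squares
wins; exact ties go to the smallest parameter norm. A fit needs at least 5
observations at 4 distinct temperatures; anything less is a hard error
rather than a quietly unstable fit.

## Residual bootstrap

Trait uncertainty per replicate comes from a residual bootstrap (default
1000 iterations): residuals are randomly reassigned across the fitted
values, added back, and the curve is refitted; `T_opt` and `T_max` are
re-derived each time. The default reassignment is a permutation without
replacement; `mode = "resample"` gives classic with-replacement residual
resampling. Both are provided because the two readings of "randomly
reassigned" differ and neither can be ruled out; outputs record the mode.

One correction matters at this sample size. Residuals of a 4-parameter
curve fitted to n = 6 points carry only about `(n − p)/n = 1/3` of the
error variance, so reassigning them raw makes pseudo-data far less noisy
than real data and the resulting intervals strongly anticonservative (we
measure ≈70% coverage at nominal 95%). `residual_bootstrap()` therefore
rescales residuals by `sqrt(n/(n − p))` before reassignment — the standard
variance correction for residual resampling — which restores the
bootstrap spread of `T_opt` to the estimator's true sampling spread.
`inflate = FALSE` gives the uncorrected procedure.

Even corrected, percentile intervals at n = 6 undercover somewhat: in our
simulations (200 units at the cold-selected ambient cell, noise sd
0.05 /day, 400 iterations) the 95% interval for `T_opt` covers the truth
for ≈85% of units. The residual shortfall is estimator bias and skew —
the ML `T_opt` from six points is biased low by ≈0.1 °C with a long left
tail, and equal-tailed percentile intervals correct neither. Bias-corrected
(BCa) or studentized intervals would, but are out of scope here: the
percentile interval is the method this analysis is defined with. Users
should read the per-replicate trait CIs as approximate.

Refits warm-start at the original estimates and fall back to the full
multi-start grid when the warm start fails; iterations whose refit still
fails are dropped and counted, never re-randomized, and a replicate with
more than 5% failures is flagged unreliable. Draws are seeded per
(replicate, iteration) from the master seed, so serial and
parallel-by-replicate execution give identical output.

Intervals are equal-tailed percentile intervals with type-7 (linear
order-statistic interpolation) quantiles, stated explicitly because
quantile conventions differ across software.

## Treatment-effect inference

Each trait is modelled as
`trait ~ selection_high + pco2_std + selection_high:pco2_std`, with the
selection temperature coded 0/1 (15.0 °C reference) and pCO₂ standardized
by subtracting its mean and dividing by **two** standard deviations, so the
continuous coefficient is directly comparable to the binary contrast (the
standardized predictor has mean 0 and SD 0.5 by construction).

For `T_opt` and `T_max` the model is fitted once per bootstrap iteration —
for iteration k, the 30 units' k-th draws form the response — and each
coefficient's 95% CI is the percentile interval of its draws. Iterations
where any unit's refit failed are skipped listwise so every fitted model
sees the complete design. A coefficient is significant when its interval
excludes zero. When the interaction is significant, the main effects are
still reported but flagged non-interpretable: with a significant
interaction, "the" main effect of either factor is not a meaningful
quantity. Under an all-null simulation this CI-exclusion rule holds its
nominal rate (measured 5–6% per treatment coefficient).

`mu_max` has no bootstrap distribution (it is a measured value, not a
curve-derived one), so its model is fitted once and its CIs are
normal-theory t-intervals on n − 4 degrees of freedom. The adjusted R²
reported for every trait comes from the single model on point-estimate
traits, not from bootstrap averages.

Treatment-cell summaries mirror the same logic: cell means of `T_opt` and
`T_max` get percentile CIs of per-iteration cell means; `mu_max` cell
means get t-intervals across the 5 replicates.

## The synthetic-data generator

`reference_scenario()` encodes the treatment structure this analysis is
built to detect, as planted trait values per cell:

| cell | T_opt (°C) | T_max (°C) | peak μ (/day) |
|---|---|---|---|
| cold-selected, 400 μatm | 21.3 | 28.0 | 1.15 |
| cold-selected, 1100 μatm | 21.3 | 27.0 | 1.07 |
| cold-selected, 2200 μatm | 21.3 | 26.0 | 0.95 |
| warm-selected, any pCO₂ | 22.0 | 28.7 | 1.10 → 1.01 |

i.e. a 0.7 °C optimum shift under warm selection; `T_max` flat under warm
selection but dropping 1 and 2 °C at elevated pCO₂ under cold selection;
peak growth declining with pCO₂ roughly twice as steeply under cold
selection (0.2 vs 0.09 /day across the pCO₂ range). The exponential shape
is fixed at `b = 0.1` /°C and `(z, w, a)` are solved exactly from the
planted traits (`rn_params_for_traits()`; note the identity
`T_max − T_opt < 1/b` bounds which trait combinations exist).

The observation model matches the fitting assumptions on purpose: Gaussian
noise (sd 0.05 /day) on the rate scale, small between-replicate jitter
(sd 0.1 °C on `z`, 2% multiplicative on `a` — chosen once to mimic the
visual within-treatment spread of such assays), and truncation of negative
observed rates to zero, reproducing the measurement floor. What passing
tests on these data show is that the *analysis chain* is correct and has
the claimed operating characteristics; they do not show that real growth
data satisfy homoscedastic Gaussian noise, nor validate the curve family
itself against alternatives (Sharpe–Schoolfield and similar forms are
deliberately out of scope).

## Numerical and design choices

* Curve fits use analytic Jacobians; convergence is the Levenberg–Marquardt
  information code, and non-converged starts never win silently.
* `T_opt`/`T_max` are always cross-checked against their closed forms at
  10⁻⁴ °C; a failed check raises an error.
* Zero rates (other than censored 27 °C records) are retained in fits —
  they are real observations of no growth.
* Duplicate (replicate, assay temperature) records are schema errors;
  deliberate replicate measurements at one temperature enter as separate
  rows only through the fitting interface, where they act as weights.
* Tables written by `write_assay_table()` print doubles with 17 significant
  digits and are re-read with the base parser, so disk round trips are
  bit-exact.
* Simulation sizes used in the shipped test suite: 200 units for bootstrap
  coverage (400 iterations each), 50 simulated experiments for power
  (200 iterations each), 1000 repeats for the null-rate check. These are
  the package's chosen problem sizes for routine verification; the
  pipeline default remains 1000 iterations.

## Worked example

```{r example, eval = FALSE}
scenario <- reference_scenario()
res <- run_full_pipeline(scenario = scenario,
                         config = pipeline_config(seed = 1, n_iter = 1000),
                         outdir = "results")
res$effects$t_opt          # selection shifts T_opt; pCO2 does not
res$effects$t_max          # interaction: pCO2 lowers T_max only under cold selection
res$effects$mu_max         # pCO2 lowers peak growth, more under cold selection
res$treatment_summary      # cell means with 95% intervals
plot_reaction_norms(res$data, res$fits)
```

## Known limitations

* Six assay temperatures weakly constrain four curve parameters: expect
  wide, left-skewed `T_opt` uncertainty per replicate and the ≈85%
  effective coverage discussed above. Treatment-level inference, which
  pools 30 units, is much better behaved.
* The niche width `w` is estimated but should not be interpreted from this
  assay design: there are no observations near the lower thermal limit.
* `T_max` beyond 27 °C is an extrapolation of the fitted form.
* The censoring rule's OR/AND ambiguity can matter for replicates growing
  at 27 °C but not 26 °C; both modes are exposed and logged.
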