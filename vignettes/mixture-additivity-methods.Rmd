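---
title: "Methods: concentration-addition analysis of binary mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concentration-addition analysis of binary mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planmix)
```

## Scope

planmix analyses multi-readout concentration-response screens of binary
chemical mixtures against the Loewe concentration-addition (CA) null
model. It covers five stages: (1) a synthetic screen generator with known
ground truth, (2) benchmark-concentration (BMC) estimation with bootstrap
uncertainty, (3) closed-form CA predictions for mixtures, (4) interval-based
interaction classification, and (5) a logit-equivalence slope test of
additivity for enzyme-inhibition curves. This vignette states the models,
the defaults and their rationale, and what the package deliberately does
not attempt.

## The concentration-addition null model

Two agents with individual benchmark concentrations $B_1$ and $B_2$ (the
concentrations producing a fixed benchmark response) are concentration
additive when every mixture $(C_1, C_2)$ reaching that response satisfies
the isobole equation

$$\frac{C_1}{B_1} + \frac{C_2}{B_2} = 1 .$$

For an equimolar mixture ($C_1 = C_2 = C$) the per-component mixture BMC
follows in closed form as the halved harmonic mean,

$$B_\mathrm{mix} = \left(\frac{1}{B_1} + \frac{1}{B_2}\right)^{-1}
               = \frac{B_1}{1 + \mathrm{RPF}_2}, \qquad
  \mathrm{RPF}_2 = \frac{B_1}{B_2},$$

and for a mixture at fixed molar fractions $f_1 + f_2 = 1$ of the total
concentration $C_T$,

$$C_T = \left(\frac{f_1}{B_1} + \frac{f_2}{B_2}\right)^{-1}.$$

`predict_mixture_bmc()` and `predict_mixture_icp()` implement these forms;
the unit and acceptance suites verify them against brute-force numeric
solves of the isobole over $10^4$ random inputs to $10^{-6}$ relative
error. Two conventions matter:

* **Inactive components.** If one agent never reaches the benchmark
  response, its BMC is treated as infinite and the prediction collapses to
  the active agent's BMC (the mixture well still contains the active agent
  at its nominal per-component concentration).
* **Tested-range cap.** Predictions above the highest tested per-component
  concentration (default 10 µM) cannot be observed and are reported as
  capped/inactive rather than extrapolated.

## BMC estimation

`estimate_bmc()` follows a bootstrap crossing scheme. Raw per-animal
records are normalized by `normalize_responses()`: incidence readouts
become percent incidence; continuous readouts become percent change from
the in-plate control mean, split into a "+" (increase) and a "−"
(decrease) series so each can be compared with its own benchmark response
(BMR). Animals scored dead are excluded from all other readouts at that
concentration. Each bootstrap iteration resamples animals within each
concentration (binomially for incidence, by index for continuous values
including control wells), optionally monotonizes the response profile by
pool-adjacent-violators (`stats::isoreg`), and records the first BMR
crossing, interpolated linearly in $\log_{10}$ concentration. The estimate
is the median of the crossing distribution with a 5th–95th percentile
interval; `hit_confidence` is the fraction of iterations with a finite
crossing, and a series is called active when it is at least 0.5.

Defaults: `n_boot = 1000` for reported analyses (the acceptance studies
use 200 to keep the 50-seed design tractable at desk scale — a package
choice about problem size, not a statistical necessity; the intervals are
nearly identical), benchmark responses from the packaged `load_bmr_table()`
fixture.

## Interaction classification

`classify_interaction()` compares the observed mixture BMC interval with
the CA-predicted interval (obtained by pushing the single-agent interval
bounds through the prediction formula, or by combining bootstrap samples):
overlap → additive; observed entirely below → synergistic (mixture more
potent than predicted); entirely above → antagonistic. When only one side
is active the call follows the active side (observed-only → synergistic,
predicted-only → antagonistic); both inactive → no_effect. Intervals
spanning the whole tested range are quality-flagged. `potency_summary()`
aggregates to the per-mixture minimum BMC across readouts and reports
$\log_{10}(\mathrm{predicted}/\mathrm{experimental})$, the headline
potency-agreement metric.

## Logit-equivalence slope test

For enzyme-inhibition curves, a fixed-asymptote log-logistic curve
$I(C) = 100\,(1 + (IC_{50}/C)^h)^{-1}$ is linear on the log-logit scale:
$\ln\!\frac{I}{100 - I} = h \ln 10 \,(\log_{10} C - \log_{10} IC_{50})$.
`fit_logit_line()` fits this line (inhibition clipped to [0.5, 99.5]% so
extremes stay finite); `expected_inhibition()` converts one agent's dose
into the other's equivalents, sums, and evaluates the second line — the CA
expectation. `slope_test()` regresses observed on expected logit
inhibition (per-concentration medians by default) and t-tests the slope
against 1. A numerically perfect fit reports the slope with p = 1 rather
than a spurious rejection. Calibration is part of the acceptance suite:
with logit noise of SD 0.1 the type-I error at $\alpha = 0.05$ lies in
[0.03, 0.07] over 1000 simulations.

## Synthetic screen generator

`simulate_single_agent()` / `simulate_mixture()` emulate a plate-based
behavioral screen: 48-well plates with 8 solvent controls and five
semi-log concentrations (0.1–10 µM) × 8 animals, three replicate plates
(n = 24). Per-readout truth is a log-logistic effect curve; incidence
readouts draw Bernoulli outcomes, continuous readouts draw Gaussian noise
around the scaled baseline, and lethality masks all other readouts of a
dead animal. Mixtures are simulated by solving the effect-level isobole by
bisection (tolerance $10^{-9}$); `interaction_truth("potency_shift")`
divides the targeted EC50s by a shift factor to plant a known synergy.

What it emulates: the design geometry, normalization pathway, dominant
noise sources (binomial counting, animal loss, plate-level control
estimation). What it does not: real behavioral time series, video
tracking, inter-animal heterogeneity beyond the noise model, day-7 versus
day-12 kinetics, or chemistry. The noise defaults (`noise_sd_continuous =
0.05`) are calibrated so that acceptance properties pass at desk scale and
are explicitly non-biological.

## Numerical choices

* Log-logistic fits run on $(\log IC_{50}, \log h)$ via
  `minpack.lm::nlsLM` with a 5-point multi-start; asymptotes are fixed at
  0/100, matching normalized percent-activity data. Fits whose optimum
  leaves the plausible region fail softly (`converged = FALSE`).
* BMR crossings interpolate linearly in $\log_{10} C$; a response already
  above the BMR at the lowest tested concentration reports that
  concentration (a censoring convention, flagged by the interval hitting
  the range boundary).
* Predicted mixture curves offer a fast logit-linear grid interpolation
  (exact at the grid nodes, and everywhere when Hill slopes are equal) and
  an exact per-concentration isobole solve; both agree at the 50% level by
  construction.

## What the tests do not compute

No test or script reproduces live-animal results: the experimental BMC
heatmaps, measured IC50 values, or measured mixture inhibition curves
exist in the package only as verbatim fixtures (`load_bmc_min_table()`,
`load_ic50_table()`, `load_cpo_malo_params()`), checksum-pinned and never
refit. All empirical claims checked by the test suite are either (a)
arithmetic recomputations from those printed tables or (b) properties of
synthetic data with known ground truth.

## Limitations

* The CA machinery is strictly binary; extending the isobole forms to k
  components is algebraically direct but unimplemented.
* Interval classification inherits the bootstrap's percentile coverage;
  with very low noise the intervals can be narrower than systematic
  interpolation bias, inflating non-additive calls (the reason the
  generator's default noise is not set lower).
* The logit-equivalence test assumes parallel single-agent lines (equal
  Hill slopes) for its expectation to be exactly CA-consistent; unequal
  slopes make it an approximation, as in the practice it mirrors.
* Censored potencies (an agent inactive up to its solubility/test limit)
  are carried as censored values, never imputed.
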