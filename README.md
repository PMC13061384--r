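# planmix

Concentration-addition analysis of binary chemical mixtures in
multi-readout planarian-style screens.

## The problem

High-throughput behavioral screens expose animals to single agents and to
binary mixtures across a shared concentration series, scoring many
readouts per animal (lethality, stickiness, locomotion, and so on). The
scientific question for each mixture × readout is whether the mixture
behaves as predicted from its components alone, or is more potent
(synergistic) or less potent (antagonistic) than predicted. planmix
implements the full pipeline around the Loewe concentration-addition (CA)
null model:

* **BMC estimation** — for each condition × readout, a benchmark
  concentration (BMC): the concentration producing a readout-specific
  benchmark response (BMR), estimated by a bootstrap over animals with the
  first BMR crossing interpolated in log₁₀ concentration, yielding a
  median and 5th–95th percentile interval.
* **CA prediction** — for agents with BMCs *B₁*, *B₂*, an additive
  equimolar mixture satisfies the isobole *C/B₁ + C/B₂ = 1*, giving the
  per-component mixture BMC in closed form:
  *B*<sub>mix</sub> = (1/*B₁* + 1/*B₂*)⁻¹, with an inactive-component rule
  (infinite BMC ⇒ prediction equals the active BMC) and a tested-range
  cap. General mixing fractions *f₁*, *f₂* use
  *C*<sub>T</sub> = (*f₁*/*B₁* + *f₂*/*B₂*)⁻¹.
* **Interaction calls** — observed vs predicted interval comparison:
  overlap ⇒ additive, observed below ⇒ synergistic, above ⇒ antagonistic.
* **Dose-response and logit equivalence** — fixed-asymptote log-logistic
  fits (IC50, Hill) for enzyme-inhibition curves, and a slope test of
  observed vs CA-expected logit inhibition (H₀: slope = 1) for testing
  additivity of inhibition curves.
* **Synthetic screens** — a plate-based generator with known ground truth
  (including planted synergies) so every stage is testable without
  experimental data.

## Worked example

Simulate a single-agent screen, estimate BMCs, and form a CA prediction:

```r
library(planmix)

truth <- agent_truth(
  name = "P",
  ec50 = c(stickiness = 0.5, speed_dark = 2),
  hill = c(stickiness = 1.5, speed_dark = 1.2),
  max_effect = c(stickiness = 100, speed_dark = 80),
  direction = c(stickiness = "+", speed_dark = "-"),
  is_incidence = c(stickiness = TRUE, speed_dark = FALSE))
design <- screen_design(worm_types = "regenerating", days = 12, seed = 11L)
records <- simulate_single_agent(truth, design)

bmr <- load_bmr_table()
bmr <- bmr[bmr$worm_type == "regenerating" & bmr$day == 12 &
             bmr$readout %in% c("stickiness", "speed_dark"), ]
bmcs <- estimate_bmcs(records, bmr, n_boot = 500, seed = 1L)
bmcs[bmcs$active, c("readout", "direction", "bmr", "bmc_median", "bmc_lb", "bmc_ub")]
#>      readout direction bmr bmc_median    bmc_lb    bmc_ub
#> 1 speed_dark         -  45  2.7236121 2.5589122 2.9399967
#> 3 stickiness         +  50  0.3828887 0.2508393 0.4867483
```

Predict an equimolar mixture BMC from two single-agent BMCs (0.0050 and
0.056 µM):

```r
predict_mixture_bmc(0.0050, 0.056)
#> CA prediction: 0.00459 uM per component (0.00918 uM total)
```

Fit a log-logistic inhibition curve:

```r
conc <- 10^seq(-2, 1, 0.5)
fit_log_logistic(data.frame(
  concentration_uM = conc,
  percent_activity = 100 / (1 + (conc / 0.27)^1.1)))
#> log-logistic fit (asymptotes 0/100): IC50 = 0.27 uM (SE 0), Hill = 1.1 (SE 0), n = 7, residual SD = 0%
```

## Analysis workflow

`analysis/` holds numbered drivers that run the whole study into
`results/`:

```sh
Rscript analysis/01_simulate_screen.R    # synthetic screen with a planted synergy
Rscript analysis/02_estimate_bmcs.R      # normalization + bootstrap BMCs
Rscript analysis/03_predict_classify.R   # CA predictions + interaction calls
Rscript analysis/04_table_replication.R  # replicate the published potency-ratio table
Rscript analysis/05_ache_additivity.R    # enzyme-inhibition arm + slope test
```

Stage 3 recovers the planted truth: the sham mixture's stickiness series
is called synergistic, every other active series additive.

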