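# Shared ground truths built on readouts from the packaged benchmark table
# (regenerating, day 12: lethality BMR 15, stickiness 50, speed_dark -45/+45,
# resting_dark +50/-55), so simulated screens flow through the whole
# pipeline unchanged.

test_readouts <- c("lethality", "stickiness", "speed_dark", "resting_dark")

make_truth <- function(name = "A",
                       ec50 = c(lethality = 3.16, stickiness = 0.5,
                                speed_dark = 2, resting_dark = 1.5),
                       hill = c(lethality = 2, stickiness = 1.5,
                                speed_dark = 1.2, resting_dark = 1),
                       max_effect = c(lethality = 100, stickiness = 100,
                                      speed_dark = 80, resting_dark = 90),
                       ache_ic50 = 1, ache_hill = 1.2) {
  agent_truth(name, ec50 = ec50, hill = hill, max_effect = max_effect,
              direction = c(lethality = "+", stickiness = "+",
                            speed_dark = "-", resting_dark = "+"),
              is_incidence = c(lethality = TRUE, stickiness = TRUE,
                               speed_dark = FALSE, resting_dark = FALSE),
              ache_ic50 = ache_ic50, ache_hill = ache_hill)
}

make_design <- function(seed = 1L, noise_sd_continuous = 0.05, ...) {
  screen_design(worm_types = "regenerating", days = 12,
                noise_sd_continuous = noise_sd_continuous, seed = seed, ...)
}

# BMR rows for the test readouts (regenerating, day 12)
test_bmr_table <- function() {
  bmr <- load_bmr_table()
  bmr[bmr$readout %in% test_readouts & bmr$worm_type == "regenerating" &
        bmr$day == 12, ]
}

# noiseless log-logistic activity data
make_activity <- function(ic50, hill, conc = 10^seq(-1.75, 1.75, by = 0.5),
                          replicates = 1) {
  data.frame(concentration_uM = rep(conc, each = replicates),
             percent_activity = rep(100 / (1 + (conc / ic50)^hill),
                                    each = replicates))
}

# half of the last printed decimal place of a number: the rounding radius
# of a value reproduced from a printed table
half_ulp <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(NA_real_)
    for (d in 0:6) if (isTRUE(all.equal(round(v, d), v, tolerance = 1e-12)))
      return(0.5 * 10^(-d))
    0.5e-6
  }, 0)
}
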