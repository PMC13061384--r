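# small hand-built screen: one plate, 8 controls + 8 animals per conc
toy_records <- function(readout, is_incidence, values_by_conc, control_values,
                        direction = "+") {
  concs <- as.numeric(names(values_by_conc))
  rows <- data.frame(
    condition = "X",
    concentration_uM = c(rep(0, length(control_values)),
                         rep(concs, lengths(values_by_conc))),
    worm_type = "regenerating", day = 12, plate_id = "p1",
    well_id = seq_len(length(control_values) + sum(lengths(values_by_conc))),
    readout = readout, direction = direction,
    value = c(control_values, unlist(values_by_conc, use.names = FALSE)),
    is_incidence = is_incidence, stringsAsFactors = FALSE)
  rows
}

test_that("incidence and percent-change normalization count correctly", {
  # 12 of 24 animals stuck -> 50% incidence
  inc <- toy_records("stickiness", TRUE,
                     list(`1` = rep(c(0, 1), 12)), rep(0, 8))
  s <- normalize_responses(inc)
  expect_equal(s$response[s$concentration_uM == 1], 50)
  # control mean 1.0, treated mean 0.4 -> -60%, i.e. magnitude 60 on the
  # "-" series and 0 on the "+" series
  cont <- toy_records("speed_dark", FALSE, list(`1` = rep(0.4, 8)), rep(1, 8))
  s <- normalize_responses(cont)
  expect_equal(s$response[s$direction == "-"], 60)
  expect_equal(s$response[s$direction == "+"], 0)
})

test_that("missing controls and zero control means are handled", {
  no_ctrl <- toy_records("speed_dark", FALSE, list(`1` = rep(0.4, 8)),
                         numeric(0))
  expect_error(normalize_responses(no_ctrl), "controls")
  zero_ctrl <- toy_records("speed_dark", FALSE, list(`1` = rep(0.4, 8)),
                           rep(0, 8))
  s <- normalize_responses(zero_ctrl)
  expect_false(any(s$usable))
  expect_true(all(is.na(s$response)))
})

test_that("the BMR crossing interpolates in log10 concentration", {
  conc <- c(0.1, 0.316, 1, 3.16, 10)
  # hand interpolation between 1 and 3.16 uM at BMR 50:
  # 10^(0 + (50-30)/(70-30) * log10(3.16)) = 1.7776
  expect_equal(bmr_crossing(conc, c(0, 10, 30, 70, 90), 50),
               10^(0.5 * log10(3.16)), tolerance = 1e-12)
  # response never reaches the BMR
  expect_true(is.na(bmr_crossing(conc, c(0, 5, 10, 15, 20), 50)))
  # response exactly equal to the BMR at a tested concentration
  expect_equal(bmr_crossing(conc, c(0, 10, 50, 70, 90), 50), 1)
  # already above the BMR at the lowest tested concentration
  expect_equal(bmr_crossing(conc, c(60, 70, 80, 90, 95), 50), 0.1)
})

test_that("bootstrap BMC estimation is seed-deterministic", {
  rec <- simulate_single_agent(make_truth(), make_design(seed = 2))
  bmr <- list(readout = "stickiness", worm_type = "regenerating", day = 12,
              direction = "+", bmr = 50)
  e1 <- estimate_bmc(rec, bmr, n_boot = 200, seed = 10)
  e2 <- estimate_bmc(rec, bmr, n_boot = 200, seed = 10)
  expect_identical(e1$samples, e2$samples)
  expect_identical(e1$bmc_median, e2$bmc_median)
  e3 <- estimate_bmc(rec, bmr, n_boot = 200, seed = 11)
  expect_false(identical(e1$samples, e3$samples))
})

test_that("active estimates have ordered limits inside the tested range", {
  bmr <- list(readout = "stickiness", worm_type = "regenerating", day = 12,
              direction = "+", bmr = 50)
  for (s in 1:15) {
    rec <- simulate_single_agent(make_truth(), make_design(seed = 100 + s))
    est <- estimate_bmc(rec, bmr, n_boot = 200, seed = s)
    if (est$active) {
      expect_true(est$bmc_lb <= est$bmc_median)
      expect_true(est$bmc_median <= est$bmc_ub)
      expect_true(est$bmc_median >= est$min_conc - 1e-12)
      expect_true(est$bmc_median <= est$max_conc + 1e-12)
    }
  }
})

test_that("responses that never reach the BMR give an inactive estimate", {
  # all-zero responses: degenerate, hit confidence exactly 0
  rec <- toy_records("stickiness", TRUE,
                     setNames(replicate(5, rep(0, 24), simplify = FALSE),
                              c(0.1, 0.316, 1, 3.16, 10)),
                     rep(0, 8))
  bmr <- list(readout = "stickiness", worm_type = "regenerating", day = 12,
              direction = "+", bmr = 50)
  est <- estimate_bmc(rec, bmr, n_boot = 200, seed = 1)
  expect_false(est$active)
  expect_equal(est$hit_confidence, 0)
  # max response ~17% with BMR 50: inactive, essentially never crossing
  rec2 <- toy_records("stickiness", TRUE,
                      setNames(lapply(c(0, 0, 1, 2, 4), function(k)
                        rep(c(1, 0), c(k, 24 - k))),
                        c(0.1, 0.316, 1, 3.16, 10)),
                      rep(0, 8))
  est2 <- estimate_bmc(rec2, bmr, n_boot = 200, seed = 1)
  expect_false(est2$active)
  expect_lt(est2$hit_confidence, 0.05)
})

test_that("a tenfold potency change moves the median BMC tenfold", {
  bmr <- list(readout = "resting_dark", worm_type = "regenerating", day = 12,
              direction = "+", bmr = 50)
  des <- make_design(seed = 3, noise_sd_continuous = 0,
                     concentrations = signif(10^seq(-2, 1.5, 0.5), 3))
  ec50 <- c(lethality = 100, stickiness = 0.5, speed_dark = 2,
            resting_dark = 0.3)
  rec1 <- simulate_single_agent(make_truth(ec50 = ec50), des)
  ec50_10 <- ec50; ec50_10["resting_dark"] <- 3
  rec10 <- simulate_single_agent(make_truth(ec50 = ec50_10), des)
  b1 <- estimate_bmc(rec1, bmr, n_boot = 100, seed = 1)
  b10 <- estimate_bmc(rec10, bmr, n_boot = 100, seed = 1)
  ratio <- b10$bmc_median / b1$bmc_median
  expect_gt(ratio, 7.5)
  expect_lt(ratio, 12.5)
})

test_that("animals scored dead are excluded from behavioral summaries", {
  tr <- make_truth(ec50 = c(lethality = 0.5, stickiness = 0.5,
                            speed_dark = 2, resting_dark = 1.5))
  rec <- simulate_single_agent(tr, make_design(seed = 6))
  dead <- rec$readout == "lethality" & rec$value == 1
  expect_gt(sum(dead), 0)
  s <- normalize_responses(rec)
  n_top <- s$n[s$readout == "speed_dark" & s$direction == "-" &
                 s$concentration_uM == 10][1]
  expect_lt(n_top, 24)  # survivors only
  # lethality itself keeps the full head count
  n_leth <- s$n[s$readout == "lethality" & s$concentration_uM == 10][1]
  expect_equal(n_leth, 24)
})
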