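test_that("relative potency is the plain potency ratio", {
  expect_equal(relative_potency(1.0, 0.5), 2.0)
  expect_equal(relative_potency(0.3, 0.3), 1.0)
  # day-12 AChE IC50s, regenerating: CPF 0.27, DZN 0.056
  ic50 <- load_ic50_table()
  cpf <- ic50$ic50_uM[ic50$op == "CPF" & ic50$worm_type == "regenerating"]
  dzn <- ic50$ic50_uM[ic50$op == "DZN" & ic50$worm_type == "regenerating"]
  expect_equal(relative_potency(cpf, dzn), 4.821, tolerance = 1e-3)
  expect_error(relative_potency(0, 1))
  expect_error(relative_potency(1, Inf))
})

test_that("equimolar mixture BMC follows the harmonic form and the inactive rule", {
  # sham combination: equal BMCs B give B/2 per component
  p <- predict_mixture_bmc(0.6, 0.6)
  expect_equal(p$bmc_mix_per_component, 0.3)
  expect_equal(p$bmc_mix_total, 0.6)
  expect_equal(p$rpf2, 1)
  # day-12 regenerating DDVP (0.0050) + DZN (0.056)
  p2 <- predict_mixture_bmc(0.0050, 0.056)
  expect_equal(p2$bmc_mix_per_component, 0.004590, tolerance = 1e-4)
  # independent check: numeric solve of C/B1 + C/B2 = 1 at C1 = C2 = C
  num <- uniroot(function(cc) cc / 0.0050 + cc / 0.056 - 1,
                 c(1e-6, 0.0050), tol = 1e-12)$root
  expect_equal(p2$bmc_mix_per_component, num, tolerance = 1e-9)
  # inactive component: prediction equals the active BMC
  p3 <- predict_mixture_bmc(0.3, NA)
  expect_equal(p3$bmc_mix_per_component, 0.3)
  expect_true(is.na(p3$rpf2))
  # both inactive -> inactive prediction
  expect_false(predict_mixture_bmc(NA, Inf)$active)
  # prediction above the 10 uM cap is suppressed
  p4 <- predict_mixture_bmc(30, 30)
  expect_true(p4$capped)
  expect_false(p4$active)
  expect_error(predict_mixture_bmc(-1, 2))
})

test_that("prediction respects swap symmetry and the harmonic bounds", {
  withr::with_seed(42, {
    for (i in 1:200) {
      b <- 10^runif(2, -3, 2)
      p12 <- predict_mixture_bmc(b[1], b[2], cap = Inf)
      p21 <- predict_mixture_bmc(b[2], b[1], cap = Inf)
      expect_equal(p12$bmc_mix_per_component, p21$bmc_mix_per_component)
      expect_true(p12$bmc_mix_per_component <= min(b) + 1e-12)
      expect_true(p12$bmc_mix_per_component >= min(b) / 2 - 1e-12)
    }
  })
})

test_that("closed forms agree with the numeric isobole solve", {
  withr::with_seed(77, {
    b1 <- 10^runif(1000, -3, 2); b2 <- 10^runif(1000, -3, 2)
    f1 <- runif(1000, 0.01, 0.99)
  })
  # equimolar per-component closed form vs numeric root of the isobole
  closed <- 1 / (1 / b1 + 1 / b2)
  num <- vapply(seq_along(b1), function(i)
    uniroot(function(cc) cc / b1[i] + cc / b2[i] - 1,
            c(1e-12, min(b1[i], b2[i])), tol = 1e-13)$root, 0)
  expect_lt(max(abs(closed / num - 1)), 1e-6)
  # RPF form equals the harmonic form
  expect_equal(b1 / (1 + b1 / b2), closed, tolerance = 1e-12)
  # total-mixture form with fractions vs numeric solve
  closed4 <- 1 / (f1 / b1 + (1 - f1) / b2)
  num4 <- vapply(seq_along(b1), function(i)
    uniroot(function(ct) f1[i] * ct / b1[i] + (1 - f1[i]) * ct / b2[i] - 1,
            c(1e-12, 1e6), tol = 1e-13)$root, 0)
  expect_lt(max(abs(closed4 / num4 - 1)), 1e-6)
})

test_that("interval propagation pushes bounds through the formula", {
  est <- function(m, lb, ub, active = TRUE)
    list(bmc_median = m, bmc_lb = lb, bmc_ub = ub, active = active)
  # degenerate intervals [B,B] x [B,B] -> [B/2, B/2]
  p <- predict_interval(est(1, 1, 1), est(1, 1, 1))
  expect_equal(c(p$interval_lb, p$interval_ub), c(0.5, 0.5))
  # [1,2] and [2,4] -> [2/3, 4/3]
  p2 <- predict_interval(est(1.5, 1, 2), est(3, 2, 4))
  expect_equal(c(p2$interval_lb, p2$interval_ub), c(2 / 3, 4 / 3))
  expect_true(p2$interval_lb <= p2$bmc_mix_per_component)
  expect_true(p2$interval_ub >= p2$bmc_mix_per_component)
  # one inactive component: interval equals the active component's interval
  p3 <- predict_interval(est(NA, NA, NA, active = FALSE), est(3, 2, 4))
  expect_equal(c(p3$interval_lb, p3$interval_ub), c(2, 4))
  expect_error(predict_interval(est(1.5, 2, 1), est(3, 2, 4)), "inverted")
  expect_error(predict_interval(est(NA, NA, NA, FALSE),
                                est(NA, NA, NA, FALSE)))
})

test_that("bootstrap interval propagation uses the combined samples", {
  est <- function(m, samples) list(bmc_median = m, bmc_lb = min(samples),
                                   bmc_ub = max(samples), active = TRUE,
                                   samples = samples)
  s1 <- rep(2, 100); s2 <- rep(2, 100)
  p <- predict_interval(est(2, s1), est(2, s2), method = "bootstrap")
  expect_equal(c(p$interval_lb, p$interval_ub), c(1, 1))
})

test_that("effect-level mixture predictions follow the fraction-weighted form", {
  fitA <- list(ic50 = 1, hill = 1.3, converged = TRUE)
  fitB <- list(ic50 = 13.6, hill = 1.3, converged = TRUE)
  # self-mixture at any fractions returns the single-agent ICp
  self <- predict_mixture_icp(fitA, fitA, f1 = 0.3, p = c(10, 50, 90))
  expect_equal(self, effect_level(fitA, c(10, 50, 90))$icp, tolerance = 1e-12)
  # oxon mixture at the stated constant ratio 0.007 = [CPO]/[MALO]
  f1 <- 0.007 / 1.007
  pred <- predict_mixture_icp(fitA, fitB, f1 = f1, p = 50)
  expect_equal(pred, 12.5047, tolerance = 1e-4)
  # independent 50% isobole solve at that ratio
  num <- uniroot(function(ct) f1 * ct / 1 + (1 - f1) * ct / 13.6 - 1,
                 c(1, 14), tol = 1e-12)$root
  expect_equal(pred, num, tolerance = 1e-9)
  # equal fractions, IC50s 1 and 3: total 1.5 = 2 x per-component 0.75
  fit3 <- list(ic50 = 3, hill = 1.3, converged = TRUE)
  expect_equal(predict_mixture_icp(fitA, fit3, 0.5, 50), 1.5,
               tolerance = 1e-12)
  expect_equal(predict_mixture_icp(fitA, fit3, 0.5, 50),
               2 * predict_mixture_bmc(1, 3)$bmc_mix_per_component,
               tolerance = 1e-15)
  expect_error(predict_mixture_icp(fitA, fitB, f1 = 0.5, p = 101))
  expect_error(predict_mixture_icp(fitA, fitB, f1 = 1.2, p = 50))
})

test_that("predicted mixture curves are monotone and method-consistent", {
  fitA <- list(ic50 = 0.8, hill = 2, converged = TRUE)
  # identical components: curve equals the single-agent curve
  cv <- predicted_curve(fitA, fitA, f1 = 0.5)
  expect_equal(cv$conc_total, effect_level(fitA, cv$p)$icp, tolerance = 1e-12)
  expect_true(all(diff(cv$conc_total) > 0))
  # equal Hill slopes: grid interpolation and dense isobole solve agree
  # inside the tabulated concentration range (outside it the grid clamps)
  fitB <- list(ic50 = 5, hill = 2, converged = TRUE)
  cvB <- predicted_curve(fitA, fitB, 0.5)
  grid <- attr(cvB, "interpolate")
  dense <- attr(predicted_curve(fitA, fitB, 0.5, method = "isobole"),
                "interpolate")
  inside <- function(cv) 10^seq(log10(min(cv$conc_total)) + 0.01,
                                log10(max(cv$conc_total)) - 0.01,
                                length.out = 25)
  cc <- inside(cvB)
  expect_lt(max(abs(grid(cc) - dense(cc))), 1e-6)
  # unequal Hill slopes (1 vs 3): exact agreement at p = 50, bounded
  # differences elsewhere
  fitC <- list(ic50 = 0.8, hill = 1, converged = TRUE)
  fitD <- list(ic50 = 5, hill = 3, converged = TRUE)
  ic50mix <- predict_mixture_icp(fitC, fitD, 0.5, 50)
  cvCD <- predicted_curve(fitC, fitD, 0.5)
  g2 <- attr(cvCD, "interpolate")
  d2 <- attr(predicted_curve(fitC, fitD, 0.5, method = "isobole"),
             "interpolate")
  expect_equal(g2(ic50mix), 50, tolerance = 1e-6)
  expect_equal(d2(ic50mix), 50, tolerance = 1e-6)
  cc2 <- inside(cvCD)
  diffs <- abs(g2(cc2) - d2(cc2))
  expect_gt(max(diffs), 1e-9)   # genuinely different between nodes
  expect_lt(max(diffs), 1)      # but bounded well under one percentage point
})
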