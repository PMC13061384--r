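#' Relative potency factor
#'
#' \eqn{RPF_2 = BMC_1 / BMC_2}: the potency of component 2 expressed in
#' units of component 1 (also applied to IC50s).
#'
#' @param bmc1,bmc2 Positive finite potencies in uM.
#' @return The dimensionless relative potency factor.
#' @export
relative_potency <- function(bmc1, bmc2) {
  if (any(!is.finite(c(bmc1, bmc2))) || any(c(bmc1, bmc2) <= 0))
    stop("both potencies must be positive and finite")
  bmc1 / bmc2
}

#' Loewe-predicted BMC of an equimolar binary mixture
#'
#' Concentration addition predicts the per-component mixture BMC as the
#' harmonic combination \eqn{BMC_{mix} = 1/(1/BMC_1 + 1/BMC_2)}
#' (equivalently \eqn{BMC_1/(1+RPF_2)}). A component without an active BMC
#' is treated as infinitely dilute (its BMC is infinite) and the prediction
#' equals the active component's BMC; with both inactive the prediction is
#' inactive. Predictions above the cap (default 10 uM, the maximum tested
#' concentration) are flagged `capped` and treated downstream as no
#' predicted effect.
#'
#' @param bmc1,bmc2 Single-agent BMCs in uM; `NA` or `Inf` marks an
#'   inactive component.
#' @param cap Per-component concentration cap in uM.
#' @return An object of class `ca_prediction`: `bmc_mix_per_component`,
#'   `bmc_mix_total` (= 2x per component), `rpf2`, `capped`, `active`.
#' @export
predict_mixture_bmc <- function(bmc1, bmc2, cap = 10) {
  act1 <- is.finite(bmc1); act2 <- is.finite(bmc2)
  if ((act1 && bmc1 <= 0) || (act2 && bmc2 <= 0))
    stop("active BMCs must be positive")
  if (!act1 && !act2) {
    mix <- NA_real_
  } else if (act1 && act2) {
    mix <- 1 / (1 / bmc1 + 1 / bmc2)
  } else {
    mix <- if (act1) bmc1 else bmc2
  }
  capped <- is.finite(mix) && mix > cap
  structure(list(
    bmc_mix_per_component = mix,
    bmc_mix_total = 2 * mix,
    rpf2 = if (act1 && act2) bmc1 / bmc2 else NA_real_,
    capped = capped,
    active = is.finite(mix) && !capped,
    cap = cap, bmc1 = bmc1, bmc2 = bmc2),
    class = "ca_prediction")
}

#' @export
print.ca_prediction <- function(x, ...) {
  if (!is.finite(x$bmc_mix_per_component)) {
    cat("CA prediction: inactive (no active component)\n")
  } else {
    cat(sprintf(
      "CA prediction: %.4g uM per component (%.4g uM total)%s\n",
      x$bmc_mix_per_component, x$bmc_mix_total,
      if (x$capped) sprintf(" [capped > %g uM: no predicted effect]", x$cap) else ""))
    if (!is.null(x$interval_lb))
      cat(sprintf("  interval [%.4g, %.4g] uM per component\n",
                  x$interval_lb, x$interval_ub))
  }
  invisible(x)
}

#' Loewe-predicted mixture BMC with a propagated interval
#'
#' Combines two single-agent [estimate_bmc()] results into a point
#' prediction plus an uncertainty interval. The default (`method =
#' "bounds"`) pushes the 5th-percentile bounds and the 95th-percentile
#' bounds through the harmonic formula, applying the inactive-component
#' rule coordinate-wise; `method = "bootstrap"` instead combines the two
#' bootstrap BMC samples iteration-wise and takes the 5th/95th percentiles
#' of the combined distribution.
#'
#' @param est1,est2 `bmc_estimate` objects (or lists with `bmc_median`,
#'   `bmc_lb`, `bmc_ub`, `active`, and for the bootstrap method `samples`).
#' @param cap Per-component prediction cap in uM.
#' @param method Interval propagation method.
#' @return A `ca_prediction` with `interval_lb`/`interval_ub` (uM per
#'   component).
#' @export
predict_interval <- function(est1, est2, cap = 10,
                             method = c("bounds", "bootstrap")) {
  method <- match.arg(method)
  val <- function(e, f) if (isTRUE(e$active)) e[[f]] else NA_real_
  for (e in list(est1, est2)) {
    if (isTRUE(e$active) &&
        (e$bmc_lb > e$bmc_median || e$bmc_median > e$bmc_ub))
      stop("inverted BMC interval")
  }
  if (!isTRUE(est1$active) && !isTRUE(est2$active))
    stop("at least one component must be active")
  pred <- predict_mixture_bmc(val(est1, "bmc_median"), val(est2, "bmc_median"),
                              cap = cap)
  combine <- function(a, b) {
    fa <- is.finite(a); fb <- is.finite(b)
    ifelse(fa & fb, 1 / (1 / a + 1 / b), ifelse(fa, a, ifelse(fb, b, NA_real_)))
  }
  if (method == "bounds") {
    pred$interval_lb <- combine(val(est1, "bmc_lb"), val(est2, "bmc_lb"))
    pred$interval_ub <- combine(val(est1, "bmc_ub"), val(est2, "bmc_ub"))
  } else {
    s1 <- if (isTRUE(est1$active)) est1$samples else NA_real_
    s2 <- if (isTRUE(est2$active)) est2$samples else NA_real_
    n <- max(length(s1), length(s2))
    comb <- combine(rep_len(s1, n), rep_len(s2, n))
    comb <- comb[is.finite(comb)]
    if (!length(comb)) stop("no finite combined bootstrap draws")
    q <- stats::quantile(comb, c(0.05, 0.95), names = FALSE)
    pred$interval_lb <- q[1]; pred$interval_ub <- q[2]
  }
  pred$interval_method <- method
  pred
}

#' Loewe-predicted effect-level concentration for an arbitrary-ratio mixture
#'
#' Total-mixture concentration producing p% inhibition under concentration
#' addition: \eqn{IC_p^{mix,total} = 1/(f_1/IC_p^{(1)} + f_2/IC_p^{(2)})},
#' where \eqn{f_1 + f_2 = 1} are the components' fractions of the total
#' mixture. With equal fractions this equals twice the per-component
#' harmonic combination.
#'
#' @param fit1,fit2 Converged [fit_log_logistic()] results.
#' @param f1 Fraction of component 1 in the total mixture (f2 = 1 - f1).
#' @param p Effect level(s) in percent inhibition, inside (0, 100).
#' @return Numeric vector of total-mixture ICp values (uM).
#' @export
predict_mixture_icp <- function(fit1, fit2, f1 = 0.5, p = 50) {
  if (f1 <= 0 || f1 >= 1) stop("f1 must be strictly inside (0, 1)")
  icp1 <- effect_level(fit1, p)$icp
  icp2 <- effect_level(fit2, p)$icp
  1 / (f1 / icp1 + (1 - f1) / icp2)
}

#' Predicted mixture inhibition curve under concentration addition
#'
#' `method = "grid"` evaluates [predict_mixture_icp()] over a grid of
#' effect levels, giving (total concentration, inhibition) pairs that are
#' exact at the grid nodes; intermediate concentrations are interpolated
#' logit-linearly in log10 concentration (exact when the two Hill slopes
#' are equal, since the mixture curve is then itself log-logistic).
#' `method = "isobole"` solves the isobole numerically for the inhibition
#' at each requested concentration, with no interpolation.
#'
#' @inheritParams predict_mixture_icp
#' @param effect_grid Effect levels (percent) for the grid method; at
#'   least 5 points inside (0, 100).
#' @return Data frame with `p` (percent inhibition) and
#'   `conc_total` (uM), plus an `interpolate` attribute: a function
#'   mapping total concentration to predicted percent inhibition.
#' @export
predicted_curve <- function(fit1, fit2, f1 = 0.5,
                            effect_grid = seq(5, 95, by = 5),
                            method = c("grid", "isobole")) {
  method <- match.arg(method)
  if (length(effect_grid) < 5 || any(effect_grid <= 0 | effect_grid >= 100))
    stop("effect_grid must have >= 5 points inside (0, 100)")
  effect_grid <- sort(effect_grid)
  conc <- predict_mixture_icp(fit1, fit2, f1, effect_grid)
  if (is.unsorted(conc, strictly = TRUE))
    stop("internal consistency failure: non-monotone predicted curve")
  curve <- data.frame(p = effect_grid, conc_total = conc)
  if (method == "grid") {
    lgt <- function(p) log(p / (100 - p))
    interp <- function(conc_total) {
      y <- stats::approx(log10(conc), lgt(effect_grid), xout = log10(conc_total),
                         rule = 2)$y
      100 * exp(y) / (1 + exp(y))
    }
  } else {
    interp <- function(conc_total) {
      vapply(conc_total, function(ct) {
        f <- function(p) predict_mixture_icp(fit1, fit2, f1, p) - ct
        lo <- 1e-6; hi <- 100 - 1e-6
        if (f(lo) >= 0) return(0)
        if (f(hi) <= 0) return(100)
        stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
      }, 0)
    }
  }
  attr(curve, "interpolate") <- interp
  attr(curve, "method") <- method
  curve
}
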