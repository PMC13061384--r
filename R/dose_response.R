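#' Fit a fixed-asymptote log-logistic inhibition curve
#'
#' Least-squares fit of percent activity
#' \eqn{A(C) = 100 / (1 + (C/IC_{50})^h)} with the lower asymptote fixed at
#' 0 and the upper at 100. The fit is parameterised on
#' \eqn{(\log IC_{50}, \log h)} to enforce positivity and uses
#' Levenberg-Marquardt nonlinear least squares with a multi-start over 5
#' log-spaced IC50 seeds spanning the tested range; the best-SSE converged
#' start wins. Standard errors come from the local curvature of the
#' objective (delta method back to the natural scale). Optimiser failure or
#' an IC50 pinned far outside the tested range yields `converged = FALSE`,
#' never an error. Activities outside [0, 100] are retained as-is (the
#' asymptotes are fixed, so clipping would only bias the fit).
#'
#' @param records Data frame with columns `concentration_uM` and
#'   `percent_activity` (e.g. from [simulate_ache_assay()] or
#'   [read_ache_csv()]). Alternatively pass `conc` and `activity` vectors.
#' @param conc,activity Optional explicit vectors overriding `records`.
#' @param use_means If `TRUE`, fit per-concentration means instead of
#'   individual replicates (default `FALSE`: replicates enter individually).
#' @return An object of class `dr_fit`: list with `ic50`, `hill`,
#'   `ic50_se`, `hill_se`, `n_obs`, `residual_sd`, `converged`,
#'   `lower_limit` (0), `upper_limit` (100).
#' @export
fit_log_logistic <- function(records = NULL, conc = NULL, activity = NULL,
                             use_means = FALSE) {
  if (is.null(conc)) {
    stopifnot(is.data.frame(records),
              all(c("concentration_uM", "percent_activity") %in% names(records)))
    conc <- records$concentration_uM
    activity <- records$percent_activity
  }
  keep <- is.finite(conc) & is.finite(activity) & conc > 0
  conc <- conc[keep]; activity <- activity[keep]
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct positive concentrations")
  if (use_means) {
    activity <- tapply(activity, conc, mean)
    conc <- as.numeric(names(activity))
    activity <- as.numeric(activity)
  }
  failed <- function() structure(
    list(ic50 = NA_real_, hill = NA_real_, ic50_se = NA_real_,
         hill_se = NA_real_, n_obs = length(conc),
         residual_sd = NA_real_, converged = FALSE,
         lower_limit = 0, upper_limit = 100), class = "dr_fit")
  if (stats::sd(activity) == 0) return(failed())
  dat <- data.frame(conc = conc, activity = activity)
  starts <- exp(seq(log(min(conc)), log(max(conc)), length.out = 5))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        activity ~ 100 / (1 + (conc / exp(lic50))^exp(lh)),
        data = dat, start = list(lic50 = log(s), lh = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(failed())
  cf <- stats::coef(best$fit)
  ic50 <- exp(cf[["lic50"]]); hill <- exp(cf[["lh"]])
  # an IC50 driven far beyond the tested range is a boundary solution
  if (ic50 < min(conc) / 1e3 || ic50 > max(conc) * 1e3 ||
      hill < 1e-4 || hill > 1e4) return(failed())
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  ic50_se <- if (is.null(vc)) NA_real_ else ic50 * sqrt(vc["lic50", "lic50"])
  hill_se <- if (is.null(vc)) NA_real_ else hill * sqrt(vc["lh", "lh"])
  df <- length(conc) - 2L
  structure(list(
    ic50 = ic50, hill = hill, ic50_se = ic50_se, hill_se = hill_se,
    n_obs = length(conc),
    residual_sd = if (df > 0) sqrt(best$sse / df) else 0,
    converged = TRUE, lower_limit = 0, upper_limit = 100),
    class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  if (!x$converged) {
    cat("log-logistic fit: NOT converged (n =", x$n_obs, ")\n")
  } else {
    cat(sprintf(
      "log-logistic fit (asymptotes 0/100): IC50 = %.4g uM (SE %.3g), Hill = %.3g (SE %.3g), n = %d, residual SD = %.3g%%\n",
      x$ic50, x$ic50_se, x$hill, x$hill_se, x$n_obs, x$residual_sd))
  }
  invisible(x)
}

#' Effect-level concentration from a log-logistic fit
#'
#' The concentration producing p% inhibition:
#' \eqn{IC_p = IC_{50} \cdot (p/(100-p))^{1/h}}. `effect_level(fit, 50)`
#' returns the IC50 exactly.
#'
#' @param fit A converged [fit_log_logistic()] result, or any list with
#'   `ic50` and `hill`.
#' @param p Effect level(s) in percent inhibition, strictly inside (0, 100).
#' @return Data frame with columns `p` and `icp` (uM).
#' @export
effect_level <- function(fit, p) {
  if (isFALSE(fit$converged)) stop("fit did not converge")
  if (any(p <= 0 | p >= 100)) stop("p must be strictly inside (0, 100)")
  data.frame(p = p, icp = fit$ic50 * (p / (100 - p))^(1 / fit$hill))
}
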