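#' Log-logit regression line for one agent's inhibition data
#'
#' Ordinary least squares of the natural-log logit of fractional inhibition
#' on log10 concentration: \eqn{Y = Y_0 + b \cdot \log_{10} C}, where
#' \eqn{Y = \ln(I/(100-I))} and I is percent inhibition (100 minus percent
#' activity). Inhibition is clipped to [0.5, 99.5]% before the logit so
#' that complete/zero inhibition remains finite; the number of clipped
#' points is reported. For data generated by a log-logistic curve with Hill
#' slope h, the true line has slope \eqn{b = h \ln 10}.
#'
#' @param records Data frame with `concentration_uM` and
#'   `percent_activity`, or pass `conc`/`activity` vectors.
#' @param conc,activity Optional explicit vectors.
#' @param clip Inhibition clip bounds in percent (default 0.5 / 99.5).
#' @return An object of class `logit_line`: `intercept` (Y0), `slope` (b,
#'   logit per log10 uM), `n`, `residual_se`, `n_clipped`, `clip`.
#' @export
fit_logit_line <- function(records = NULL, conc = NULL, activity = NULL,
                           clip = c(0.5, 99.5)) {
  if (is.null(conc)) {
    stopifnot(is.data.frame(records),
              all(c("concentration_uM", "percent_activity") %in% names(records)))
    conc <- records$concentration_uM
    activity <- records$percent_activity
  }
  keep <- is.finite(conc) & is.finite(activity) & conc > 0
  conc <- conc[keep]; activity <- activity[keep]
  if (length(unique(conc)) < 3)
    stop("need at least 3 distinct positive concentrations")
  inhib <- 100 - activity
  lo <- inhib <= clip[1]; hi <- inhib >= clip[2]
  if (all(lo) || all(hi))
    stop("all points clipped on the same side; line is uninformative")
  inhib <- pmin(pmax(inhib, clip[1]), clip[2])
  y <- log(inhib / (100 - inhib))
  fit <- stats::lm(y ~ log10(conc))
  # direct residual SE; summary.lm warns on (legitimate) noiseless input
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 n = length(y),
                 residual_se = sqrt(sum(stats::resid(fit)^2) /
                                      fit$df.residual),
                 n_clipped = sum(lo | hi), clip = clip),
            class = "logit_line")
}

#' @export
print.logit_line <- function(x, ...) {
  cat(sprintf(
    "log-logit line: Y = %.4g + %.4g * log10(C)  (n = %d, residual SE %.3g, %d clipped)\n",
    x$intercept, x$slope, x$n, x$residual_se, x$n_clipped))
  invisible(x)
}

# predicted logit inhibition of a line at concentration c (uM)
logit_at <- function(line, conc) line$intercept + line$slope * log10(conc)

#' Equivalent concentration of one agent in units of another
#'
#' The concentration of agent B producing the same logit inhibition as
#' concentration `cA` of agent A, read off the two log-logit lines:
#' \eqn{10^{(Y_A(c_A) - Y_{0B}) / b_B}}.
#'
#' @param cA Concentration(s) of agent A in uM (positive).
#' @param lineA,lineB [fit_logit_line()] results for agents A and B.
#' @return Equivalent concentration(s) of agent B in uM.
#' @export
equivalent_concentration <- function(cA, lineA, lineB) {
  if (any(cA <= 0) || any(!is.finite(cA))) stop("cA must be positive and finite")
  if (lineB$slope == 0) stop("agent B line has zero slope")
  10^((logit_at(lineA, cA) - lineB$intercept) / lineB$slope)
}

#' Expected mixture inhibition under concentration addition
#'
#' Converts agent A's dose to its B-equivalent, sums with the B dose, and
#' evaluates agent B's log-logit line at the summed concentration:
#' \eqn{X = \log_{10}(c_A^{eq} + c_B)}, \eqn{Y = Y_{0B} + b_B X}.
#'
#' @param cA,cB Component concentrations in uM (`cA = 0` reduces to the
#'   single-agent B line; the sum must be positive).
#' @param lineA,lineB [fit_logit_line()] results.
#' @return Data frame: cA, cB, conc_equivalent (total B-equivalent uM),
#'   expected_logit, expected_inhibition (percent).
#' @export
expected_inhibition <- function(cA, cB, lineA, lineB) {
  n <- max(length(cA), length(cB))
  cA <- rep_len(cA, n); cB <- rep_len(cB, n)
  ceq <- numeric(n)
  pos <- cA > 0
  if (any(pos)) ceq[pos] <- equivalent_concentration(cA[pos], lineA, lineB)
  total <- ceq + cB
  if (any(total <= 0)) stop("summed equivalent concentration must be positive")
  y <- logit_at(lineB, total)
  data.frame(cA = cA, cB = cB, conc_equivalent = total,
             expected_logit = y,
             expected_inhibition = 100 * exp(y) / (1 + exp(y)))
}

#' Slope test of observed versus expected logit inhibition
#'
#' Regresses observed logit inhibition on the concentration-addition
#' expectation and tests the slope against 1.0 (t test on the coefficient):
#' under additivity the observed and expected logits fall on the identity
#' line. When `concentration` is supplied and `use_medians = TRUE`
#' (the default, matching practice of summarising replicate noise), the
#' per-concentration medians of observed and expected are used.
#'
#' @param observed Observed logit inhibition values.
#' @param expected Expected logit inhibition values (same length).
#' @param concentration Optional concentration labels for median collapse.
#' @param use_medians Collapse to per-concentration medians first.
#' @param alpha Significance level for `reject_at_alpha` (default 0.05).
#' @return An object of class `slope_test`: `slope_estimate`, `slope_se`,
#'   `p_value` (H0: slope = 1), `n_points`, `reject_at_alpha`, `alpha`,
#'   `perfect_fit`.
#' @export
slope_test <- function(observed, expected, concentration = NULL,
                       use_medians = TRUE, alpha = 0.05) {
  stopifnot(length(observed) == length(expected))
  if (!is.null(concentration) && use_medians) {
    observed <- tapply(observed, concentration, stats::median)
    expected <- tapply(expected, concentration, stats::median)
    observed <- as.numeric(observed); expected <- as.numeric(expected)
  }
  if (length(observed) < 3) stop("need at least 3 points")
  if (stats::sd(expected) == 0) stop("expected values have zero variance")
  fit <- stats::lm(observed ~ expected)
  b <- unname(stats::coef(fit)[2])
  df <- fit$df.residual
  rss <- sum(stats::resid(fit)^2)
  perfect <- rss < 1e-20 * max(1, sum(observed^2))
  if (perfect) {
    se <- 0
    p <- 1
  } else {
    se <- summary(fit)$coefficients["expected", "Std. Error"]
    tstat <- (b - 1) / se
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(slope_estimate = b, slope_se = se, p_value = p,
                 n_points = length(observed),
                 reject_at_alpha = !perfect && p < alpha,
                 alpha = alpha, perfect_fit = perfect,
                 intercept = unname(stats::coef(fit)[1])),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf(
    "observed ~ expected logit slope = %.4g (SE %.3g), H0 slope = 1: p = %.4g%s (n = %d)\n",
    x$slope_estimate, x$slope_se, x$p_value,
    if (x$perfect_fit) " [perfect fit]" else "", x$n_points))
  invisible(x)
}
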