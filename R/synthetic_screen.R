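#' Ground-truth description of a single agent
#'
#' Bundles the per-readout concentration-response parameters used by the
#' synthetic screen generator: a log-logistic effect curve per behavioral
#' readout plus one log-logistic AChE inhibition curve. Effect curves are
#' increasing in concentration,
#' \eqn{E(C) = E_{max} / (1 + (EC_{50}/C)^h)},
#' with `max_effect` in percent (incidence readouts: maximal percent of
#' animals responding; continuous readouts: maximal percent change from
#' control, applied in the readout's `direction`).
#'
#' @param name Agent identifier (no `"."`, which separates mixture ids).
#' @param ec50 Named numeric vector, EC50 in uM per readout (> 0).
#' @param hill Named numeric vector, Hill slope per readout (> 0).
#' @param max_effect Named numeric vector, maximal effect in percent per
#'   readout (incidence: <= 100).
#' @param direction Named character vector per readout, `"+"` or `"-"`.
#' @param is_incidence Named logical vector per readout: per-animal 0/1
#'   (Bernoulli) readout vs continuous readout.
#' @param baseline Named numeric vector, control mean for continuous
#'   readouts in native response units (ignored for incidence readouts).
#'   Default 1 for every readout.
#' @param ache_ic50,ache_hill Parameters of the agent's AChE inhibition
#'   curve (activity \eqn{= 100/(1+(C/IC_{50})^h)}).
#' @return An object of class `agent_truth`.
#' @export
agent_truth <- function(name, ec50, hill, max_effect, direction,
                        is_incidence, baseline = NULL,
                        ache_ic50 = 1, ache_hill = 1) {
  stopifnot(is.character(name), length(name) == 1L, !grepl(".", name, fixed = TRUE))
  readouts <- names(ec50)
  if (is.null(readouts) || any(readouts == ""))
    stop("'ec50' must be a named vector (one entry per readout)")
  for (arg in list(hill = hill, max_effect = max_effect,
                   direction = direction, is_incidence = is_incidence)) {
    if (!setequal(names(arg), readouts))
      stop("all per-readout vectors must share the same readout names")
  }
  if (is.null(baseline)) baseline <- stats::setNames(rep(1, length(readouts)), readouts)
  if (!setequal(names(baseline), readouts))
    stop("'baseline' must be named by the same readouts")
  if (any(ec50 <= 0) || ache_ic50 <= 0) stop("EC50/IC50 values must be positive")
  if (any(hill[readouts] <= 0) || ache_hill <= 0) stop("Hill slopes must be positive")
  if (any(max_effect[readouts] <= 0)) stop("max_effect must be positive")
  if (any(max_effect[readouts][is_incidence[readouts]] > 100))
    stop("incidence max_effect cannot exceed 100%")
  if (!all(direction[readouts] %in% c("+", "-"))) stop("direction must be '+' or '-'")
  structure(list(name = name, readouts = readouts,
                 ec50 = ec50[readouts], hill = hill[readouts],
                 max_effect = max_effect[readouts],
                 direction = direction[readouts],
                 is_incidence = is_incidence[readouts],
                 baseline = baseline[readouts],
                 ache_ic50 = ache_ic50, ache_hill = ache_hill),
            class = "agent_truth")
}

#' Ground-truth interaction model for a simulated binary mixture
#'
#' `loewe_additive` simulates exact concentration addition; `potency_shift`
#' divides both components' equipotent concentrations by `shift_factor`
#' before solving the isobole, so `shift_factor > 1` yields synergy and
#' `< 1` antagonism relative to the additive null.
#'
#' @param model `"loewe_additive"` or `"potency_shift"`.
#' @param shift_factor Positive scalar; forced to 1 for `loewe_additive`.
#' @param applies_to `"all"` or a character vector of readouts the shift
#'   applies to (others stay additive).
#' @return An object of class `interaction_truth`.
#' @export
interaction_truth <- function(model = c("loewe_additive", "potency_shift"),
                              shift_factor = 1, applies_to = "all") {
  model <- match.arg(model)
  if (shift_factor <= 0) stop("shift_factor must be positive")
  if (model == "loewe_additive" && shift_factor != 1)
    stop("loewe_additive forces shift_factor = 1")
  structure(list(model = model, shift_factor = shift_factor,
                 applies_to = applies_to),
            class = "interaction_truth")
}

#' Design of a simulated screening experiment
#'
#' Mirrors the 48-well planarian screening layout: each plate holds one row
#' of 8 animals per concentration plus 8 in-plate solvent controls, and
#' three replicate plates give n = 24 animals per concentration.
#'
#' @param concentrations Tested concentrations in uM, strictly increasing
#'   and positive. Default: 0.1 to 10 uM in semi-log steps.
#' @param replicate_plates Number of replicate plates (default 3).
#' @param n_per_concentration Animals per concentration; must equal
#'   `8 * replicate_plates`.
#' @param worm_types,days Strata to simulate (same ground-truth curves in
#'   each stratum; strata are analysed separately downstream).
#' @param noise_sd_continuous Gaussian noise SD for continuous readouts, in
#'   native response units (baseline defaults to 1, so 0.05 is a 5% CV).
#' @param plate_offset_sd Optional SD of an additive per-plate offset on
#'   continuous readouts (0 = no plate effects, the default).
#' @param seed Integer seed; every simulation call is reproducible.
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(concentrations = c(0.1, 0.316, 1, 3.16, 10),
                          replicate_plates = 3,
                          n_per_concentration = 8 * replicate_plates,
                          worm_types = c("adult", "regenerating"),
                          days = c(7, 12),
                          noise_sd_continuous = 0.05,
                          plate_offset_sd = 0,
                          seed = 1L) {
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be positive and strictly increasing")
  if (n_per_concentration != 8 * replicate_plates)
    stop("n_per_concentration must equal 8 * replicate_plates")
  structure(list(concentrations = concentrations,
                 replicate_plates = replicate_plates,
                 n_per_concentration = n_per_concentration,
                 worm_types = worm_types, days = days,
                 noise_sd_continuous = noise_sd_continuous,
                 plate_offset_sd = plate_offset_sd,
                 seed = as.integer(seed)),
            class = "screen_design")
}

# log-logistic effect curve, increasing in C: Emax / (1 + (EC50/C)^h)
loglogistic_effect <- function(conc, ec50, hill, max_effect) {
  ifelse(conc <= 0, 0, max_effect / (1 + (ec50 / conc)^hill))
}

# inverse: concentration producing effect E (0 < E < max_effect)
loglogistic_inverse <- function(effect, ec50, hill, max_effect) {
  ec50 * (effect / (max_effect - effect))^(1 / hill)
}

#' Expected Loewe-additive effect of an equimolar binary combination
#'
#' Solves the isobole \eqn{c_1/EC_E^{(1)} + c_2/EC_E^{(2)} = 1} for the
#' effect level E at the given per-component concentrations, by bisection
#' on E (relative tolerance 1e-9). Handles unequal Hill slopes exactly.
#' When the requested concentrations exceed what either curve can reach,
#' the effect is capped at the smaller maximal effect and the result
#' carries `attr(, "capped") = TRUE`.
#'
#' @param conc1,conc2 Component concentrations in uM (vectors recycle).
#' @param ec50_1,hill1,max1,ec50_2,hill2,max2 Log-logistic parameters of
#'   the two single-agent curves.
#' @param tol Relative bisection tolerance on the effect.
#' @return Numeric vector of expected effects (percent), with a logical
#'   `capped` attribute of the same length.
#' @export
loewe_mixture_effect <- function(conc1, conc2, ec50_1, hill1, max1,
                                 ec50_2, hill2, max2, tol = 1e-9) {
  n <- max(length(conc1), length(conc2))
  conc1 <- rep_len(conc1, n); conc2 <- rep_len(conc2, n)
  emax <- min(max1, max2)
  out <- numeric(n); capped <- logical(n)
  for (i in seq_len(n)) {
    c1 <- conc1[i]; c2 <- conc2[i]
    if (c1 <= 0 && c2 <= 0) { out[i] <- 0; next }
    f <- function(e) {
      s <- 0
      if (c1 > 0) s <- s + c1 / loglogistic_inverse(e, ec50_1, hill1, max1)
      if (c2 > 0) s <- s + c2 / loglogistic_inverse(e, ec50_2, hill2, max2)
      s - 1
    }
    hi <- emax * (1 - 1e-12)
    if (f(hi) > 0) { out[i] <- emax; capped[i] <- TRUE; next }
    lo <- emax * 1e-15
    if (f(lo) < 0) { out[i] <- 0; next }
    while ((hi - lo) > tol * max(hi, .Machine$double.eps)) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    out[i] <- (lo + hi) / 2
  }
  attr(out, "capped") <- capped
  out
}

# expected per-readout effect (percent) for a mixture under an interaction
# truth, at per-component concentration conc
mixture_expected_effect <- function(truthA, truthB, interaction, readout, conc) {
  shift <- 1
  if (interaction$model == "potency_shift" &&
      (identical(interaction$applies_to, "all") ||
       readout %in% interaction$applies_to))
    shift <- interaction$shift_factor
  loewe_mixture_effect(conc, conc,
                       truthA$ec50[readout] / shift, truthA$hill[readout],
                       truthA$max_effect[readout],
                       truthB$ec50[readout] / shift, truthB$hill[readout],
                       truthB$max_effect[readout])
}

# one stratum x plate worth of wells for every readout, given a function
# effect_fn(readout, conc) -> expected percent effect
simulate_records <- function(condition, truth, design, effect_fn) {
  concs <- design$concentrations
  rows <- list()
  has_lethality <- "lethality" %in% truth$readouts
  for (wt in design$worm_types) for (day in design$days) {
    for (plate in seq_len(design$replicate_plates)) {
      plate_id <- sprintf("%s_%s_d%d_p%d", condition, wt, day, plate)
      well_conc <- c(rep(0, 8), rep(concs, each = 8))
      well_id <- seq_along(well_conc)
      plate_off <- if (design$plate_offset_sd > 0)
        stats::rnorm(1, 0, design$plate_offset_sd) else 0
      # lethality is drawn first; dead animals are masked (NA) in all
      # other readouts, mirroring the screen's manual lethality call
      dead <- rep(FALSE, length(well_conc))
      if (has_lethality) {
        p <- pmin(1, effect_fn("lethality", well_conc) / 100)
        dead <- stats::rbinom(length(well_conc), 1L, p) == 1L
      }
      for (ro in truth$readouts) {
        if (ro == "lethality") {
          value <- as.numeric(dead)
        } else if (truth$is_incidence[ro]) {
          p <- pmin(1, effect_fn(ro, well_conc) / 100)
          value <- as.numeric(stats::rbinom(length(well_conc), 1L, p))
          value[dead] <- NA_real_
        } else {
          s <- if (truth$direction[ro] == "+") 1 else -1
          mu <- truth$baseline[ro] *
            (1 + s * effect_fn(ro, well_conc) / 100) + plate_off
          value <- stats::rnorm(length(well_conc), mu,
                                design$noise_sd_continuous)
          value[dead] <- NA_real_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          condition = condition, concentration_uM = well_conc,
          worm_type = wt, day = day, plate_id = plate_id,
          well_id = well_id, readout = ro,
          direction = if (truth$is_incidence[[ro]]) "+" else
            truth$direction[[ro]],
          value = unname(value),
          is_incidence = truth$is_incidence[[ro]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a single-agent screening data set
#'
#' Draws per-animal responses for every readout in `truth` under the plate
#' layout in `design`: incidence readouts are Bernoulli per animal with the
#' log-logistic probability, continuous readouts are Gaussian around the
#' log-logistic mean, and each plate carries 8 in-plate solvent controls at
#' concentration 0. Animals scored dead contribute only to the lethality
#' readout (their other values are NA).
#'
#' @param truth An [agent_truth()].
#' @param design A [screen_design()]; `design$seed` fixes the draw.
#' @return A long-format data frame of screen records (one row per animal
#'   per readout).
#' @export
simulate_single_agent <- function(truth, design) {
  stopifnot(inherits(truth, "agent_truth"), inherits(design, "screen_design"))
  withr::with_seed(design$seed, simulate_records(
    truth$name, truth, design,
    function(ro, conc) loglogistic_effect(conc, truth$ec50[ro],
                                          truth$hill[ro], truth$max_effect[ro])))
}

#' Simulate an equimolar binary-mixture screening data set
#'
#' Expected responses follow the Loewe isobole solved exactly per
#' concentration (see [loewe_mixture_effect()]); under a `potency_shift`
#' interaction both components' equipotent concentrations are divided by
#' the shift factor first. Concentrations are per component (an equimolar
#' well at c contains each agent at c). Both truths must agree on readout
#' set, direction, incidence flags and baselines.
#'
#' @param truthA,truthB [agent_truth()] objects for the two components.
#' @param interaction An [interaction_truth()].
#' @param design A [screen_design()].
#' @return A long-format data frame of screen records with condition
#'   `"A.B"`.
#' @export
simulate_mixture <- function(truthA, truthB,
                             interaction = interaction_truth(), design) {
  stopifnot(inherits(truthA, "agent_truth"), inherits(truthB, "agent_truth"),
            inherits(interaction, "interaction_truth"),
            inherits(design, "screen_design"))
  if (!setequal(truthA$readouts, truthB$readouts))
    stop("mixture components must share the same readouts")
  same <- function(f) all(truthA[[f]][truthA$readouts] ==
                          truthB[[f]][truthA$readouts])
  if (!same("direction") || !same("is_incidence") || !same("baseline"))
    stop("mixture components must agree on direction, incidence and baseline")
  condition <- paste(truthA$name, truthB$name, sep = ".")
  withr::with_seed(design$seed, simulate_records(
    condition, truthA, design,
    function(ro, conc)
      as.numeric(mixture_expected_effect(truthA, truthB, interaction, ro, conc))))
}

#' Simulate an AChE activity assay
#'
#' Percent activity relative to solvent control for a single agent or a
#' fixed-ratio binary mixture, with Gaussian noise on the activity scale.
#' For mixtures the expected inhibition at total concentration C is the
#' exact Loewe solution of the isobole over the component inhibition
#' curves at doses `fractions * C`. Values are NOT clipped to [0, 100]
#' (the output carries `attr(, "clipped") = FALSE`).
#'
#' @param truths A single [agent_truth()] or list of two.
#' @param fractions Mixing fractions summing to 1 (length matching
#'   `truths`).
#' @param concentrations Total concentrations in uM.
#' @param replicates Technical replicates per concentration (default 3).
#' @param noise_sd Gaussian noise SD in percent activity.
#' @param seed Integer seed.
#' @return Data frame: condition, concentration_uM (total), replicate,
#'   percent_activity.
#' @export
simulate_ache_assay <- function(truths, fractions = 1, concentrations,
                                replicates = 3, noise_sd = 5, seed = 1L) {
  if (inherits(truths, "agent_truth")) truths <- list(truths)
  stopifnot(all(vapply(truths, inherits, TRUE, "agent_truth")),
            length(fractions) == length(truths), replicates >= 1)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  condition <- paste(vapply(truths, `[[`, "", "name"), collapse = ".")
  inhibition <- if (length(truths) == 1L) {
    100 - 100 / (1 + (concentrations / truths[[1]]$ache_ic50)^truths[[1]]$ache_hill)
  } else {
    as.numeric(loewe_mixture_effect(
      fractions[1] * concentrations, fractions[2] * concentrations,
      truths[[1]]$ache_ic50, truths[[1]]$ache_hill, 100,
      truths[[2]]$ache_ic50, truths[[2]]$ache_hill, 100))
  }
  out <- withr::with_seed(as.integer(seed), {
    data.frame(
      condition = condition,
      concentration_uM = rep(concentrations, each = replicates),
      replicate = rep(seq_len(replicates), times = length(concentrations)),
      percent_activity = stats::rnorm(length(concentrations) * replicates,
                                      rep(100 - inhibition, each = replicates),
                                      noise_sd),
      stringsAsFactors = FALSE)
  })
  attr(out, "clipped") <- FALSE
  out
}

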