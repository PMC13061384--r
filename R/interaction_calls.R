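#' Classify one mixture readout as additive, synergistic or antagonistic
#'
#' Compares the observed mixture BMC interval with the Loewe-predicted
#' interval. Overlapping intervals are additive; an observed interval
#' entirely below the predicted one is synergistic (the mixture is more
#' potent than predicted); entirely above is antagonistic. When only one
#' side has an active BMC the intervals are treated as non-overlapping by
#' rule: an observed-only BMC means the mixture acted where none was
#' predicted (observed < predicted, synergistic), a predicted-only BMC the
#' reverse (antagonistic). Both sides inactive is `no_effect`. A capped
#' prediction (> cap) counts as inactive.
#'
#' @param observed A `bmc_estimate` (or list with `active`, `bmc_lb`,
#'   `bmc_ub`).
#' @param predicted A `ca_prediction` from [predict_interval()] (or list
#'   with `active`, `interval_lb`, `interval_ub`).
#' @param conc_range Optional tested range `c(min, max)` in uM; intervals
#'   spanning the whole range get `quality = "interval_spans_range"`.
#' @return List with `call` (one of `additive`, `synergistic`,
#'   `antagonistic`, `no_effect`), `provenance`, and `quality`.
#' @export
classify_interaction <- function(observed, predicted, conc_range = NULL) {
  obs_act <- isTRUE(observed$active)
  prd_act <- isTRUE(predicted$active) && !isTRUE(predicted$capped)
  if (obs_act && (!is.finite(observed$bmc_lb) || !is.finite(observed$bmc_ub) ||
                  observed$bmc_lb > observed$bmc_ub))
    stop("malformed observed interval")
  if (prd_act && (!is.finite(predicted$interval_lb) ||
                  !is.finite(predicted$interval_ub) ||
                  predicted$interval_lb > predicted$interval_ub))
    stop("malformed predicted interval")
  quality <- "ok"
  if (!is.null(conc_range) && obs_act &&
      observed$bmc_lb <= conc_range[1] && observed$bmc_ub >= conc_range[2])
    quality <- "interval_spans_range"
  if (!obs_act && !prd_act) {
    res <- list(call = "no_effect", provenance = "both_inactive")
  } else if (obs_act && !prd_act) {
    res <- list(call = "synergistic", provenance = "one_sided_observed")
  } else if (!obs_act && prd_act) {
    res <- list(call = "antagonistic", provenance = "one_sided_predicted")
  } else if (observed$bmc_ub < predicted$interval_lb) {
    res <- list(call = "synergistic", provenance = "observed_below")
  } else if (observed$bmc_lb > predicted$interval_ub) {
    res <- list(call = "antagonistic", provenance = "observed_above")
  } else {
    res <- list(call = "additive", provenance = "overlap")
  }
  res$quality <- quality
  res
}

#' Classify every readout of a mixture screen
#'
#' Merges observed mixture BMC estimates with CA predictions on
#' (mixture, worm_type, day, readout, direction) and applies
#' [classify_interaction()] row-wise.
#'
#' @param observed Data frame of observed mixture estimates (layout of
#'   [estimate_bmcs()], `condition` holding the mixture id).
#' @param predicted Data frame with the same keys plus
#'   `pred_median`, `pred_lb`, `pred_ub`, `pred_active`.
#' @param conc_range Optional tested range passed through.
#' @return `observed` with `call`, `provenance` and `quality` columns.
#' @export
classify_interactions <- function(observed, predicted, conc_range = NULL) {
  keys <- c("condition", "worm_type", "day", "readout", "direction")
  m <- merge(observed, predicted[c(keys, "pred_median", "pred_lb", "pred_ub",
                                   "pred_active")],
             by = keys, all.x = TRUE)
  if (anyDuplicated(m[keys])) stop("duplicate classification keys")
  res <- lapply(seq_len(nrow(m)), function(i) {
    classify_interaction(
      list(active = m$active[i], bmc_lb = m$bmc_lb[i], bmc_ub = m$bmc_ub[i]),
      list(active = isTRUE(m$pred_active[i]), capped = FALSE,
           interval_lb = m$pred_lb[i], interval_ub = m$pred_ub[i]),
      conc_range = conc_range)
  })
  m$call <- vapply(res, `[[`, "", "call")
  m$provenance <- vapply(res, `[[`, "", "provenance")
  m$quality <- vapply(res, `[[`, "", "quality")
  m
}

#' Overall potency discrepancy between observed and predicted mixtures
#'
#' For each mixture and worm type, takes the minimum median BMC across all
#' readouts and directions on each side (`BMC_min`) and reports
#' \eqn{\log_{10}(BMC_{min}^{pred} / BMC_{min}^{exp})}: positive values
#' mean the mixture was experimentally more potent than the additive
#' prediction. If either side has no active BMC the ratio is `NA`.
#'
#' @param observed_bmcs Data frame with `mixture` (or `condition`),
#'   `worm_type`, `readout`, `bmc_median` and `active` for the
#'   experimental mixtures.
#' @param predicted_bmcs Same layout for the CA-predicted BMCs.
#' @return Data frame: mixture, worm_type, experimental_bmc_min,
#'   predicted_bmc_min, log10_ratio, min_readout_experimental,
#'   min_readout_predicted.
#' @export
potency_summary <- function(observed_bmcs, predicted_bmcs) {
  fix <- function(d) {
    if (!"mixture" %in% names(d) && "condition" %in% names(d))
      d$mixture <- d$condition
    if (!"active" %in% names(d)) d$active <- is.finite(d$bmc_median)
    if (!"readout" %in% names(d)) d$readout <- NA_character_
    d
  }
  obs <- fix(observed_bmcs); prd <- fix(predicted_bmcs)
  keys <- unique(rbind(obs[c("mixture", "worm_type")],
                       prd[c("mixture", "worm_type")]))
  keys <- keys[order(keys$mixture, keys$worm_type), ]
  mins <- function(d, mx, wt) {
    sub <- d[d$mixture == mx & d$worm_type == wt & d$active &
             is.finite(d$bmc_median), ]
    if (!nrow(sub)) return(list(bmc = NA_real_, readout = NA_character_))
    i <- which.min(sub$bmc_median)
    list(bmc = sub$bmc_median[i], readout = sub$readout[i])
  }
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    o <- mins(obs, keys$mixture[i], keys$worm_type[i])
    p <- mins(prd, keys$mixture[i], keys$worm_type[i])
    data.frame(mixture = keys$mixture[i], worm_type = keys$worm_type[i],
               experimental_bmc_min = o$bmc, predicted_bmc_min = p$bmc,
               log10_ratio = if (is.finite(o$bmc) && is.finite(p$bmc))
                 log10(p$bmc / o$bmc) else NA_real_,
               min_readout_experimental = o$readout,
               min_readout_predicted = p$readout,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format table for interaction or potency heatmaps
#'
#' Reshapes a complete set of interaction calls (or BMC values) into tidy
#' rows ready for heatmap rendering, with deterministic ordering: mixtures
#' alphabetical, readouts in the benchmark-table order (then direction).
#'
#' @param calls Data frame from [classify_interactions()] (or any frame
#'   with condition/mixture, worm_type, day, readout, direction and a value
#'   column).
#' @param value Name of the column to carry as the cell value (default
#'   `"call"`).
#' @param readout_order Readout ordering; defaults to the packaged
#'   benchmark table order.
#' @return Tidy data frame: worm_type, day, mixture, readout, direction,
#'   value.
#' @export
heatmap_table <- function(calls, value = "call",
                          readout_order = unique(load_bmr_table()$readout)) {
  d <- calls
  if (!"mixture" %in% names(d) && "condition" %in% names(d))
    d$mixture <- d$condition
  keys <- c("worm_type", "day", "mixture", "readout", "direction")
  stopifnot(all(c(keys, value) %in% names(d)))
  if (anyDuplicated(d[keys])) stop("duplicate keys in heatmap input")
  ro <- match(d$readout, readout_order)
  ro[is.na(ro)] <- length(readout_order) + 1L
  d <- d[order(d$worm_type, d$day, d$mixture, ro, d$direction), ]
  out <- d[c(keys)]
  out$value <- d[[value]]
  rownames(out) <- NULL
  out
}
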