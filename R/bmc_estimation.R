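#' Per-concentration response summaries from raw screen records
#'
#' Collapses animal-level records to the response scale the benchmark
#' analysis works on. Incidence readouts become the percent of animals
#' responding at each concentration. Continuous readouts become the percent
#' change of the per-concentration mean from the in-plate solvent-control
#' mean, computed per plate and averaged across plates; each bidirectional
#' readout yields two series (`"+"` and `"-"`), where the series magnitude
#' is the change in that direction and changes in the opposite direction
#' contribute 0. Animals with NA values (e.g. masked dead animals) are
#' dropped from non-lethality summaries.
#'
#' @param records Long-format screen records (see
#'   [simulate_single_agent()] / [read_screen_csv()]).
#' @return Data frame: condition, worm_type, day, readout, direction,
#'   concentration_uM, response (percent magnitude), n, usable.
#' @export
normalize_responses <- function(records) {
  req <- c("condition", "concentration_uM", "worm_type", "day", "plate_id",
           "readout", "value", "is_incidence")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  keys <- unique(records[c("condition", "worm_type", "day", "readout")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- records[records$condition == k$condition &
                   records$worm_type == k$worm_type &
                   records$day == k$day & records$readout == k$readout, ]
    inc <- sub$is_incidence[1]
    concs <- sort(unique(sub$concentration_uM[sub$concentration_uM > 0]))
    if (inc) {
      resp <- vapply(concs, function(cc) {
        v <- sub$value[sub$concentration_uM == cc]
        v <- v[!is.na(v)]
        100 * mean(v)
      }, 0)
      n <- vapply(concs, function(cc)
        sum(!is.na(sub$value[sub$concentration_uM == cc])), 0L)
      out[[length(out) + 1L]] <- data.frame(
        k, direction = "+", concentration_uM = concs,
        response = resp, n = n, usable = TRUE, row.names = NULL)
    } else {
      if (!any(sub$concentration_uM == 0))
        stop("missing in-plate solvent controls for readout '", k$readout, "'")
      plates <- unique(sub$plate_id)
      ctrl_mean <- vapply(plates, function(p)
        mean(sub$value[sub$plate_id == p & sub$concentration_uM == 0],
             na.rm = TRUE), 0)
      names(ctrl_mean) <- plates
      usable <- all(is.finite(ctrl_mean)) && all(ctrl_mean != 0)
      signed <- vapply(concs, function(cc) {
        pct <- vapply(plates, function(p) {
          v <- sub$value[sub$plate_id == p & sub$concentration_uM == cc]
          v <- v[!is.na(v)]
          if (!length(v)) return(NA_real_)
          100 * (mean(v) - ctrl_mean[[p]]) / ctrl_mean[[p]]
        }, 0)
        mean(pct, na.rm = TRUE)
      }, 0)
      n <- vapply(concs, function(cc)
        sum(!is.na(sub$value[sub$concentration_uM == cc])), 0L)
      for (dir in c("+", "-")) {
        s <- if (dir == "+") 1 else -1
        out[[length(out) + 1L]] <- data.frame(
          k, direction = dir, concentration_uM = concs,
          response = if (usable) pmax(0, s * signed) else NA_real_,
          n = n, usable = usable, row.names = NULL)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' First benchmark-response crossing of a concentration-response series
#'
#' Scans concentrations from low to high and returns the first point where
#' the response magnitude reaches the BMR, linearly interpolated in
#' log10(concentration). A response exactly equal to the BMR at a tested
#' concentration returns that concentration (ties break toward the lower
#' concentration); a series already at or above the BMR at the lowest
#' tested concentration returns that lowest concentration; a series that
#' never reaches the BMR returns `NA`.
#'
#' @param conc Tested concentrations (uM, ascending).
#' @param response Response magnitudes (percent) at `conc`.
#' @param bmr Benchmark response (> 0).
#' @return The benchmark concentration in uM, or `NA_real_`.
#' @export
bmr_crossing <- function(conc, response, bmr) {
  stopifnot(length(conc) == length(response), bmr > 0,
            !is.unsorted(conc, strictly = TRUE))
  hit <- which(response >= bmr)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1L) return(conc[1])
  frac <- (bmr - response[i - 1]) / (response[i] - response[i - 1])
  10^(log10(conc[i - 1]) + frac * (log10(conc[i]) - log10(conc[i - 1])))
}

# pool-adjacent-violators: non-decreasing fit of response vs conc order
monotonize_response <- function(response) {
  if (length(response) < 2) return(response)
  stats::isoreg(seq_along(response), response)$yf
}

#' Bootstrap benchmark-concentration estimate for one readout series
#'
#' Estimates the BMC of one (condition, worm type, day, readout, direction)
#' series by resampling animals within each concentration with replacement
#' (`n_boot` iterations), recomputing the per-concentration summaries,
#' optionally monotonizing them (pool-adjacent-violators, on by default),
#' and locating the first BMR crossing with [bmr_crossing()]. Iterations
#' without a crossing count as inactive; the reported BMC is the median of
#' the finite crossings with 5th/95th percentile limits, and
#' `hit_confidence` is the fraction of iterations with a finite crossing.
#' The estimate is `active` when the median is finite, lies within the
#' tested range, and `hit_confidence >= hit_threshold`.
#'
#' For incidence readouts the within-concentration animal resample is drawn
#' as the equivalent binomial count; continuous readouts resample animal
#' indices within each (plate, concentration) cell and controls within each
#' plate, renormalizing against the resampled in-plate control mean.
#'
#' @param records Raw screen records for a single condition (and at least
#'   the stratum addressed by `bmr`).
#' @param bmr A one-row data frame or list with `readout`, `worm_type`,
#'   `day`, `direction` and `bmr` (see [load_bmr_table()]).
#' @param n_boot Bootstrap iterations (default 1000; fewer than 100 sets
#'   the `low_n_boot` flag).
#' @param seed Integer seed for the bootstrap.
#' @param monotonize Apply pool-adjacent-violators before crossing.
#' @param hit_threshold Minimum hit confidence for an `active` call.
#' @return An object of class `bmc_estimate`.
#' @export
estimate_bmc <- function(records, bmr, n_boot = 1000, seed = 1L,
                         monotonize = TRUE, hit_threshold = 0.5) {
  bmr <- as.list(bmr)
  sub <- records[records$readout == bmr$readout &
                 records$worm_type == bmr$worm_type &
                 records$day == bmr$day, ]
  if (!nrow(sub)) stop("no records match the BMR specification")
  if (length(unique(sub$condition)) != 1L)
    stop("records must contain a single condition")
  concs <- sort(unique(sub$concentration_uM[sub$concentration_uM > 0]))
  if (length(concs) < 4) stop("need at least 4 tested concentrations")
  inc <- sub$is_incidence[1]
  s <- if (bmr$direction == "+") 1 else -1
  max_tested <- max(concs)
  # concentrations where lethality masking left no scoreable animals carry
  # no information for this readout; the series continues without them
  n_avail <- vapply(concs, function(cc)
    sum(!is.na(sub$value[sub$concentration_uM == cc])), 0L)
  concs <- concs[n_avail > 0]
  inactive_estimate <- function() structure(c(
    list(condition = sub$condition[1], readout = bmr$readout,
         worm_type = bmr$worm_type, day = bmr$day,
         direction = bmr$direction, bmr = bmr$bmr,
         bmc_lb = NA_real_, bmc_median = NA_real_, bmc_ub = NA_real_,
         hit_confidence = 0, active = FALSE, n_boot = n_boot,
         low_n_boot = n_boot < 100, max_conc = max_tested,
         min_conc = NA_real_, samples = rep(NA_real_, n_boot))),
    class = "bmc_estimate")
  if (length(concs) < 2) return(inactive_estimate())

  boot_mat <- withr::with_seed(as.integer(seed), {
    if (inc) {
      m <- matrix(NA_real_, n_boot, length(concs))
      for (j in seq_along(concs)) {
        v <- sub$value[sub$concentration_uM == concs[j]]
        v <- v[!is.na(v)]
        m[, j] <- 100 * stats::rbinom(n_boot, length(v), mean(v)) / length(v)
      }
      m
    } else {
      plates <- unique(sub$plate_id)
      # per-boot control mean for each plate
      ctrl <- lapply(plates, function(p) {
        v <- sub$value[sub$plate_id == p & sub$concentration_uM == 0]
        v <- v[!is.na(v)]
        idx <- matrix(sample.int(length(v), n_boot * length(v), replace = TRUE),
                      n_boot)
        rowMeans(matrix(v[idx], n_boot))
      })
      names(ctrl) <- plates
      m <- matrix(NA_real_, n_boot, length(concs))
      for (j in seq_along(concs)) {
        pct <- matrix(NA_real_, n_boot, length(plates))
        for (k in seq_along(plates)) {
          v <- sub$value[sub$plate_id == plates[k] &
                         sub$concentration_uM == concs[j]]
          v <- v[!is.na(v)]
          if (!length(v)) next
          idx <- matrix(sample.int(length(v), n_boot * length(v),
                                   replace = TRUE), n_boot)
          tr <- rowMeans(matrix(v[idx], n_boot))
          pct[, k] <- 100 * (tr - ctrl[[k]]) / ctrl[[k]]
        }
        m[, j] <- rowMeans(pct, na.rm = TRUE)
      }
      s * m
    }
  })

  crossings <- apply(boot_mat, 1, function(r) {
    if (monotonize) r <- monotonize_response(r)
    bmr_crossing(concs, r, bmr$bmr)
  })
  finite <- crossings[is.finite(crossings)]
  hit_conf <- length(finite) / n_boot
  if (length(finite)) {
    q <- stats::quantile(finite, c(0.05, 0.5, 0.95), names = FALSE)
    est <- list(bmc_lb = q[1], bmc_median = q[2], bmc_ub = q[3])
  } else {
    est <- list(bmc_lb = NA_real_, bmc_median = NA_real_, bmc_ub = NA_real_)
  }
  structure(c(
    list(condition = sub$condition[1], readout = bmr$readout,
         worm_type = bmr$worm_type, day = bmr$day,
         direction = bmr$direction, bmr = bmr$bmr),
    est,
    list(hit_confidence = hit_conf,
         active = is.finite(est$bmc_median) &&
           est$bmc_median <= max_tested && hit_conf >= hit_threshold,
         n_boot = n_boot, low_n_boot = n_boot < 100,
         max_conc = max_tested, min_conc = min(concs),
         samples = crossings)),
    class = "bmc_estimate")
}

#' @export
print.bmc_estimate <- function(x, ...) {
  cat(sprintf("BMC estimate: %s / %s (%s, day %s, dir %s)\n",
              x$condition, x$readout, x$worm_type, x$day, x$direction))
  if (x$active)
    cat(sprintf("  median %.4g uM [%.4g, %.4g], hit confidence %.2f (n_boot %d)\n",
                x$bmc_median, x$bmc_lb, x$bmc_ub, x$hit_confidence, x$n_boot))
  else
    cat(sprintf("  inactive (hit confidence %.2f)\n", x$hit_confidence))
  invisible(x)
}

#' @export
as.data.frame.bmc_estimate <- function(x, ...) {
  data.frame(condition = x$condition, readout = x$readout,
             worm_type = x$worm_type, day = x$day, direction = x$direction,
             bmr = x$bmr, bmc_median = x$bmc_median, bmc_lb = x$bmc_lb,
             bmc_ub = x$bmc_ub, hit_confidence = x$hit_confidence,
             active = x$active, n_boot = x$n_boot,
             stringsAsFactors = FALSE)
}

#' Estimate BMCs for every condition and BMR series in a screen
#'
#' Applies [estimate_bmc()] to each condition in `records` crossed with
#' each applicable row of the BMR table (matching readout, worm type and
#' day present in the records). Per-series seeds are derived
#' deterministically from `seed`.
#'
#' @param records Long-format screen records (any number of conditions).
#' @param bmr_table BMR table (see [load_bmr_table()]); only rows whose
#'   readout/worm_type/day occur in `records` are used.
#' @inheritParams estimate_bmc
#' @return Data frame of estimates (one row per condition x BMR series).
#' @export
estimate_bmcs <- function(records, bmr_table, n_boot = 1000, seed = 1L,
                          monotonize = TRUE, hit_threshold = 0.5) {
  conds <- unique(records$condition)
  out <- list()
  k <- 0L
  for (cond in conds) {
    rc <- records[records$condition == cond, ]
    have <- unique(rc[c("readout", "worm_type", "day")])
    use <- merge(bmr_table, have)
    use <- use[order(use$readout, use$worm_type, use$day, use$direction), ]
    for (i in seq_len(nrow(use))) {
      k <- k + 1L
      est <- estimate_bmc(rc, use[i, ], n_boot = n_boot,
                          seed = (as.integer(seed) + 7919L * k) %% .Machine$integer.max,
                          monotonize = monotonize,
                          hit_threshold = hit_threshold)
      out[[k]] <- as.data.frame(est)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
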