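extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "planmix")
  if (p == "") stop("packaged fixture not found: ", file)
  p
}

read_fixture <- function(file) {
  utils::read.csv(extdata_path(file), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Packaged reference tables
#'
#' Loaders for the fixtures shipped with the package:
#' `load_bmr_table()` gives the benchmark responses per readout, worm type,
#' day and direction; `load_bmc_min_table()` the published per-mixture
#' minimum BMCs (experimental and CA-predicted) with their log10 ratios;
#' `load_ic50_table()` the day-12 AChE IC50s of the seven pesticides in
#' adult and regenerating planarians; `load_cpo_malo_params()` the stated
#' in-vitro oxon mixture design parameters (mixing ratio and preliminary
#' IC50s, stored verbatim). `fixture_checksums()` reports the MD5 of each
#' packaged fixture file.
#'
#' @return A data frame (or named character vector for
#'   `fixture_checksums()`).
#' @export
load_bmr_table <- function() read_fixture("bmr_table.csv")

#' @rdname load_bmr_table
#' @export
load_bmc_min_table <- function() read_fixture("bmc_min_table.csv")

#' @rdname load_bmr_table
#' @export
load_ic50_table <- function() read_fixture("ache_ic50_table.csv")

#' @rdname load_bmr_table
#' @export
load_cpo_malo_params <- function() read_fixture("cpo_malo_params.csv")

#' @rdname load_bmr_table
#' @export
fixture_checksums <- function() {
  files <- c("bmr_table.csv", "bmc_min_table.csv", "ache_ic50_table.csv",
             "cpo_malo_params.csv")
  sums <- vapply(files, function(f) unname(tools::md5sum(extdata_path(f))), "")
  sums
}

screen_columns <- c("condition", "concentration_uM", "worm_type", "day",
                    "plate_id", "well_id", "readout", "direction", "value",
                    "is_incidence")

#' Read and validate a long-format screen CSV
#'
#' Columns must match the screen-record schema (concentrations in uM per
#' component; `value` is the per-animal response, 0/1 for incidence
#' readouts). Malformed rows are rejected with their line numbers. Readout
#' names must appear in the benchmark table or be declared via
#' `extra_readouts`.
#'
#' @param path CSV path.
#' @param bmr_table Benchmark table defining known readouts.
#' @param extra_readouts Additional readout names to accept.
#' @return Validated data frame of screen records.
#' @export
read_screen_csv <- function(path, bmr_table = load_bmr_table(),
                            extra_readouts = NULL) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(screen_columns, names(d))
  if (length(missing_cols))
    stop("screen CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  bad_row <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop("invalid screen CSV: ", what, " at row(s) ",
           paste(utils::head(rows, 5), collapse = ", "),
           if (length(rows) > 5) " ..." else "")
  }
  bad_row(!is.finite(d$concentration_uM) | d$concentration_uM < 0,
          "negative or non-numeric concentration_uM")
  bad_row(!d$direction %in% c("+", "-", "n/a"), "unknown direction")
  bad_row(d$is_incidence & !is.na(d$value) & !d$value %in% c(0, 1),
          "incidence value not in {0, 1}")
  bad_row(!d$is_incidence & !is.na(d$value) & !is.finite(d$value),
          "non-finite continuous value")
  known <- union(unique(bmr_table$readout), extra_readouts)
  unknown <- setdiff(unique(d$readout), known)
  if (length(unknown))
    stop("unknown readout(s) not in the benchmark table and not declared: ",
         paste(unknown, collapse = ", "))
  d
}

#' Write screen records to CSV
#'
#' Serialises concentrations in plain decimal notation so that fixture
#' diffs stay readable; a header comment states units and the
#' per-component concentration convention. Round-trips losslessly through
#' [read_screen_csv()].
#'
#' @param records Screen-record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(records, path) {
  stopifnot(all(screen_columns %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# Long-format screen records; concentration_uM is per component",
    "# (an equimolar mixture well at c contains each agent at c uM)."),
    con)
  d <- records[screen_columns]
  d$concentration_uM <- format(d$concentration_uM, scientific = FALSE,
                               trim = TRUE)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write AChE activity CSVs
#'
#' Schema: condition, concentration_uM (total), replicate,
#' percent_activity (percent of solvent control; values outside [0, 100]
#' are legitimate and preserved).
#'
#' @param path CSV path.
#' @return Data frame of activity records.
#' @export
read_ache_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("condition", "concentration_uM", "replicate", "percent_activity")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("AChE CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(d$concentration_uM < 0)) stop("negative concentration in AChE CSV")
  d
}

#' @rdname read_ache_csv
#' @param records Activity records to write.
#' @export
write_ache_csv <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# AChE activity records; concentration_uM is the TOTAL mixture concentration.",
             con)
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Record simulation ground truth as JSON
#'
#' Writes every ground-truth parameter (per-readout curves, interaction
#' model, design, seed) alongside simulated data so a simulation is fully
#' reproducible and downstream recovery can be checked against truth.
#'
#' @param truths List of [agent_truth()] objects.
#' @param design The [screen_design()] used.
#' @param interaction Optional [interaction_truth()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truths, design, interaction = NULL, path) {
  if (inherits(truths, "agent_truth")) truths <- list(truths)
  # named atomic vectors become JSON objects, keeping per-readout names
  keep_names <- function(x)
    lapply(unclass(x), function(v)
      if (is.atomic(v) && !is.null(names(v))) as.list(v) else v)
  obj <- list(
    truths = lapply(truths, keep_names),
    design = unclass(design),
    interaction = if (!is.null(interaction)) keep_names(interaction))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full mixture-analysis pipeline
#'
#' Orchestrates simulate (optional) -> normalize -> BMC estimation -> CA
#' prediction -> interaction classification -> potency summary, writing
#' every stage as CSV plus a JSON report (seeds, fixture checksums, call
#' counts) into `config$output_dir`. Re-running with the same config
#' reproduces all outputs byte-for-byte.
#'
#' `config` is a list (or path to a YAML file with the same fields):
#' \describe{
#'   \item{scenario}{`"table3-replication"` (summarise the packaged
#'     published BMC_min fixture; no simulation), or `"simulate"` (run the
#'     synthetic screen defined by `agents`, `mixtures`, `design`).}
#'   \item{agents}{For `simulate`: named list of [agent_truth()] objects.}
#'   \item{mixtures}{For `simulate`: list of lists with `a`, `b` and
#'     optionally an [interaction_truth()] `interaction`.}
#'   \item{design}{A [screen_design()].}
#'   \item{n_boot, seed, hit_threshold, cap}{Stage parameters (defaults
#'     1000, 1, 0.5, 10).}
#'   \item{output_dir}{Directory for outputs (created if needed).}
#' }
#'
#' @param config Configuration list or YAML path.
#' @return Invisibly, a list with the stage tables and the report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(scenario = "table3-replication", n_boot = 1000, seed = 1L,
         hit_threshold = 0.5, cap = 10, output_dir = "planmix_output"),
    config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_file <- function(f) file.path(cfg$output_dir, f)
  report <- list(scenario = cfg$scenario, seed = cfg$seed,
                 n_boot = cfg$n_boot, hit_threshold = cfg$hit_threshold,
                 cap_uM = cfg$cap,
                 fixture_checksums = as.list(fixture_checksums()))
  result <- list()

  if (cfg$scenario == "table3-replication") {
    t3 <- load_bmc_min_table()
    obs <- data.frame(mixture = t3$mixture, worm_type = t3$worm_type,
                      readout = NA_character_,
                      bmc_median = t3$experimental_bmc_min)
    prd <- data.frame(mixture = t3$mixture, worm_type = t3$worm_type,
                      readout = NA_character_,
                      bmc_median = t3$predicted_bmc_min)
    summ <- potency_summary(obs, prd)
    utils::write.csv(summ, out_file("potency_summary.csv"), row.names = FALSE)
    result$potency_summary <- summ
    report$n_mixture_strata <- nrow(summ)
    report$n_finite_ratios <- sum(is.finite(summ$log10_ratio))
  } else if (cfg$scenario == "simulate") {
    stopifnot(!is.null(cfg$agents), !is.null(cfg$design))
    records <- do.call(rbind, lapply(cfg$agents, simulate_single_agent,
                                     design = cfg$design))
    for (mx in cfg$mixtures) {
      inter <- if (is.null(mx$interaction)) interaction_truth() else mx$interaction
      records <- rbind(records, simulate_mixture(
        cfg$agents[[mx$a]], cfg$agents[[mx$b]], inter, cfg$design))
    }
    write_screen_csv(records, out_file("screen_records.csv"))
    write_truth_json(cfg$agents, cfg$design, path = out_file("truth.json"))
    summaries <- normalize_responses(records)
    utils::write.csv(summaries, out_file("response_summaries.csv"),
                     row.names = FALSE)
    bmr <- cfg$bmr_table
    if (is.null(bmr)) bmr <- load_bmr_table()
    bmcs <- estimate_bmcs(records, bmr, n_boot = cfg$n_boot, seed = cfg$seed,
                          hit_threshold = cfg$hit_threshold)
    utils::write.csv(bmcs, out_file("bmc_estimates.csv"), row.names = FALSE)
    preds <- predict_mixture_table(bmcs, cfg$mixtures, cfg$agents,
                                   cap = cfg$cap)
    utils::write.csv(preds, out_file("ca_predictions.csv"), row.names = FALSE)
    mix_ids <- vapply(cfg$mixtures, function(m)
      paste(cfg$agents[[m$a]]$name, cfg$agents[[m$b]]$name, sep = "."), "")
    obs_mix <- bmcs[bmcs$condition %in% mix_ids, ]
    calls <- classify_interactions(
      obs_mix, preds,
      conc_range = range(cfg$design$concentrations))
    utils::write.csv(calls, out_file("interaction_calls.csv"),
                     row.names = FALSE)
    prd_tab <- data.frame(mixture = preds$condition,
                          worm_type = preds$worm_type,
                          readout = preds$readout,
                          bmc_median = preds$pred_median,
                          active = preds$pred_active)
    summ <- potency_summary(obs_mix, prd_tab)
    utils::write.csv(summ, out_file("potency_summary.csv"), row.names = FALSE)
    utils::write.csv(heatmap_table(calls, readout_order = unique(bmr$readout)),
                     out_file("heatmap_calls.csv"), row.names = FALSE)
    result <- list(records = records, summaries = summaries, bmcs = bmcs,
                   predictions = preds, calls = calls, potency_summary = summ)
    report$call_counts <- as.list(table(calls$call))
  } else {
    stop("unknown scenario: ", cfg$scenario)
  }

  jsonlite::write_json(report, out_file("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(sprintf("planmix pipeline run: scenario=%s seed=%d n_boot=%d",
                       cfg$scenario, as.integer(cfg$seed), as.integer(cfg$n_boot)),
               sprintf("fixture %s md5=%s", names(fixture_checksums()),
                       fixture_checksums())),
             out_file("pipeline.log"))
  result$report <- report
  invisible(result)
}

# CA predictions for every mixture x readout series present in a BMC table
predict_mixture_table <- function(bmcs, mixtures, agents, cap = 10) {
  rows <- list()
  for (mx in mixtures) {
    a <- agents[[mx$a]]$name; b <- agents[[mx$b]]$name
    mix_id <- paste(a, b, sep = ".")
    ea <- bmcs[bmcs$condition == a, ]
    eb <- bmcs[bmcs$condition == b, ]
    keys <- merge(ea[c("worm_type", "day", "readout", "direction")],
                  eb[c("worm_type", "day", "readout", "direction")])
    keys <- unique(keys)
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      pick <- function(d) {
        r <- d[d$worm_type == k$worm_type & d$day == k$day &
               d$readout == k$readout & d$direction == k$direction, ]
        list(active = isTRUE(r$active[1]), bmc_median = r$bmc_median[1],
             bmc_lb = r$bmc_lb[1], bmc_ub = r$bmc_ub[1])
      }
      e1 <- pick(ea); e2 <- pick(eb)
      if (!e1$active && !e2$active) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = mix_id, k, pred_median = NA_real_, pred_lb = NA_real_,
          pred_ub = NA_real_, pred_active = FALSE, rpf2 = NA_real_,
          capped = FALSE, row.names = NULL)
        next
      }
      pr <- predict_interval(e1, e2, cap = cap)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = mix_id, k,
        pred_median = pr$bmc_mix_per_component,
        pred_lb = pr$interval_lb, pred_ub = pr$interval_ub,
        pred_active = pr$active, rpf2 = pr$rpf2, capped = pr$capped,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
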