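#!/usr/bin/env Rscript
# Stage 3: concentration-addition predictions and interaction calls.
#
# For each mixture condition in the BMC table, predicts the equimolar
# mixture BMC from the single-agent estimates under Loewe additivity,
# compares observed and predicted intervals, and classifies every readout
# series as additive / synergistic / antagonistic / no_effect. Also writes
# the per-mixture minimum-BMC potency summary and the heatmap-shaped call
# table.

suppressPackageStartupMessages(library(planmix))

res_dir <- file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "..", "results")

bmcs <- utils::read.csv(file.path(res_dir, "bmc_estimates.csv"))
truth <- jsonlite::read_json(file.path(res_dir, "truth.json"))

agent_names <- vapply(truth$truths, function(t) t$name, "")
mix_ids <- grep(".", unique(bmcs$condition), fixed = TRUE, value = TRUE)
split_mix <- strsplit(mix_ids, ".", fixed = TRUE)
agents <- setNames(lapply(agent_names, function(n) list(name = n)),
                   agent_names)
mixtures <- lapply(split_mix, function(ab) list(a = ab[1], b = ab[2]))

preds <- planmix:::predict_mixture_table(bmcs, mixtures, agents, cap = 10)
utils::write.csv(preds, file.path(res_dir, "ca_predictions.csv"),
                 row.names = FALSE)

conc_range <- range(unlist(truth$design$concentrations))
obs_mix <- bmcs[bmcs$condition %in% mix_ids, ]
calls <- classify_interactions(obs_mix, preds, conc_range = conc_range)
utils::write.csv(calls, file.path(res_dir, "interaction_calls.csv"),
                 row.names = FALSE)

prd_tab <- data.frame(mixture = preds$condition, worm_type = preds$worm_type,
                      readout = preds$readout, bmc_median = preds$pred_median,
                      active = preds$pred_active)
summ <- potency_summary(obs_mix, prd_tab)
utils::write.csv(summ, file.path(res_dir, "potency_summary.csv"),
                 row.names = FALSE)
utils::write.csv(
  heatmap_table(calls, readout_order = unique(load_bmr_table()$readout)),
  file.path(res_dir, "heatmap_calls.csv"), row.names = FALSE)

cat("interaction calls:\n")
print(table(calls$readout, calls$call))
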