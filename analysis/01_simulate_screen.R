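#!/usr/bin/env Rscript
# Stage 1: simulate a small behavioral screen.
#
# Two hypothetical organophosphorus-like agents are screened singly and as
# equimolar binary mixtures on four regenerating day-12 readouts. One
# mixture is truly concentration-additive; the other hides a tenfold
# synergistic potency shift on stickiness. Everything downstream
# (02-03) works only from the records written here, as it would for a
# real screen; the generating truth is stored alongside for the record.

suppressPackageStartupMessages(library(planmix))

out_dir <- file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "..", "results")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

per_readout <- function(lethality, stickiness, speed_dark, resting_dark)
  c(lethality = lethality, stickiness = stickiness,
    speed_dark = speed_dark, resting_dark = resting_dark)

shared <- list(
  hill = per_readout(2, 1.5, 1.2, 1),
  max_effect = per_readout(100, 100, 80, 90),
  direction = per_readout("+", "+", "-", "+"),
  is_incidence = c(lethality = TRUE, stickiness = TRUE,
                   speed_dark = FALSE, resting_dark = FALSE))

agent_P <- do.call(agent_truth, c(list(
  name = "P", ec50 = per_readout(3.16, 0.5, 2, 1.5),
  ache_ic50 = 1, ache_hill = 1.3), shared))
agent_Q <- do.call(agent_truth, c(list(
  name = "Q", ec50 = per_readout(6.3, 1.5, 4, 3),
  ache_ic50 = 13.6, ache_hill = 1.3), shared))

design <- screen_design(worm_types = "regenerating", days = 12, seed = 20260101L)

records <- rbind(
  simulate_single_agent(agent_P, design),
  simulate_single_agent(agent_Q, design),
  # P.Q: truly additive mixture
  simulate_mixture(agent_P, agent_Q, interaction_truth(), design),
  # P.P sham with a hidden tenfold potency shift on stickiness
  simulate_mixture(agent_P, agent_P,
                   interaction_truth("potency_shift", shift_factor = 10,
                                     applies_to = "stickiness"),
                   design))

write_screen_csv(records, file.path(out_dir, "screen_records.csv"))
write_truth_json(list(agent_P, agent_Q), design,
                 path = file.path(out_dir, "truth.json"))
cat("wrote", nrow(records), "screen records for",
    length(unique(records$condition)), "conditions\n")
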