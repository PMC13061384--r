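#!/usr/bin/env Rscript
# Stage 2: normalize responses and estimate benchmark concentrations.
#
# Reads the screen records from stage 1, converts raw per-animal values
# into percent responses relative to in-plate controls, and estimates a
# bootstrap BMC (median and 5th-95th percentile interval) for every
# condition x readout series against the packaged benchmark-response
# levels.

suppressPackageStartupMessages(library(planmix))

res_dir <- file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "..", "results")

records <- read_screen_csv(file.path(res_dir, "screen_records.csv"))
bmr_all <- load_bmr_table()
bmr <- bmr_all[bmr_all$worm_type == "regenerating" & bmr_all$day == 12 &
                 bmr_all$readout %in% unique(records$readout), ]

summaries <- normalize_responses(records)
utils::write.csv(summaries, file.path(res_dir, "response_summaries.csv"),
                 row.names = FALSE)

bmcs <- estimate_bmcs(records, bmr, n_boot = 1000, seed = 20260102L)
utils::write.csv(bmcs, file.path(res_dir, "bmc_estimates.csv"),
                 row.names = FALSE)
cat("estimated", nrow(bmcs), "BMC series;",
    sum(bmcs$active), "active\n")
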