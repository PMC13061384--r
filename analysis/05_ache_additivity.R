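#!/usr/bin/env Rscript
# Stage 5: in-vitro enzyme-inhibition arm.
#
# Simulates AChE activity assays for two agents and their constant-ratio
# mixture, fits fixed-asymptote log-logistic curves, derives the
# concentration-addition prediction for the mixture curve, and runs the
# logit-equivalence slope test of observed against expected inhibition.

suppressPackageStartupMessages(library(planmix))

res_dir <- file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "..", "results")
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

pp <- load_cpo_malo_params()
val <- function(p) pp$value[pp$parameter == p]
ratio <- val("cpo_malo_ratio")               # [fast] / [slow] molar ratio
f_fast <- ratio / (1 + ratio)                # fraction of the fast inhibitor

fast <- agent_truth("FASTOX", ec50 = c(lethality = 1e6),
                    hill = c(lethality = 1), max_effect = c(lethality = 100),
                    direction = c(lethality = "+"),
                    is_incidence = c(lethality = TRUE),
                    ache_ic50 = val("cpo_preliminary_ic50"), ache_hill = 1.3)
slow <- agent_truth("SLOWOX", ec50 = c(lethality = 1e6),
                    hill = c(lethality = 1), max_effect = c(lethality = 100),
                    direction = c(lethality = "+"),
                    is_incidence = c(lethality = TRUE),
                    ache_ic50 = val("malo_preliminary_ic50"), ache_hill = 1.3)

conc <- 10^seq(-2, 2.5, length.out = 10)
assay <- rbind(
  simulate_ache_assay(fast, 1, concentrations = conc, replicates = 3,
                      noise_sd = 3, seed = 501L),
  simulate_ache_assay(slow, 1, concentrations = conc, replicates = 3,
                      noise_sd = 3, seed = 502L),
  simulate_ache_assay(list(fast, slow), c(f_fast, 1 - f_fast),
                      concentrations = conc, replicates = 3,
                      noise_sd = 3, seed = 503L))
write_ache_csv(assay, file.path(res_dir, "ache_activity.csv"))

fit_of <- function(cond) fit_log_logistic(assay[assay$condition == cond, ])
fit_fast <- fit_of("FASTOX"); fit_slow <- fit_of("SLOWOX")
mix_cond <- setdiff(unique(assay$condition), c("FASTOX", "SLOWOX"))
mix <- assay[assay$condition == mix_cond, ]

ic50_mix_pred <- predict_mixture_icp(fit_fast, fit_slow, f1 = f_fast, p = 50)
curve <- predicted_curve(fit_fast, fit_slow, f1 = f_fast)
utils::write.csv(curve, file.path(res_dir, "ache_predicted_curve.csv"),
                 row.names = FALSE)

line_fast <- fit_logit_line(assay[assay$condition == "FASTOX", ])
line_slow <- fit_logit_line(assay[assay$condition == "SLOWOX", ])
exp_mix <- expected_inhibition(mix$concentration_uM * f_fast,
                               mix$concentration_uM * (1 - f_fast),
                               line_fast, line_slow)
obs_inh <- pmin(pmax(100 - mix$percent_activity, 0.5), 99.5)
test <- slope_test(log(obs_inh / (100 - obs_inh)), exp_mix$expected_logit,
                   concentration = mix$concentration_uM)

summary_tab <- data.frame(
  ic50_fast = fit_fast$ic50, ic50_slow = fit_slow$ic50,
  ic50_mix_predicted = ic50_mix_pred,
  slope_estimate = test$slope_estimate, slope_se = test$slope_se,
  p_value = test$p_value, reject_additivity = test$reject_at_alpha)
utils::write.csv(summary_tab, file.path(res_dir, "ache_summary.csv"),
                 row.names = FALSE)

cat(sprintf("fitted IC50s: %.3g / %.3g uM; predicted mixture IC50 %.3g uM\n",
            fit_fast$ic50, fit_slow$ic50, ic50_mix_pred))
print(test)
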