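#!/usr/bin/env Rscript
# Stage 2 — direct versus indirect assessments of risk and reward.
#
# Builds observed/available step designs (10 available steps per observed
# step, gamma step lengths, uniform turning angles), attaches the habitat
# covariates, the indirect occurrence surfaces, and the direct metrics
# (log minimum of distance x time-since over lion locations and kills),
# VIF-prunes, standardizes, fits the five candidate conditional-logistic
# models clustered by coyote and ranks them by QIC.
#
# In the default scenario the coyotes were simulated to respond to the
# indirect surfaces only, so the indirect-only model should rank first —
# the same ordering reported for the field system.

library(mesorisk)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

sc <- simulate_scenario(seed = seed)
ic <- run_issf_comparison(sc, seed = seed, out_dir = "results/issf")

message("model ranking (QIC):")
print(ic$ranking, row.names = FALSE)
message(sprintf("best model: %s (%d strata; %d strata dropped for missing covariates)",
                ic$best, ic$n_strata, ic$n_strata_dropped))
b <- ic$coef_table
# generative truth was -0.5 / +0.3 on the landscape-standardized scale;
# the fitted scale standardizes over the step design, so magnitudes shift
# slightly while signs and significance carry over
message(sprintf("IndirectLion beta = %.3f (z = %.2f)  [generative truth -0.5]",
                b$beta[b$predictor == "IndirectLion"],
                b$z[b$predictor == "IndirectLion"]))
message(sprintf("IndirectKill beta = %.3f (z = %.2f)  [generative truth +0.3]",
                b$beta[b$predictor == "IndirectKill"],
                b$z[b$predictor == "IndirectKill"]))
message("outputs in results/issf/")
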