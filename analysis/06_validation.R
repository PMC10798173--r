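#!/usr/bin/env Rscript
# Validation experiments: does the analysis machinery measure what the
# generator plants, and does it control its error rates? Scaled-down
# versions of the full harnesses (the full sizes run in the test suite
# and the acceptance script); results land in results/validation.json.

library(tempopred)

set.seed(20260402L)
out <- list()

rec <- recover_global_slopes(n_reps = 5)
cat(sprintf("recovery (5 cohorts): accuracy %.2f pp / 25 ms (planted 0.6), RT %.2f ms / 25 ms (planted 5)\n",
            mean(rec$acc_decline_pp), mean(rec$rt_slope_ms)))
out$recovery <- list(acc_decline_pp = mean(rec$acc_decline_pp),
                     rt_slope_ms = mean(rec$rt_slope_ms), n_reps = 5)

pc <- staircase_calibration(n_reps = 100)
cat(sprintf("staircase: %.1f%% correct at converged SNR (3-down-1-up aims at 79.4%%)\n",
            mean(pc)))
out$staircase_pc <- list(mean = mean(pc), sd = sd(pc), n_reps = 100)

fw <- cluster_fwer(n_datasets = 100)
cat(sprintf("cluster FWER on pure noise: %.3f (nominal 0.05)\n", fw$fwer))
out$cluster_fwer <- list(fwer = fw$fwer, n_datasets = 100)

wd <- wald_slope_type1(n_reps = 100)
cat(sprintf("Wald slope type-I error: %.3f (nominal 0.05)\n", wd$rate))
out$wald_type1 <- list(rate = wd$rate, n_reps = 100)

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(out, "results/validation.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/validation.json\n")
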