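#!/usr/bin/env Rscript
# Rhythmicity-rating analyses: outlier-rater exclusion (Tukey fences on
# per-subject rating-vs-STD slopes), the rating-on-STD linear mixed
# model, and the LRT asking whether the rating adds explanatory power to
# the accuracy model beyond the global STD. Also assembles the overall
# run report. Requires the earlier scripts' artifacts in results/run/.

library(tempopred)

cfg <- default_config(seed = 20260401L)
out <- "results/run"
run_all(cfg, out, stages = "analyze_rating")

res <- jsonlite::read_json(file.path(out, "rating_results.json"))
cat(sprintf("\nExcluded raters: %s\n",
            if (length(res$excluded_subjects)) {
              paste(unlist(res$excluded_subjects), collapse = ", ")
            } else "none"))
w <- res$rating_on_std$wald[[1]]
cat(sprintf("Rating ~ global STD: Wald chi2(%d) = %.2f, p = %.3g\n",
            w$df, w$chi2, w$p))
cat(sprintf("Adding rating to the accuracy model: chi2(%d) = %.2f, p = %.3g\n",
            res$lrt_add_rating$df, res$lrt_add_rating$chi2,
            res$lrt_add_rating$p))
cat("\nRatings track the STD (planted). Conditional on the STD the rating\n")
cat("noise is independent of accuracy, yet the 0-10 clamping makes the\n")
cat("rating a mildly nonlinear proxy of the STD, so at full cohort size\n")
cat("the LRT can still pick up residual nonlinearity the linear STD term\n")
cat("misses - judge the chi-square against that, not against zero.\n")

rep <- report(jsonlite::read_json(file.path(out, "manifest.json")), out)
cat("\nreport.json / report.txt written under", out, "\n")
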