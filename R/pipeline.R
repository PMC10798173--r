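# End-to-end orchestration: simulate -> features -> global models ->
# local cluster analysis -> local/global interplay -> ratings -> report.
# Every stage reads and writes only declared CSV/JSON artifacts under the
# output directory, and the manifest records files, checksums, and
# timings so deterministic stages can be verified byte-for-byte.

stage_log <- function(fmt, ...) message(sprintf(fmt, ...))

run_stage <- function(manifest, name, out_dir, fun) {
  t0 <- Sys.time()
  files <- fun()
  secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$stages[[name]] <- list(
    files = files,
    checksums = as.list(tools::md5sum(files)),
    seconds = round(secs, 2)
  )
  stage_log("stage %-18s %5.1fs  %s", name, secs,
            paste(basename(files), collapse = ", "))
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order on a freshly simulated cohort and writes
#' the artifacts under `out_dir`: `trials.csv` (full stream),
#' `targets.csv`, `ratings.csv`, `features.csv`, `global_results.json`,
#' `contrasts_*.csv`, `local_results.json`, `odds_ratios.csv`,
#' `rating_results.json`, `manifest.json`.
#'
#' @param config A [default_config()]-shaped list.
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages to run (default all, in
#'   order).
#' @return The run manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_all <- function(config = default_config(), out_dir,
                    stages = c("simulate", "features", "analyze_global",
                               "analyze_local", "analyze_interplay",
                               "analyze_rating")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  manifest <- list(config = config, stages = list(),
                   package_version = as.character(
                     utils::packageVersion("tempopred")))
  observer <- do.call(observer_params, config$observer)
  cohort <- NULL

  if ("simulate" %in% stages) {
    manifest <- run_stage(manifest, "simulate", out_dir, function() {
      cohort <<- simulate_cohort(config$n_subjects, observer,
                                 seed = config$seed,
                                 conditions = default_conditions(config$conditions))
      write_trials_csv(cohort$stream, pth("trials.csv"))
      write_table_csv(cohort$targets, pth("targets.csv"))
      write_table_csv(cohort$ratings, pth("ratings.csv"))
      stage_log("  simulated %d subjects, %d trials (%d targets)",
                config$n_subjects, nrow(cohort$stream), nrow(cohort$targets))
      pth(c("trials.csv", "targets.csv", "ratings.csv"))
    })
  }

  load_targets <- function() {
    d <- utils::read.csv(pth("targets.csv"), stringsAsFactors = FALSE)
    tibble::as_tibble(d)
  }
  load_ratings <- function() {
    tibble::as_tibble(utils::read.csv(pth("ratings.csv"),
                                      stringsAsFactors = FALSE))
  }

  if ("features" %in% stages) {
    manifest <- run_stage(manifest, "features", out_dir, function() {
      # recompute history features from the serialized stream, so the
      # features artifact does not depend on in-memory state
      stream <- read_trials_csv(pth("trials.csv"))
      targets <- load_targets()
      feats <- features_from_stream(stream)
      keep <- c("subject", "block", "trial_index", "correct", "rt_ms")
      out <- dplyr::inner_join(
        feats, targets[keep], by = c("subject", "block", "trial_index"))
      write_table_csv(out, pth("features.csv"))
      stage_log("  %d target feature rows", nrow(out))
      pth("features.csv")
    })
  }

  if ("analyze_global" %in% stages) {
    manifest <- run_stage(manifest, "analyze_global", out_dir, function() {
      targets <- load_targets()
      res <- analyze_global(targets)
      jsonlite::write_json(res$summary, pth("global_results.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_table_csv(res$contrasts_acc, pth("contrasts_accuracy.csv"))
      write_table_csv(res$contrasts_rt, pth("contrasts_rt.csv"))
      pth(c("global_results.json", "contrasts_accuracy.csv",
            "contrasts_rt.csv"))
    })
  }

  if ("analyze_local" %in% stages) {
    manifest <- run_stage(manifest, "analyze_local", out_dir, function() {
      feats <- tibble::as_tibble(utils::read.csv(pth("features.csv"),
                                                 stringsAsFactors = FALSE))
      res <- analyze_local(feats, config)
      jsonlite::write_json(res, pth("local_results.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      pth("local_results.json")
    })
  }

  if ("analyze_interplay" %in% stages) {
    manifest <- run_stage(manifest, "analyze_interplay", out_dir, function() {
      feats <- tibble::as_tibble(utils::read.csv(pth("features.csv"),
                                                 stringsAsFactors = FALSE))
      ors <- dplyr::bind_rows(lapply(config$analysis$n_local, function(N)
        fit_local_global(feats, N, "accuracy")))
      ors$fit <- NULL
      write_table_csv(ors, pth("odds_ratios.csv"))
      pth("odds_ratios.csv")
    })
  }

  if ("analyze_rating" %in% stages) {
    manifest <- run_stage(manifest, "analyze_rating", out_dir, function() {
      targets <- load_targets()
      ratings <- load_ratings()
      excl <- tryCatch(exclude_outlier_raters(ratings), error = function(e) {
        warning("rating outlier exclusion skipped: ", conditionMessage(e))
        list(kept = unique(ratings$subject), excluded = character(0),
             fences = c(lower = NA_real_, upper = NA_real_))
      })
      kept <- targets$subject %in% excl$kept
      rm_res <- rating_models(targets[kept, ],
                              ratings[ratings$subject %in% excl$kept, ])
      res <- list(
        excluded_subjects = excl$excluded,
        slope_fences = as.list(excl$fences),
        lrt_add_rating = unclass(rm_res$lrt_rating),
        rating_on_std = list(
          fixed = as.data.frame(rm_res$rating_on_std$fixed),
          wald = as.data.frame(wald_type2(rm_res$rating_on_std))
        )
      )
      jsonlite::write_json(res, pth("rating_results.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      pth("rating_results.json")
    })
  }

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' History features for every target of a serialized trial stream
#'
#' @param stream Long trial table ([read_trials_csv()] schema) covering
#'   whole blocks.
#' @return Tibble of per-target history features with `subject`, `block`,
#'   `condition_std_ms` identifiers.
#' @export
features_from_stream <- function(stream) {
  parts <- split(stream, list(stream$subject, stream$block), drop = TRUE)
  rows <- lapply(parts, function(d) {
    d <- d[order(d$trial_index), ]
    blk <- structure(list(condition = condition_spec(d$condition_std_ms[1]),
                          trials = d), class = "oddball_block")
    tibble::tibble(subject = d$subject[1], block = d$block[1],
                   condition_std_ms = d$condition_std_ms[1],
                   compute_history_features(blk))
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$subject, out$block, out$trial_index), ]
}

#' Global-STD analyses of accuracy and response time
#'
#' Fits the continuous global-STD mixed models (binomial logit for
#' accuracy; gamma for RT, log link by default with the identity link also
#' fitted for the ms-scale slope), compares random-intercept vs
#' random-slope structures by LRT, runs Type II Wald tests, Tukey
#' post-hoc contrasts over the six condition levels, and repeats the
#' accuracy/RT models restricted to targets preceded by a 500 ms SOA.
#'
#' @param targets Target-level table (`subject`, `condition_std_ms`,
#'   `correct`, `rt_ms`, `last_soa_ms`).
#' @return List with `summary` (JSON-ready), `contrasts_acc`,
#'   `contrasts_rt`, and the fitted models.
#' @export
analyze_global <- function(targets) {
  d <- as.data.frame(targets)
  d$std25 <- d$condition_std_ms / 25
  d$condition <- factor(d$condition_std_ms)

  acc0 <- fit_glmm(correct ~ std25 + (1 | subject), d, family = "binomial")
  acc1 <- tryCatch(
    fit_glmm(correct ~ std25 + (std25 | subject), d, family = "binomial"),
    error = function(e) NULL)
  lrt_acc_slope <- if (!is.null(acc1)) lrt(acc0, acc1) else NULL
  acc_best <- if (!is.null(lrt_acc_slope) && isTRUE(lrt_acc_slope$p < 0.05))
    acc1 else acc0

  rt0 <- fit_glmm(rt_ms ~ std25 + (1 | subject), d, family = "gamma")
  rt1 <- tryCatch(
    fit_glmm(rt_ms ~ std25 + (std25 | subject), d, family = "gamma"),
    error = function(e) NULL)
  lrt_rt_slope <- if (!is.null(rt1)) lrt(rt0, rt1) else NULL
  rt_best <- if (!is.null(lrt_rt_slope) && isTRUE(lrt_rt_slope$p < 0.05)) rt1 else rt0
  rt_ident <- fit_glmm(rt_ms ~ std25 + (std25 | subject), d,
                       family = "gamma", link = "identity")

  acc_fac <- fit_glmm(correct ~ condition + (1 | subject), d,
                      family = "binomial")
  rt_fac <- fit_glmm(rt_ms ~ condition + (1 | subject), d, family = "gamma")
  contrasts_acc <- pairwise_tukey(acc_fac)
  contrasts_rt <- pairwise_tukey(rt_fac)

  d500 <- restrict_to_mean_soa(d)
  acc500 <- fit_glmm(correct ~ std25 + (1 | subject), d500,
                     family = "binomial")
  rt500 <- fit_glmm(rt_ms ~ std25 + (1 | subject), d500, family = "gamma")

  ame_acc <- average_marginal_effect(acc_best, d, "std25")
  summary <- list(
    n_targets = nrow(d),
    accuracy = list(
      fixed = as.data.frame(acc_best$fixed),
      wald = as.data.frame(wald_type2(acc_best)),
      lrt_random_slope = if (!is.null(lrt_acc_slope))
        unclass(lrt_acc_slope),
      ame_per_25ms_pp = 100 * ame_acc,
      restricted_500 = list(fixed = as.data.frame(acc500$fixed),
                            wald = as.data.frame(wald_type2(acc500)))
    ),
    rt = list(
      fixed = as.data.frame(rt_best$fixed),
      wald = as.data.frame(wald_type2(rt_best)),
      lrt_random_slope = if (!is.null(lrt_rt_slope)) unclass(lrt_rt_slope),
      identity_slope_ms_per_25ms =
        rt_ident$fixed$estimate[rt_ident$fixed$term == "std25"],
      restricted_500 = list(fixed = as.data.frame(rt500$fixed),
                            wald = as.data.frame(wald_type2(rt500)))
    )
  )
  list(summary = summary, contrasts_acc = contrasts_acc,
       contrasts_rt = contrasts_rt,
       fits = list(acc = acc_best, rt = rt_best, rt_identity = rt_ident))
}

#' Local-history cluster analyses
#'
#' For each configured (N_mean, N_std) pair, condition subset, and measure
#' (accuracy, RT): per-participant 2-D binned maps, per-participant
#' z-scoring, intersection masking, and the sign-flip cluster permutation
#' test.
#'
#' @param feats Per-target feature rows ([features_from_stream()] joined
#'   with responses).
#' @param config Run configuration ([default_config()]).
#' @return JSON-ready list of test records keyed
#'   `"<subset>.N<mean>_<std>.<measure>"`.
#' @export
analyze_local <- function(feats, config = default_config()) {
  an <- config$analysis
  out <- list()
  for (subset_name in names(an$condition_subsets)) {
    stds <- an$condition_subsets[[subset_name]]
    sub <- feats[feats$condition_std_ms %in% stds, ]
    for (pair in an$local_pairs) {
      for (measure in c("acc", "rt")) {
        maps <- lapply(split(sub, sub$subject), function(d)
          bin_performance_map(d, pair[1], pair[2],
                              min_count = an$min_count))
        zmaps <- tryCatch(
          lapply(maps, zscore_map, measure = measure),
          warning = function(w) NULL)
        rec_name <- sprintf("%s.N%d_%d.%s", subset_name, pair[1], pair[2],
                            measure)
        if (is.null(zmaps)) {
          out[[rec_name]] <- list(skipped = "degenerate z-map")
          next
        }
        grp <- tryCatch(stack_group(zmaps), error = function(e) NULL)
        if (is.null(grp) || nrow(grp$data) < 2) {
          out[[rec_name]] <- list(skipped = "no jointly valid bins")
          next
        }
        ct <- permutation_test(grp$data, grp$mask, grp$dims,
                               n_perm = an$n_perm,
                               alpha_form = an$alpha_form,
                               seed = config$seed)
        out[[rec_name]] <- cluster_test_record(ct)
        stage_log("  %s: %d clusters (%d significant)", rec_name,
                  length(ct$clusters),
                  sum(vapply(ct$clusters, `[[`, TRUE, "significant")))
      }
    }
  }
  out
}

#' Assemble a human-readable run report
#'
#' Reads the stage artifacts listed in a manifest and assembles a single
#' JSON summary plus a plain-text digest. Values are copied from the
#' artifacts without recomputation; missing stages are flagged as absent.
#'
#' @param manifest A [run_all()] manifest (or path to `manifest.json`).
#' @param out_dir Directory holding the stage artifacts.
#' @return List with `json` (the summary, also written to `report.json`)
#'   and `text` (lines also written to `report.txt`).
#' @export
report <- function(manifest, out_dir) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  pth <- function(f) file.path(out_dir, f)
  have <- function(f) file.exists(pth(f))
  summary <- list(seed = manifest$config$seed,
                  package_version = manifest$package_version,
                  sections = list())
  lines <- c(sprintf("tempopred run report (seed %s)", manifest$config$seed))

  if (have("targets.csv")) {
    targ <- utils::read.csv(pth("targets.csv"))
    by_cond <- do.call(rbind, lapply(split(targ, targ$condition_std_ms),
      function(d) data.frame(condition_std_ms = d$condition_std_ms[1],
                             acc = mean(d$correct), rt = mean(d$rt_ms),
                             n = nrow(d))))
    by_cond <- by_cond[order(by_cond$condition_std_ms), ]
    summary$sections$per_condition <- by_cond
    lines <- c(lines, "per-condition means:",
               sprintf("  STD %3d ms: accuracy %.3f, RT %.1f ms (n=%d)",
                       by_cond$condition_std_ms, by_cond$acc, by_cond$rt,
                       by_cond$n))
  } else {
    summary$sections$per_condition <- "absent"
    lines <- c(lines, "simulate stage output absent")
  }
  for (f in c("global_results.json", "local_results.json",
              "rating_results.json")) {
    key <- sub("_results.json", "", f)
    if (have(f)) {
      summary$sections[[key]] <- jsonlite::read_json(pth(f))
      lines <- c(lines, sprintf("%s results: present", key))
    } else {
      summary$sections[[key]] <- "absent"
      lines <- c(lines, sprintf("%s results: ABSENT", key))
    }
  }
  if (have("odds_ratios.csv")) {
    summary$sections$interplay <- utils::read.csv(pth("odds_ratios.csv"))
    lines <- c(lines, "interplay odds ratios: present")
  } else {
    summary$sections$interplay <- "absent"
    lines <- c(lines, "interplay odds ratios: ABSENT")
  }
  jsonlite::write_json(summary, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(lines, pth("report.txt"))
  list(json = summary, text = lines)
}
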