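# Plain-text artifact I/O: long-format trial CSVs, feature and map tables,
# JSON summaries, and the YAML run configuration. Readers validate schemas
# strictly so silent column drift fails loudly.

trials_schema <- c("subject", "block", "condition_std_ms", "trial_index",
                   "soa_ms", "is_target", "is_deviant")

#' Write / read the long-format trials CSV
#'
#' Header `subject,block,condition_std_ms,trial_index,soa_ms,is_target,
#' is_deviant`; `soa_ms` is empty for the first trial of each block and
#' the flags are 0/1. Target rows may additionally carry `correct` and
#' `rt_ms`.
#'
#' @param trials Trial table (e.g. from [session_trials()] or the
#'   `stream`/`targets` component of [simulate_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  stopifnot(all(trials_schema %in% names(trials)))
  out <- as.data.frame(trials)
  out$is_target <- as.integer(out$is_target)
  out$is_deviant <- as.integer(out$is_deviant)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trials_schema, names(d))
  if (length(missing)) {
    stop("trials CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(d$is_target %in% 0:1) || !all(d$is_deviant %in% 0:1)) {
    stop("trial flags must be 0/1", call. = FALSE)
  }
  if (any(d$is_deviant == 1 & d$is_target == 0)) {
    stop("deviant flag set on a standard trial", call. = FALSE)
  }
  d$is_target <- d$is_target == 1
  d$is_deviant <- d$is_deviant == 1
  tibble::as_tibble(d)
}

#' Write a generic results table as CSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a cluster test result to JSON-ready form
#'
#' @param ct A [permutation_test()] result.
#' @return A plain list (t-map as tidy records, clusters with bins, stats
#'   and p-values, reference-distribution summary) suitable for
#'   [jsonlite::write_json()].
#' @export
cluster_test_record <- function(ct) {
  stopifnot(inherits(ct, "cluster_test"))
  list(
    n_participants = ct$n,
    n_valid_bins = sum(ct$mask),
    n_perm = ct$n_perm,
    alpha_form = ct$alpha_form,
    seed = ct$seed,
    crit = as.numeric(ct$crit),
    tmap = data.frame(bin = which(ct$mask),
                      t = ct$tmap[ct$mask], p = ct$pmap[ct$mask]),
    clusters = lapply(ct$clusters, function(cl)
      list(bins = cl$bins, stat = cl$stat, sign = cl$sign, p = cl$p,
           significant = cl$significant))
  )
}

#' Default run configuration
#'
#' All defaults mirror the experimental design: 19 subjects, 12 blocks (2
#' per condition), 6 conditions with STDs 0-150 ms, 410 trials and 56
#' targets per block, 1000 sign-flip permutations.
#'
#' @param seed Master seed for the run.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_subjects = 19L,
    conditions = c(0, 25, 50, 75, 100, 150),
    observer = unclass(observer_params()),
    analysis = list(
      n_local = 2:7,
      local_pairs = list(c(2, 2), c(4, 4), c(6, 6)),
      condition_subsets = list(
        all_nonperiodic = c(25, 50, 75, 100, 150),
        low = c(25, 50),
        high = c(75, 100, 150)
      ),
      n_perm = 1000L,
      alpha_form = 0.05,
      min_count = 5L
    )
  )
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return The configuration list (reader) or `path` (writer, invisibly).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  cfg <- utils::modifyList(base, cfg)
  cfg$observer <- do.call(observer_params,
                          cfg$observer[names(cfg$observer) %in%
                                         names(formals(observer_params))])
  cfg$observer <- unclass(cfg$observer)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
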