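# Oddball stimulus timelines: constrained target placement and SOA streams.
#
# A block is 410 trials, 56 of them targets. Targets cannot occur in the
# first 10 trials and must be separated by 4-10 standards. Jointly these
# constraints are tighter than iid uniform gaps (mean gap 7 would need 441+
# trials), so target layouts are sampled uniformly over the set of feasible
# compositions via dynamic-programming composition counting.

# Count bounded-part compositions: counts[j, s + 1] = number of ways to
# write s using parts j..K with the given bounds. Doubles are exact enough
# here (relative error ~1e-15 on astronomically large counts). Each row is
# a windowed sum of the next (a cumulative-sum convolution), and tables
# are cached per bound signature since the design reuses one layout.
.composition_cache <- new.env(parent = emptyenv())

composition_counts <- function(lo, hi, total) {
  key <- paste(c(lo, hi, total), collapse = ",")
  hit <- .composition_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- length(lo)
  counts <- matrix(0, nrow = k + 1L, ncol = total + 1L)
  counts[k + 1L, 1L] <- 1
  for (j in k:1) {
    cs <- cumsum(counts[j + 1L, ])
    s <- 0:total
    upper_idx <- pmin(s - lo[j], total) + 1L   # index of F(s - lo)
    lower_idx <- s - hi[j]                      # index of F(s - hi - 1)
    row <- ifelse(upper_idx >= 1L, cs[pmax(upper_idx, 1L)], 0) -
      ifelse(lower_idx >= 1L, cs[pmax(lower_idx, 1L)], 0)
    row[upper_idx < 1L] <- 0
    counts[j, ] <- row
  }
  .composition_cache[[key]] <- counts
  counts
}

#' Sample a feasible target layout for one block
#'
#' Partitions the standards of a block into a prefix (before the first
#' target), inter-target gaps, and a tail (after the last target), drawing
#' uniformly over all partitions that satisfy the design constraints:
#' prefix of at least `prefix_min` standards, every gap in
#' `[gap_min, gap_max]`.
#'
#' The prefix is bounded above at `prefix_min + (gap_max - gap_min)` and
#' the tail at `gap_max`; uniformity is over the feasible compositions
#' under those bounds, achieved by sequential conditional sampling against
#' a composition-count table.
#'
#' @param n_targets Number of targets (design default 56).
#' @param n_trials Number of trials in the block (design default 410).
#' @param prefix_min Minimum number of leading standards (design default 10).
#' @param gap_min,gap_max Bounds on standards between consecutive targets.
#' @param prefix_max,tail_max Upper bounds for prefix and tail; defaults
#'   derived from the gap range as described above.
#' @return List with integer fields `prefix`, `gaps` (length
#'   `n_targets - 1`), and `tail`; `prefix + sum(gaps) + tail + n_targets`
#'   equals `n_trials`.
#' @export
sample_target_gaps <- function(n_targets, n_trials,
                               prefix_min = 10,
                               gap_min = 4, gap_max = 10,
                               prefix_max = prefix_min + (gap_max - gap_min),
                               tail_max = gap_max) {
  stopifnot(n_targets >= 1, n_trials > n_targets)
  n_standards <- n_trials - n_targets
  lo <- c(prefix_min, rep(gap_min, n_targets - 1L), 0L)
  hi <- c(prefix_max, rep(gap_max, n_targets - 1L), tail_max)
  if (sum(lo) > n_standards || sum(hi) < n_standards) {
    stop(sprintf(paste0(
      "infeasible layout: %d standards cannot be split into prefix ",
      "[%d,%d], %d gaps in [%d,%d] and tail [0,%d]"),
      n_standards, prefix_min, prefix_max, n_targets - 1L, gap_min, gap_max,
      tail_max), call. = FALSE)
  }
  counts <- composition_counts(lo, hi, n_standards)
  parts <- integer(length(lo))
  s <- n_standards
  for (j in seq_along(lo)) {
    vals <- lo[j]:hi[j]
    vals <- vals[vals <= s]
    w <- counts[j + 1L, s - vals + 1L]
    parts[j] <- if (length(vals) == 1L) vals else
      vals[sample.int(length(vals), 1L, prob = w)]
    s <- s - parts[j]
  }
  list(prefix = parts[1L],
       gaps = parts[seq_len(n_targets - 1L) + 1L],
       tail = parts[length(parts)])
}

#' Generate one oddball block
#'
#' Draws every trial's SOA independently from the condition's discretized
#' Gaussian (standards and targets alike), places targets according to
#' [sample_target_gaps()], and assigns each target a deviant identity with
#' probability one half. The first trial of a block has no preceding sound,
#' so its SOA is `NA`.
#'
#' @param spec A [condition_spec()].
#' @param n_trials,n_targets Block design numbers (defaults 410 and 56).
#' @param prefix_min Minimum number of leading standard trials (default 10).
#' @param deviant_prob Probability that a target carries the deviant pitch.
#' @return An object of class `oddball_block`: list with `condition` and a
#'   data frame `trials` with columns `trial_index`, `soa_ms`, `is_target`,
#'   `is_deviant`.
#' @export
build_block <- function(spec, n_trials = 410, n_targets = 56,
                        prefix_min = 10, deviant_prob = 0.5) {
  stopifnot(inherits(spec, "condition_spec"))
  dist <- soa_distribution(spec)
  layout <- sample_target_gaps(n_targets, n_trials, prefix_min = prefix_min)
  target_idx <- layout$prefix + 1L +
    cumsum(c(0L, layout$gaps + 1L))
  is_target <- rep(FALSE, n_trials)
  is_target[target_idx] <- TRUE
  is_deviant <- rep(FALSE, n_trials)
  is_deviant[target_idx] <- stats::runif(n_targets) < deviant_prob
  trials <- tibble::tibble(
    trial_index = seq_len(n_trials),
    soa_ms = c(NA_real_, sample_soas(dist, n_trials - 1L)),
    is_target = is_target,
    is_deviant = is_deviant
  )
  structure(list(condition = spec, trials = trials),
            class = "oddball_block")
}

#' Draw a pseudo-randomized block order
#'
#' Shuffles the multiset of condition labels, rejecting any order that
#' presents the same condition twice in succession; the result is uniform
#' over admissible arrangements.
#'
#' @param stds Vector of condition labels (one entry per block).
#' @return A permutation of `stds` with no adjacent repeats.
#' @export
draw_block_order <- function(stds) {
  repeat {
    order_std <- sample(stds)
    if (all(diff(order_std) != 0)) return(order_std)
  }
}

#' Generate a full 12-block session
#'
#' Two blocks per condition; the block order is shuffled with rejection of
#' any order presenting the same condition twice in succession, which makes
#' the order uniform over admissible arrangements of the condition
#' multiset.
#'
#' @param subject_id Subject identifier (kept in the output).
#' @param conditions List of [condition_spec()]s (default the six design
#'   conditions).
#' @param blocks_per_condition Number of blocks per condition (default 2).
#' @param ... Passed to [build_block()].
#' @return An object of class `oddball_session`: list with `subject_id`,
#'   `blocks` (list of `oddball_block`), and `condition_order` (the STD of
#'   each block, ms).
#' @export
build_session <- function(subject_id, conditions = default_conditions(),
                          blocks_per_condition = 2, ...) {
  stds <- rep(vapply(conditions, `[[`, 0, "std_soa"), blocks_per_condition)
  order_std <- draw_block_order(stds)
  specs <- lapply(order_std, condition_spec)
  blocks <- lapply(specs, build_block, ...)
  structure(list(subject_id = subject_id,
                 blocks = blocks,
                 condition_order = order_std),
            class = "oddball_session")
}

#' Flatten a session to a long trial table
#'
#' @param session An [build_session()] result.
#' @return A tibble with one row per trial: `subject`, `block`,
#'   `condition_std_ms`, `trial_index`, `soa_ms`, `is_target`, `is_deviant`.
#' @export
session_trials <- function(session) {
  stopifnot(inherits(session, "oddball_session"))
  out <- lapply(seq_along(session$blocks), function(b) {
    blk <- session$blocks[[b]]
    tibble::tibble(
      subject = session$subject_id,
      block = b,
      condition_std_ms = blk$condition$std_soa,
      blk$trials
    )
  })
  dplyr::bind_rows(out)
}

#' Check block design invariants
#'
#' Asserts the hard constraints of the design on a generated block: trial
#' and target counts, no target among the first `prefix_min` trials, all
#' inter-target gaps within bounds, every defined SOA on the condition
#' grid.
#'
#' @param block An `oddball_block`.
#' @param n_trials,n_targets,prefix_min,gap_min,gap_max Expected design
#'   numbers.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_block <- function(block, n_trials = 410, n_targets = 56,
                           prefix_min = 10, gap_min = 4, gap_max = 10) {
  stopifnot(inherits(block, "oddball_block"))
  tr <- block$trials
  if (nrow(tr) != n_trials) stop("wrong trial count: ", nrow(tr))
  idx <- tr$trial_index[tr$is_target]
  if (length(idx) != n_targets) stop("wrong target count: ", length(idx))
  if (any(idx <= prefix_min)) stop("target within the first ", prefix_min,
                                   " trials")
  gaps <- diff(idx) - 1L
  if (any(gaps < gap_min | gaps > gap_max)) {
    stop("inter-target gap outside [", gap_min, ",", gap_max, "]")
  }
  if (any(tr$is_deviant & !tr$is_target)) stop("deviant flag on a standard")
  soa <- tr$soa_ms[-1L]
  grid <- soa_distribution(block$condition)$support
  if (anyNA(soa) || !all(soa %in% grid)) stop("SOA off the condition grid")
  invisible(TRUE)
}

#' @export
print.oddball_block <- function(x, ...) {
  cat(sprintf("oddball block (%s): %d trials, %d targets\n",
              x$condition$label, nrow(x$trials), sum(x$trials$is_target)))
  invisible(x)
}

#' @export
print.oddball_session <- function(x, ...) {
  cat(sprintf("oddball session '%s': %d blocks (condition STDs: %s)\n",
              as.character(x$subject_id), length(x$blocks),
              paste(x$condition_order, collapse = " ")))
  invisible(x)
}
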