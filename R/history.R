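# Local temporal statistics: mean and STD of the N SOAs preceding each
# target, and 2-D sliding-window binned performance maps.

#' Trial-history features for every target in a block
#'
#' For a target at trial `i`, the "N previous SOAs" are
#' `soa(i), soa(i-1), ..., soa(i-N+1)` — the window includes the SOA
#' immediately preceding the target, so `mean_1` equals the last SOA.
#' Means are computed for N = 1..7 and STDs (sample, n-1 denominator by
#' default) for N = 2..7. Targets never occur before trial 11, so every
#' window is fully defined.
#'
#' @param block An `oddball_block`.
#' @param n_mean_max,n_std_max Largest window lengths (defaults 7).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A tibble with one row per target: `trial_index`, `last_soa_ms`,
#'   `mean_1` .. `mean_7`, `std_2` .. `std_7` (ms).
#' @export
compute_history_features <- function(block, n_mean_max = 7, n_std_max = 7,
                                     sd_type = c("sample", "population")) {
  stopifnot(inherits(block, "oddball_block"))
  sd_type <- match.arg(sd_type)
  soa <- block$trials$soa_ms
  idx <- block$trials$trial_index[block$trials$is_target]
  stopifnot(all(idx > n_mean_max))  # guaranteed by the no-target prefix
  feat <- tibble::tibble(trial_index = idx, last_soa_ms = soa[idx])
  windows <- lapply(idx, function(i) soa[i:(i - max(n_mean_max, n_std_max) + 1L)])
  for (n in seq_len(n_mean_max)) {
    feat[[paste0("mean_", n)]] <-
      vapply(windows, function(w) mean(w[seq_len(n)]), 0)
  }
  for (n in 2:n_std_max) {
    feat[[paste0("std_", n)]] <- vapply(windows, function(w) {
      x <- w[seq_len(n)]
      s2 <- stats::var(x)
      if (sd_type == "population") s2 <- s2 * (n - 1) / n
      sqrt(s2)
    }, 0)
  }
  feat
}

#' Default 2-D binning grids
#'
#' Bin centers for the local-mean axis (400-600 ms, 10 ms apart, window
#' half-width 20 ms) and the local-STD axis (10-100 ms, 5 ms apart,
#' half-width 10 ms). Adjacent windows overlap by at least half their
#' width, so neighbouring bins share trials.
#'
#' @name binning_grids
#' @export
default_mean_grid <- function() seq(400, 600, by = 10)

#' @rdname binning_grids
#' @export
default_std_grid <- function() seq(10, 100, by = 5)

#' Bin one participant's targets into a 2-D performance map
#'
#' A target enters bin `(m, s)` when `|mean_Nmean - m| <= mean_halfwidth`
#' and `|std_Nstd - s| <= std_halfwidth` (inclusive boundaries; windows
#' overlap, so one trial may enter several bins). Bins holding fewer than
#' `min_count` trials are marked invalid and excluded from later analysis.
#'
#' @param features A tibble of target features carrying `mean_<N_mean>` and
#'   `std_<N_std>` columns plus `correct` and `rt_ms`.
#' @param N_mean,N_std Window lengths selecting the feature columns
#'   (`N_mean` in 1..7, `N_std` in 2..7).
#' @param mean_grid,std_grid Bin centers (ms).
#' @param mean_halfwidth,std_halfwidth Window half-widths (ms).
#' @param min_count Minimum trials per valid bin (default 5).
#' @return An object of class `performance_map`: matrices `count`, `acc`,
#'   `rt`, `valid` (rows = mean bins, columns = STD bins) plus the grids.
#' @export
bin_performance_map <- function(features, N_mean, N_std,
                                mean_grid = default_mean_grid(),
                                std_grid = default_std_grid(),
                                mean_halfwidth = 20, std_halfwidth = 10,
                                min_count = 5) {
  stopifnot(N_mean %in% 1:7, N_std %in% 2:7)
  m_col <- paste0("mean_", N_mean)
  s_col <- paste0("std_", N_std)
  stopifnot(all(c(m_col, s_col, "correct", "rt_ms") %in% names(features)))
  n <- nrow(features)
  dims <- c(length(mean_grid), length(std_grid))
  if (n == 0L) {
    z <- matrix(0, dims[1], dims[2])
    return(structure(list(mean_grid = mean_grid, std_grid = std_grid,
                          count = z, acc = z * NA, rt = z * NA,
                          valid = matrix(FALSE, dims[1], dims[2]),
                          min_count = min_count),
                     class = "performance_map"))
  }
  A <- abs(outer(features[[m_col]], mean_grid, `-`)) <= mean_halfwidth
  B <- abs(outer(features[[s_col]], std_grid, `-`)) <= std_halfwidth
  mode(A) <- "numeric"; mode(B) <- "numeric"
  count <- crossprod(A, B)
  acc <- crossprod(A * features$correct, B) / count
  rt <- crossprod(A * features$rt_ms, B) / count
  valid <- count >= min_count
  acc[!valid] <- NA_real_
  rt[!valid] <- NA_real_
  structure(list(mean_grid = mean_grid, std_grid = std_grid,
                 count = count, acc = acc, rt = rt, valid = valid,
                 min_count = min_count),
            class = "performance_map")
}

#' Z-score a performance map within a participant
#'
#' Standardizes one measure (`acc` or `rt`) over the participant's valid
#' bins (mean 0, sample SD 1). Invalid bins stay invalid. With fewer than
#' two valid bins, or zero variance across them, the whole map is returned
#' invalid with a warning.
#'
#' @param map A [bin_performance_map()] result.
#' @param measure `"acc"` or `"rt"`.
#' @return An object of class `zmap`: matrix `z` plus `valid` and the grids.
#' @export
zscore_map <- function(map, measure = c("acc", "rt")) {
  stopifnot(inherits(map, "performance_map"))
  measure <- match.arg(measure)
  vals <- map[[measure]]
  valid <- map$valid
  z <- vals * NA_real_
  nv <- sum(valid)
  if (nv < 2L || stats::sd(vals[valid]) == 0) {
    warning("z-scoring impossible (", nv, " valid bins",
            if (nv >= 2L) ", zero variance", "); map marked invalid")
    valid <- valid & FALSE
  } else {
    z[valid] <- (vals[valid] - mean(vals[valid])) / stats::sd(vals[valid])
  }
  structure(list(mean_grid = map$mean_grid, std_grid = map$std_grid,
                 z = z, valid = valid, measure = measure),
            class = "zmap")
}

#' Stack participants' z-maps for the group-level test
#'
#' A bin enters the group test only when it is valid for every
#' participant (intersection mask): the cluster test requires a complete
#' participants-by-bins array.
#'
#' @param zmaps List of [zscore_map()] results on identical grids.
#' @return List with `data` (participants x bins matrix over all bins,
#'   `NA` outside the mask, bins in column-major order of the map
#'   matrices), `mask` (logical vector), and `dims` (mean bins, STD bins).
#' @export
stack_group <- function(zmaps) {
  stopifnot(length(zmaps) >= 1, all(vapply(zmaps, inherits, TRUE, "zmap")))
  dims <- dim(zmaps[[1]]$z)
  mask <- Reduce(`&`, lapply(zmaps, function(m) as.vector(m$valid)))
  if (!any(mask)) stop("no bin is valid for all participants", call. = FALSE)
  data <- do.call(rbind, lapply(zmaps, function(m) as.vector(m$z)))
  data[, !mask] <- NA_real_
  list(data = data, mask = mask, dims = dims,
       mean_grid = zmaps[[1]]$mean_grid, std_grid = zmaps[[1]]$std_grid)
}
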