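# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force loops, exhaustive enumeration,
# closed forms.

# Moments of a discretized Gaussian by direct summation from the density.
oracle_grid_moments <- function(mean, std, grid = seq(100, 900, 25)) {
  w <- stats::dnorm(grid, mean, std)
  p <- w / sum(w)
  m <- sum(grid * p)
  list(mean = m, sd = sqrt(sum((grid - m)^2 * p)), probs = p)
}

# All feasible (prefix, gaps..., tail) compositions for a small layout.
oracle_enumerate_layouts <- function(n_targets, n_trials, prefix_min,
                                     gap_min = 4, gap_max = 10,
                                     prefix_max = prefix_min + (gap_max - gap_min),
                                     tail_max = gap_max) {
  total <- n_trials - n_targets
  parts <- c(list(prefix_min:prefix_max),
             rep(list(gap_min:gap_max), n_targets - 1),
             list(0:tail_max))
  grid <- do.call(expand.grid, parts)
  grid[rowSums(grid) == total, , drop = FALSE]
}

# Windowed statistics recomputed by a plain loop over the raw SOA list.
oracle_history <- function(soa, target_idx, n) {
  t(vapply(target_idx, function(i) {
    w <- soa[(i - n + 1):i]
    c(mean = mean(w), sd = if (n >= 2) stats::sd(w) else NA_real_)
  }, c(mean = 0, sd = 0)))
}

# Quadratic brute-force bin assignment.
oracle_bin_map <- function(mean_vals, std_vals, correct, rt,
                           mean_grid, std_grid, mhw = 20, shw = 10) {
  nm <- length(mean_grid); ns <- length(std_grid)
  count <- matrix(0, nm, ns); acc <- matrix(NA_real_, nm, ns)
  rtm <- matrix(NA_real_, nm, ns)
  for (a in seq_len(nm)) for (b in seq_len(ns)) {
    inbin <- abs(mean_vals - mean_grid[a]) <= mhw &
      abs(std_vals - std_grid[b]) <= shw
    count[a, b] <- sum(inbin)
    if (any(inbin)) {
      acc[a, b] <- mean(correct[inbin])
      rtm[a, b] <- mean(rt[inbin])
    }
  }
  list(count = count, acc = acc, rt = rtm)
}

# Recursive flood fill (rook adjacency) over a logical matrix.
oracle_flood_fill <- function(active_mat) {
  labels <- matrix(0L, nrow(active_mat), ncol(active_mat))
  lab <- 0L
  fill <- function(i, j, lab) {
    stack <- list(c(i, j))
    while (length(stack)) {
      ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (i < 1 || j < 1 || i > nrow(active_mat) || j > ncol(active_mat))
        next
      if (!active_mat[i, j] || labels[i, j] != 0L) next
      labels[i, j] <<- lab
      stack <- c(stack, list(c(i - 1, j), c(i + 1, j),
                             c(i, j - 1), c(i, j + 1)))
    }
  }
  for (i in seq_len(nrow(active_mat))) for (j in seq_len(ncol(active_mat))) {
    if (active_mat[i, j] && labels[i, j] == 0L) {
      lab <- lab + 1L
      fill(i, j, lab)
    }
  }
  labels
}

# A tiny deterministic feature table for binning tests.
make_feature_fixture <- function(n, seed = 7) {
  set.seed(seed)
  tibble::tibble(
    mean_4 = runif(n, 390, 610),
    std_4 = runif(n, 5, 105),
    correct = rbinom(n, 1, 0.8),
    rt_ms = rgamma(n, 20, scale = 25)
  )
}

# Small simulated cohort for mixed-model unit tests (cheaper than the full
# design).
make_small_cohort <- function(n_subjects = 6, seed = 11,
                              params = observer_params()) {
  simulate_cohort(n_subjects, params, seed = seed)
}
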