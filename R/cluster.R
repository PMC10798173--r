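# One-sample cluster-based sign-flip permutation test on 2-D z-scored
# performance maps. Bins are laid out column-major on the (mean, STD) grid
# exactly as in the map matrices, so vector index k maps to grid cell
# (row = (k-1) %% n_mean + 1, col = (k-1) %/% n_mean + 1).

#' One-sample t-map over valid bins
#'
#' Per-bin one-sample t-test against zero across participants
#' (`df = n - 1`, two-sided p). Bins with zero across-participant variance
#' cannot support a finite t; they are flagged and assigned
#' `t = sign(mean) * Inf`, `p = 0`, i.e. treated as supra-threshold with
#' the sign of their mean.
#'
#' @param data Participants x bins matrix (`NA` outside the mask).
#' @param mask Logical vector of jointly valid bins.
#' @return List with numeric vectors `t`, `p` (NA outside the mask), the
#'   number of participants `n`, and logical `zero_var` flags.
#' @export
one_sample_tmap <- function(data, mask = rep(TRUE, ncol(data))) {
  stopifnot(is.matrix(data), nrow(data) >= 2, length(mask) == ncol(data))
  n <- nrow(data)
  m <- unname(colMeans(data))
  s <- unname(apply(data, 2, stats::sd))
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  zero_var <- mask & !is.na(s) & s == 0
  t[zero_var] <- sign(m[zero_var]) * Inf
  p[zero_var] <- 0
  t[!mask] <- NA_real_
  p[!mask] <- NA_real_
  list(t = t, p = p, n = n, zero_var = zero_var)
}

# Connected components (4-neighbour / rook adjacency) among the TRUE cells
# of a logical vector laid out on an n_mean x n_std grid. Returns an
# integer label vector (0 = not a member).
label_components <- function(active, dims) {
  n_mean <- dims[1]; n_std <- dims[2]
  labels <- integer(length(active))
  next_label <- 0L
  for (start in which(active)) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    labels[start] <- next_label
    while (length(queue)) {
      k <- queue[[1]]; queue <- queue[-1]
      i <- (k - 1L) %% n_mean + 1L
      j <- (k - 1L) %/% n_mean + 1L
      nb <- c(if (i > 1L) k - 1L, if (i < n_mean) k + 1L,
              if (j > 1L) k - n_mean, if (j < n_std) k + n_mean)
      nb <- nb[active[nb] & labels[nb] == 0L]
      labels[nb] <- next_label
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Find supra-threshold clusters on the bin grid
#'
#' Bins whose per-bin p-value is at or below the cluster-forming threshold
#' are split by the sign of their t-value and grouped into connected
#' components under 4-neighbour (rook) adjacency on the 2-D bin lattice.
#' The cluster statistic is the sum of the member t-values.
#'
#' @param t,p Per-bin t and p vectors (as from [one_sample_tmap()]).
#' @param mask Logical vector of valid bins.
#' @param dims Grid dimensions `c(n_mean_bins, n_std_bins)`.
#' @param alpha Cluster-forming threshold on the two-sided per-bin p.
#' @return List of clusters, each a list with `bins` (vector indices),
#'   `stat` (sum of t), `sign` (+1 or -1); empty list when no bin is
#'   supra-threshold.
#' @export
find_clusters <- function(t, p, mask, dims, alpha = 0.05) {
  stopifnot(length(t) == prod(dims), length(p) == length(t),
            length(mask) == length(t))
  supra <- mask & !is.na(p) & p <= alpha & t != 0
  out <- list()
  for (sgn in c(1, -1)) {
    active <- supra & sign(t) == sgn
    labels <- label_components(active, dims)
    for (lab in seq_len(max(labels))) {
      bins <- which(labels == lab)
      out[[length(out) + 1L]] <-
        list(bins = bins, stat = sum(t[bins]), sign = sgn)
    }
  }
  out
}

# t-vector for every sign-flip at once: under row sign-flips the per-bin
# sum of squares is invariant, so each permutation's mean and SD come from
# one matrix product.
perm_tmatrix <- function(X, signs) {
  n <- nrow(X)
  ss <- colSums(X^2)
  M <- signs %*% X / n                       # n_perm x bins means
  V <- sweep(-n * M^2, 2, ss, `+`) / (n - 1) # per-perm variances
  V[V < 0] <- 0                              # numerical guard
  M / sqrt(V / n)
}

#' Sign-flip cluster-based permutation test
#'
#' One-sample test of zero mean over participants on a 2-D map. The
#' observed t-map is thresholded and clustered ([find_clusters()]); the
#' reference distribution is built from `n_perm` random whole-map sign
#' flips of each participant's data (identity flip included as the first
#' permutation), recording each permutation's most extreme cluster
#' statistic with its sign (zero when the permutation yields no cluster),
#' one signed value per permutation. An observed cluster is significant
#' when its statistic falls below the 2.5th or above the 97.5th percentile
#' of that signed reference distribution (two-sided family-wise level
#' 5%); per-cluster p-values are two-sided exceedance ranks with the +1
#' finite-sample correction.
#'
#' @param data Participants x bins matrix (`NA` outside the mask).
#' @param mask Logical vector of jointly valid bins.
#' @param dims Grid dimensions `c(n_mean_bins, n_std_bins)`.
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param alpha_form Cluster-forming threshold (default 0.05).
#' @param seed Optional integer seed for the sign flips.
#' @return Object of class `cluster_test`: `tmap`, `pmap`, `clusters`
#'   (with `p` and `significant` added), `perm_stats` (tibble of per-
#'   permutation extremes), `ref` (signed extreme reference, one entry
#'   per permutation), `crit`
#'   (the 2.5/97.5 percentile cut), plus `n_perm`, `alpha_form`, `seed`.
#' @export
permutation_test <- function(data, mask, dims, n_perm = 1000,
                             alpha_form = 0.05, seed = NULL) {
  stopifnot(nrow(data) >= 2)
  if (!is.null(seed)) set.seed(seed)
  obs <- one_sample_tmap(data, mask)
  clusters <- find_clusters(obs$t, obs$p, mask, dims, alpha_form)

  X <- data[, mask, drop = FALSE]
  n <- nrow(X)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                  nrow = n_perm)
  signs[1, ] <- 1                          # identity permutation included
  tmat <- perm_tmatrix(X, signs)
  tcrit <- stats::qt(1 - alpha_form / 2, df = n - 1)
  sub_dims <- dims                          # cluster on the full grid
  max_pos <- numeric(n_perm); min_neg <- numeric(n_perm)
  tfull <- rep(NA_real_, length(mask))
  for (r in seq_len(n_perm)) {
    tfull[mask] <- tmat[r, ]
    supra_pos <- !is.na(tfull) & tfull >= tcrit
    supra_neg <- !is.na(tfull) & tfull <= -tcrit
    mp <- 0; mn <- 0
    if (any(supra_pos)) {
      labs <- label_components(supra_pos, sub_dims)
      mp <- max(vapply(seq_len(max(labs)),
                       function(l) sum(tfull[labs == l]), 0))
    }
    if (any(supra_neg)) {
      labs <- label_components(supra_neg, sub_dims)
      mn <- min(vapply(seq_len(max(labs)),
                       function(l) sum(tfull[labs == l]), 0))
    }
    max_pos[r] <- mp; min_neg[r] <- mn
  }
  ref <- ifelse(max_pos >= -min_neg, max_pos, min_neg)
  crit <- stats::quantile(ref, c(0.025, 0.975), names = FALSE)
  L <- length(ref)
  clusters <- lapply(clusters, function(cl) {
    if (cl$sign > 0) {
      p_side <- (1 + sum(ref >= cl$stat)) / (L + 1)
      cl$significant <- cl$stat > crit[2]
    } else {
      p_side <- (1 + sum(ref <= cl$stat)) / (L + 1)
      cl$significant <- cl$stat < crit[1]
    }
    cl$p <- min(1, 2 * p_side)
    cl
  })
  structure(list(tmap = obs$t, pmap = obs$p, n = n, clusters = clusters,
                 perm_stats = tibble::tibble(max_pos = max_pos,
                                             min_neg = min_neg),
                 ref = ref, crit = crit, dims = dims, mask = mask,
                 n_perm = n_perm, alpha_form = alpha_form, seed = seed),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  nsig <- sum(vapply(x$clusters, `[[`, TRUE, "significant"))
  cat(sprintf(paste0("cluster permutation test: %d participants, %d valid",
                     " bins, %d cluster(s), %d significant (n_perm = %d)\n"),
              x$n, sum(x$mask), length(x$clusters), nsig, x$n_perm))
  invisible(x)
}
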