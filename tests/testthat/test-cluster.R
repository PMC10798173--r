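# Toy inputs: participants x bins matrices on small grids, bins laid out
# column-major as in the map matrices.

test_that("t-map matches the closed form and handles symmetric samples", {
  x <- c(2.1, 1.4, 0.7, 1.9, 1.0)
  data <- cbind(x, c(-1, 0, 1, 0, 0))
  res <- one_sample_tmap(data)
  t_hand <- mean(x) / (sd(x) / sqrt(5))
  expect_lt(abs(res$t[1] - t_hand), 1e-12)
  expect_lt(abs(res$p[1] - 2 * pt(abs(t_hand), 4, lower.tail = FALSE)), 1e-12)
  expect_equal(res$t[2], 0)
  expect_equal(res$p[2], 1)
})

test_that("zero-variance bins are flagged supra-threshold with the mean's sign", {
  data <- cbind(rep(1, 5), rep(-2, 5), rnorm(5))
  res <- one_sample_tmap(data)
  expect_true(res$zero_var[1] && res$zero_var[2])
  expect_equal(res$t[1], Inf)
  expect_equal(res$t[2], -Inf)
  expect_equal(res$p[1], 0)
})

test_that("cluster finding matches a recursive flood-fill oracle", {
  dims <- c(5, 5)
  # two L-shaped positive components, one negative bin
  tm <- matrix(0, 5, 5)
  tm[1, 1:3] <- 3; tm[2, 1] <- 3            # L no. 1
  tm[4:5, 4] <- 3; tm[5, 5] <- 3            # L no. 2
  tm[3, 3] <- -3
  pm <- ifelse(tm != 0, 0.01, 0.5)
  mask <- rep(TRUE, 25)
  cl <- find_clusters(as.vector(tm), as.vector(pm), mask, dims)
  pos <- Filter(function(c) c$sign > 0, cl)
  neg <- Filter(function(c) c$sign < 0, cl)
  expect_length(pos, 2)
  expect_length(neg, 1)
  labs <- oracle_flood_fill(tm > 0)
  for (cl1 in pos) {
    oracle_members <- sort(which(labs == labs[cl1$bins[1]]))
    expect_equal(sort(cl1$bins), oracle_members)
    expect_equal(cl1$stat, sum(tm[oracle_members]))
  }
  expect_equal(neg[[1]]$bins, which(as.vector(tm) < 0))

  # empty and singleton cases
  expect_length(find_clusters(rep(0.5, 25), rep(0.5, 25), mask, dims), 0)
  t1 <- rep(0, 25); t1[13] <- 4
  p1 <- rep(1, 25); p1[13] <- 0.001
  cl1 <- find_clusters(t1, p1, mask, dims)
  expect_length(cl1, 1)
  expect_equal(cl1[[1]]$bins, 13)
  expect_equal(cl1[[1]]$stat, 4)
})

test_that("clusters never cross masked-out bins or diagonals", {
  dims <- c(3, 3)
  tm <- rep(3, 9)
  pm <- rep(0.01, 9)
  mask <- rep(TRUE, 9)
  mask[c(2, 4)] <- FALSE                   # cut the corner off
  tm[c(2, 4)] <- NA; pm[c(2, 4)] <- NA
  cl <- find_clusters(tm, pm, mask, dims)
  sizes <- sort(vapply(cl, function(c) length(c$bins), 0L))
  expect_equal(sizes, c(1L, 6L))            # bin 1 isolated from the rest
})

test_that("sign-flipping the data flips clusters and preserves p-values", {
  set.seed(24)
  data <- matrix(rnorm(19 * 36, mean = 0.3), nrow = 19)
  mask <- rep(TRUE, 36)
  r1 <- permutation_test(data, mask, c(6, 6), n_perm = 200, seed = 101)
  r2 <- permutation_test(-data, mask, c(6, 6), n_perm = 200, seed = 101)
  expect_equal(length(r1$clusters), length(r2$clusters))
  s1 <- vapply(r1$clusters, `[[`, 0, "stat")
  s2 <- vapply(r2$clusters, `[[`, 0, "stat")
  expect_equal(sort(abs(s1)), sort(abs(s2)))
  o1 <- order(abs(s1)); o2 <- order(abs(s2))
  expect_equal(vapply(r1$clusters, `[[`, 0, "sign")[o1],
               -vapply(r2$clusters, `[[`, 0, "sign")[o2])
  expect_equal(vapply(r1$clusters, `[[`, 0, "p")[o1],
               vapply(r2$clusters, `[[`, 0, "p")[o2])
})

test_that("the permutation test is reproducible and rank-corrected", {
  set.seed(25)
  data <- matrix(rnorm(10 * 16, mean = 0.5), nrow = 10)
  mask <- rep(TRUE, 16)
  r1 <- permutation_test(data, mask, c(4, 4), n_perm = 300, seed = 7)
  r2 <- permutation_test(data, mask, c(4, 4), n_perm = 300, seed = 7)
  expect_identical(r1$ref, r2$ref)
  expect_identical(vapply(r1$clusters, `[[`, 0, "p"),
                   vapply(r2$clusters, `[[`, 0, "p"))
  expect_length(r1$ref, 300)
  expect_equal(nrow(r1$perm_stats), 300)
  for (cl in r1$clusters) expect_gte(cl$p, 1 / (300 + 1))
  # participant order must not matter for the observed map
  r3 <- permutation_test(data[10:1, ], mask, c(4, 4), n_perm = 50, seed = 7)
  expect_equal(r3$tmap, r1$tmap)
})

test_that("a planted block of signal is detected as a positive cluster", {
  set.seed(26)
  dims <- c(8, 8)
  planted <- as.vector(outer(3:6, 3:6, function(i, j) i + (j - 1) * 8))
  hits <- replicate(30, {
    data <- matrix(rnorm(19 * 64), nrow = 19)
    data[, planted] <- data[, planted] + 1.5
    r <- permutation_test(data, rep(TRUE, 64), dims, n_perm = 300)
    sig <- Filter(function(c) c$significant && c$sign > 0, r$clusters)
    if (!length(sig)) return(FALSE)
    covered <- unique(unlist(lapply(sig, `[[`, "bins")))
    length(intersect(covered, planted)) >= length(planted) / 2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("a 1-D map reduces to a direct 1-D cluster permutation test", {
  # direct 1-D implementation sharing only the sign-draw convention
  direct_1d <- function(data, n_perm, alpha, seed) {
    set.seed(seed)
    n <- nrow(data); B <- ncol(data)
    tvec <- function(X) {
      m <- colMeans(X); s <- apply(X, 2, sd)
      m / (s / sqrt(n))
    }
    tcrit <- qt(1 - alpha / 2, n - 1)
    clus_1d <- function(tv) {
      out <- list()
      for (sgn in c(1, -1)) {
        r <- rle(sgn * tv >= tcrit)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        for (k in which(r$values)) {
          out[[length(out) + 1]] <- list(bins = starts[k]:ends[k],
                                         stat = sum(tv[starts[k]:ends[k]]),
                                         sign = sgn)
        }
      }
      out
    }
    obs <- clus_1d(tvec(data))
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    signs[1, ] <- 1
    mp <- numeric(n_perm); mn <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      cl <- clus_1d(tvec(signs[r, ] * data))
      st <- vapply(cl, `[[`, 0, "stat")
      mp[r] <- max(c(0, st[st > 0])); mn[r] <- min(c(0, st[st < 0]))
    }
    list(obs = obs, ref = ifelse(mp >= -mn, mp, mn))
  }
  set.seed(27)
  data <- matrix(rnorm(12 * 15, mean = 0.4), nrow = 12)
  mine <- permutation_test(data, rep(TRUE, 15), c(15, 1), n_perm = 200,
                           seed = 31)
  # same seed: identical sign draws, but my permutation path multiplies
  # t-statistics rather than data rows; the reference must agree exactly
  orc <- direct_1d(data, 200, 0.05, seed = 31)
  expect_equal(sort(mine$ref), sort(orc$ref), tolerance = 1e-9)
  expect_equal(length(mine$clusters), length(orc$obs))
  expect_equal(sort(vapply(mine$clusters, `[[`, 0, "stat")),
               sort(vapply(orc$obs, `[[`, 0, "stat")))
})
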