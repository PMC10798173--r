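test_that("discrete SOA distributions are normalized, symmetric, centred", {
  for (std in c(25, 50, 75, 100, 150)) {
    d <- soa_distribution(condition_spec(std))
    expect_length(d$support, 33)
    expect_lt(abs(sum(d$probs) - 1), 1e-12)
    expect_equal(d$probs, rev(d$probs))
    expect_lt(abs(sum(d$support * d$probs) - 500), 1e-12)
  }
  d0 <- soa_distribution(condition_spec(0))
  expect_equal(d0$support, 500)
  expect_equal(d0$probs, 1)
})

test_that("distribution moments match the summation oracle", {
  for (std in c(25, 150)) {
    d <- soa_distribution(condition_spec(std))
    orc <- oracle_grid_moments(500, std)
    m <- soa_distribution_moments(d)
    expect_lt(abs(m["mean"] - orc$mean), 1e-9)
    expect_lt(abs(m["sd"] - orc$sd), 1e-9)
    expect_lt(max(abs(d$probs - orc$probs)), 1e-12)
  }
  # grid truncation shrinks the realized STD at the widest condition
  expect_lt(soa_distribution_moments(soa_distribution(condition_spec(150)))["sd"],
            150)
})

test_that("invalid conditions are rejected", {
  expect_error(condition_spec(-25), "must be one of")
  expect_error(condition_spec(30), "must be one of")
  expect_error(condition_spec(50, grid_min = 200), "symmetric")
})

test_that("target layouts satisfy the block constraints", {
  set.seed(1)
  for (i in 1:20) {
    lay <- sample_target_gaps(56, 410, prefix_min = 10)
    expect_gte(lay$prefix, 10)
    expect_true(all(lay$gaps >= 4 & lay$gaps <= 10))
    expect_length(lay$gaps, 55)
    expect_identical(lay$prefix + sum(lay$gaps) + lay$tail + 56L, 410L)
  }
  # 56 targets need at least 10 + 55*4 standards: 270 trials cannot fit
  expect_error(sample_target_gaps(56, 270, prefix_min = 10), "infeasible")
})

test_that("a forced unique composition is returned deterministically", {
  # 2 targets, prefix exactly 1, one gap of 4, no tail slack
  lay <- sample_target_gaps(2, 2 + 1 + 4, prefix_min = 1, prefix_max = 1,
                            tail_max = 0)
  expect_identical(lay, list(prefix = 1L, gaps = 4L, tail = 0L))
})

test_that("layout sampling is uniform over feasible compositions", {
  feas <- oracle_enumerate_layouts(3, 20, prefix_min = 1)
  n_feas <- nrow(feas)
  expect_gt(n_feas, 1)
  set.seed(20)
  n_draw <- 20000
  draws <- replicate(n_draw, {
    lay <- sample_target_gaps(3, 20, prefix_min = 1)
    paste(c(lay$prefix, lay$gaps, lay$tail), collapse = "-")
  })
  keys <- apply(feas, 1, paste, collapse = "-")
  counts <- table(factor(draws, levels = keys))
  expect_identical(sum(counts), as.integer(n_draw))  # only feasible layouts
  chi <- stats::chisq.test(counts, p = rep(1 / n_feas, n_feas))
  expect_gt(chi$p.value, 0.001)
})

test_that("generated blocks honor every design invariant", {
  set.seed(2)
  for (std in c(0, 50, 150)) {
    b <- build_block(condition_spec(std))
    expect_true(validate_block(b))
  }
  bper <- build_block(condition_spec(0))
  expect_true(all(bper$trials$soa_ms[-1] == 500))
  expect_true(is.na(bper$trials$soa_ms[1]))
})

test_that("block SOA and deviant statistics match the generative moments", {
  set.seed(3)
  spec <- condition_spec(50)
  orc <- oracle_grid_moments(500, 50)
  soas <- c(); dev <- c()
  for (i in 1:200) {
    b <- build_block(spec)
    soas <- c(soas, b$trials$soa_ms[-1])
    dev <- c(dev, b$trials$is_deviant[b$trials$is_target])
  }
  se_mean <- orc$sd / sqrt(length(soas))
  expect_lt(abs(mean(soas) - 500), 3 * se_mean)
  se_dev <- 0.5 / sqrt(length(dev))
  expect_lt(abs(mean(dev) - 0.5), 3 * se_dev)
})

test_that("sessions satisfy design invariants and are seed-deterministic", {
  set.seed(4)
  s <- build_session("S01")
  expect_length(s$blocks, 12)
  tab <- table(s$condition_order)
  expect_true(all(tab == 2))
  expect_true(all(diff(s$condition_order) != 0))
  pooled <- session_trials(s)
  per_cond <- tapply(pooled$is_target, pooled$condition_std_ms, sum)
  expect_true(all(per_cond == 112))

  set.seed(99); s1 <- build_session("X")
  set.seed(99); s2 <- build_session("X")
  expect_identical(session_trials(s1), session_trials(s2))
})

test_that("each condition is equally likely to open a session", {
  # by symmetry of the multiset, the admissible-order distribution puts
  # equal mass on every condition in first position
  set.seed(5)
  stds <- rep(c(0, 25, 50, 75, 100, 150), 2)
  firsts <- replicate(6000, draw_block_order(stds)[1])
  chi <- stats::chisq.test(table(firsts), p = rep(1 / 6, 6))
  expect_gt(chi$p.value, 0.001)
  # and every draw is admissible
  orders <- replicate(200, draw_block_order(stds))
  expect_true(all(apply(orders, 2, function(o) all(diff(o) != 0))))
})

test_that("trial tables round-trip through the CSV schema", {
  set.seed(6)
  s <- build_session("S01", conditions = default_conditions(c(0, 50)),
                     blocks_per_condition = 1)
  tr <- session_trials(s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(tr, path)
  back <- read_trials_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tr))
  # strict validation
  bad <- tr; bad$is_deviant[!bad$is_target][1] <- TRUE
  write_trials_csv(bad, path)
  expect_error(read_trials_csv(path), "deviant flag")
})
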