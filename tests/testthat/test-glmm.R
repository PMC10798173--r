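test_that("a single-subject binomial fit collapses to ordinary logistic", {
  d <- data.frame(subject = "S01",
                  correct = rep(c(1, 0), c(80, 20)),
                  std25 = 0)
  fit <- fit_glmm(correct ~ 1 + (1 | subject), d, family = "binomial")
  expect_true(fit$degenerate)
  expect_lt(abs(fit$fixed$estimate[1] - qlogis(0.8)), 1e-6)
})

test_that("binomial GLMM recovers planted slope and intercept SD", {
  set.seed(28)
  ok <- replicate(12, {
    n_sub <- 12; n_per <- 200
    beta <- -0.25; tau <- 0.5
    d <- expand.grid(subject = factor(1:n_sub), i = 1:n_per)
    d$std25 <- sample(0:6, nrow(d), TRUE)
    eta <- 1.2 + rnorm(n_sub, 0, tau)[as.integer(d$subject)] + beta * d$std25
    d$correct <- rbinom(nrow(d), 1, plogis(eta))
    fit <- fit_glmm(correct ~ std25 + (1 | subject), d, family = "binomial")
    b <- fit$fixed[fit$fixed$term == "std25", ]
    abs(b$estimate - beta) < 3 * b$se
  })
  expect_gte(mean(ok), 0.9)
})

test_that("gamma-log GLMM recovers a planted mean structure", {
  set.seed(29)
  ok <- replicate(8, {
    n_sub <- 10; n_per <- 150
    d <- expand.grid(subject = factor(1:n_sub), i = 1:n_per)
    d$x <- runif(nrow(d))
    eta <- log(400) + rnorm(n_sub, 0, 0.1)[as.integer(d$subject)] + 0.3 * d$x
    d$y <- rgamma(nrow(d), shape = 15, scale = exp(eta) / 15)
    fit <- fit_glmm(y ~ x + (1 | subject), d, family = "gamma")
    b <- fit$fixed[fit$fixed$term == "x", ]
    abs(b$estimate - 0.3) < 3 * b$se
  })
  expect_gte(mean(ok), 0.75)
})

test_that("mixed fits agree with ordinary GLMs when subject variance is nil", {
  set.seed(30)
  d <- data.frame(subject = factor(rep(1:5, each = 100)))
  d$x <- runif(nrow(d))
  d$y <- rgamma(nrow(d), shape = 10, scale = exp(1 + 0.5 * d$x) / 10)
  mixed <- fit_glmm(y ~ x + (1 | subject), d, family = "gamma")
  plain <- glm(y ~ x, data = d, family = Gamma(link = "log"))
  # no subject structure was planted: estimates agree closely
  expect_lt(abs(mixed$fixed$estimate[2] - coef(plain)[2]), 0.05)
})

test_that("the likelihood-ratio test behaves on identities and boundaries", {
  set.seed(31)
  co <- make_small_cohort(5, seed = 31)
  d <- as.data.frame(co$targets)
  d$subject <- factor(d$subject)
  d$std25 <- d$condition_std_ms / 25
  m <- fit_glmm(correct ~ std25 + (1 | subject), d, family = "binomial")
  same <- lrt(m, m)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  m0 <- fit_glmm(correct ~ 1 + (1 | subject), d, family = "binomial")
  out <- lrt(m0, m)
  expect_gte(out$chi2, 0)
  expect_equal(out$df, 1)
  expect_error(lrt(m, m0), "fewer parameters")
})

test_that("Type II Wald equals z-squared for one continuous predictor", {
  set.seed(32)
  co <- make_small_cohort(5, seed = 32)
  d <- as.data.frame(co$targets)
  d$std25 <- d$condition_std_ms / 25
  fit <- fit_glmm(correct ~ std25 + (1 | subject), d, family = "binomial")
  w <- wald_type2(fit)
  z <- fit$fixed$estimate[2] / fit$fixed$se[2]
  expect_lt(abs(w$chi2[w$term == "std25"] - z^2), 1e-9)
})

test_that("Type II matches sequential tests for orthogonal predictors", {
  set.seed(33)
  n <- 400
  d <- data.frame(subject = factor(rep(1:8, length.out = n)),
                  x1 = rep(c(-1, 1), each = n / 2),
                  x2 = rep(c(-1, 1), times = n / 2))
  eta <- 0.3 + 0.4 * d$x1 - 0.3 * d$x2
  d$y <- rbinom(n, 1, plogis(eta))
  fit <- fit_glmm(y ~ x1 + x2 + (1 | subject), d, family = "binomial")
  w2 <- wald_type2(fit)
  # with orthogonal balanced predictors, each term's Wald chi2 equals its
  # own z^2 regardless of type
  z <- fit$fixed$estimate[-1] / fit$fixed$se[-1]
  expect_equal(w2$chi2, unname(z^2), tolerance = 1e-8)
})

test_that("Tukey contrasts: k = 2 identity, 15-row bookkeeping for k = 6", {
  set.seed(34)
  d2 <- data.frame(subject = factor(rep(1:6, each = 80)),
                   condition = factor(rep(c("a", "b"), 240)))
  d2$y <- rbinom(480, 1, ifelse(d2$condition == "a", 0.8, 0.7))
  f2 <- fit_glmm(y ~ condition + (1 | subject), d2, family = "binomial")
  tk2 <- pairwise_tukey(f2)
  expect_equal(nrow(tk2), 1)
  praw <- 2 * pnorm(abs(tk2$statistic), lower.tail = FALSE)
  expect_equal(tk2$p_tukey, praw, tolerance = 1e-6)

  co <- make_small_cohort(6, seed = 34)
  d6 <- as.data.frame(co$targets)
  d6$condition <- factor(d6$condition_std_ms)
  f6 <- fit_glmm(correct ~ condition + (1 | subject), d6,
                 family = "binomial")
  tk6 <- pairwise_tukey(f6)
  expect_equal(nrow(tk6), 15)
})

test_that("odds ratios transform correctly under predictor rescaling", {
  set.seed(35)
  co <- make_small_cohort(6, seed = 35,
                          params = observer_params(acc_slope_local = 0.0008))
  d <- as.data.frame(co$targets)
  row <- fit_local_global(d, N = 4)
  fit <- row$fit[[1]]
  b <- fit$fixed$estimate[fit$fixed$term == "local25"]
  expect_equal(row$or_local, exp(-b))
  expect_true(row$or_local_lo <= row$or_local &&
                row$or_local <= row$or_local_hi)
  # scaling the predictor by 2 takes the per-unit OR to its square root
  d2 <- d
  d2[["std_4"]] <- d2[["std_4"]] * 2
  row2 <- fit_local_global(d2, N = 4)
  expect_equal(log(row2$or_local), log(row$or_local) / 2, tolerance = 0.02)
})

test_that("planted local and global effects land in the right CI", {
  # design-scale cohorts: the local and global STD predictors are
  # strongly collinear (the condition STD shapes the local windows), so
  # detection needs the full 19 subjects
  set.seed(36)
  local_only <- observer_params(acc_slope_global = 0,
                                acc_slope_local = 0.0012)
  global_only <- observer_params(acc_slope_global = 0.008 / 25,
                                 acc_slope_local = 0)
  hits <- replicate(4, {
    co_l <- simulate_cohort(19, local_only)
    r_l <- fit_local_global(as.data.frame(co_l$targets), N = 4)
    co_g <- simulate_cohort(19, global_only)
    r_g <- fit_local_global(as.data.frame(co_g$targets), N = 2)
    c(local_detected = r_l$or_local_lo > 1,
      global_detected = r_g$or_global_lo > 1)
  })
  expect_gte(mean(hits["local_detected", ]), 0.75)
  expect_gte(mean(hits["global_detected", ]), 0.75)
})

test_that("restricting to the 500 ms last SOA filters exactly", {
  toy <- tibble::tibble(last_soa_ms = c(475, 500, 525, 500), correct = 1)
  expect_equal(nrow(restrict_to_mean_soa(toy)), 2)
  expect_warning(restrict_to_mean_soa(toy[1, ]), "no targets")

  set.seed(37)
  co <- simulate_cohort(3, seed = 37)
  per <- co$targets[co$targets$condition_std_ms == 0, ]
  expect_equal(nrow(restrict_to_mean_soa(per)), nrow(per))
  # kept fraction in a Gaussian condition matches the grid mass at 500
  g50 <- co$targets[co$targets$condition_std_ms == 50, ]
  mass <- oracle_grid_moments(500, 50)$probs[which(seq(100, 900, 25) == 500)]
  frac <- nrow(restrict_to_mean_soa(g50)) / nrow(g50)
  se <- sqrt(mass * (1 - mass) / nrow(g50))
  expect_lt(abs(frac - mass), 3 * se)
})

test_that("rating models detect a planted slope and not a spurious one", {
  set.seed(38)
  # power: strong planted rating-on-STD slope
  sig <- replicate(5, {
    co <- simulate_cohort(8)
    rm <- rating_models(co$targets, co$ratings)
    w <- wald_type2(rm$rating_on_std)
    w$p[w$term == "std25"] < 0.05
  })
  expect_true(all(sig))
  # null: ratings independent of accuracy given STD, so adding the rating
  # rarely improves the accuracy model
  set.seed(39)
  null_sig <- replicate(12, {
    co <- simulate_cohort(8)
    rm <- rating_models(co$targets, co$ratings)
    rm$lrt_rating$p < 0.05
  })
  expect_lte(mean(null_sig), 0.25)
})

test_that("constant ratings trip the degenerate-variance warning", {
  co <- make_small_cohort(4, seed = 40)
  ratings <- co$ratings
  ratings$rating <- 5
  expect_warning(rating_models(co$targets, ratings), "constant")
})

test_that("outlier rater exclusion applies Tukey fences to OLS slopes", {
  stds <- rep(c(0, 25, 50, 75, 100, 150), each = 2)
  mk <- function(subject, slope, intercept = 9) {
    tibble::tibble(subject = subject, condition_std_ms = stds,
                   rating = intercept + slope * stds)
  }
  # identical slopes: nobody excluded
  same <- dplyr::bind_rows(lapply(1:6, function(i) mk(paste0("S", i), -0.03)))
  expect_length(exclude_outlier_raters(same)$excluded, 0)

  # a sign-flipped extreme slope among 19 ordinary raters is excluded
  set.seed(41)
  ordinary <- dplyr::bind_rows(lapply(1:18, function(i)
    mk(paste0("S", i), rnorm(1, -0.03, 0.004))))
  flipped <- mk("S19", +0.03)
  out <- exclude_outlier_raters(dplyr::bind_rows(ordinary, flipped))
  expect_identical(out$excluded, "S19")

  # fences equal a hand-computed Tukey fence on an 8-value toy set
  slopes <- c(-0.05, -0.04, -0.035, -0.03, -0.028, -0.025, -0.02, 0.04)
  toy <- dplyr::bind_rows(lapply(seq_along(slopes), function(i)
    mk(paste0("S", i), slopes[i])))
  out2 <- exclude_outlier_raters(toy)
  q <- quantile(slopes, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(unname(out2$fences),
               c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q)),
               tolerance = 1e-10)
  expect_identical(out2$excluded, "S8")
  expect_error(exclude_outlier_raters(mk("only", -0.03)), "at least 4")
})
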