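# Validation harnesses: parameter-recovery, calibration, and error-control
# experiments run on synthetic cohorts. These are the package's own
# evidence that the analysis machinery measures what the generator plants.

#' Recover the planted global-STD slopes from simulated cohorts
#'
#' Simulates replicate cohorts at the design scale (19 subjects, 12
#' blocks) and, per replicate, fits the two global-STD mixed models:
#' the binomial logit model (subject random intercept), summarized as the
#' average marginal effect of +25 ms of STD on percent correct; and the
#' identity-link gamma model (subject random intercept and slope), whose
#' fixed slope is the RT increase in ms per +25 ms of STD.
#'
#' @param n_reps Number of replicate cohorts (default 20).
#' @param n_subjects Subjects per cohort (default 19).
#' @param params Observer parameters (defaults plant 0.6 pp and 5 ms per
#'   25 ms).
#' @param seed Optional seed set once before the first replicate.
#' @return Tibble with one row per replicate: `acc_decline_pp` (percent-
#'   correct decline per +25 ms, positive = decline) and `rt_slope_ms`
#'   (RT increase per +25 ms).
#' @export
recover_global_slopes <- function(n_reps = 20, n_subjects = 19,
                                  params = observer_params(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n_reps), function(r) {
    co <- simulate_cohort(n_subjects, params)
    d <- as.data.frame(co$targets)
    d$std25 <- d$condition_std_ms / 25
    acc <- fit_glmm(correct ~ std25 + (1 | subject), d, family = "binomial")
    ame <- average_marginal_effect(acc, d, "std25")
    # the generator plants no between-subject slope variance, so the
    # random-slope fit sits on the boundary; its fixed slope is still the
    # quantity of interest
    rt <- suppressWarnings(
      fit_glmm(rt_ms ~ std25 + (std25 | subject), d, family = "gamma",
               link = "identity"))
    tibble::tibble(rep = r,
                   acc_decline_pp = -100 * ame,
                   rt_slope_ms = rt$fixed$estimate[rt$fixed$term == "std25"])
  })
  dplyr::bind_rows(rows)
}

#' Percent correct achieved at the staircase-converged SNR
#'
#' Runs replicate staircases against a listener with a known psychometric
#' function and evaluates the listener's expected percent correct at each
#' converged SNR.
#'
#' @param n_reps Number of replicate staircases (default 100).
#' @param psy The listener's [psychometric_spec()].
#' @param seed Optional seed.
#' @return Numeric vector of expected percent correct, one per replicate.
#' @export
staircase_calibration <- function(n_reps = 100, psy = psychometric_spec(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_reps), function(r) {
    run <- suppressWarnings(run_staircase(psy))
    expected_percent_correct(psy, run$snr_db)
  }, 0)
}

#' Family-wise type-I error of the cluster permutation test
#'
#' Generates pure-noise datasets (iid standard normal, participants x
#' bins) and records the fraction on which the sign-flip cluster test
#' reports at least one significant cluster.
#'
#' @param n_datasets Number of null datasets (default 500).
#' @param n_participants Participants per dataset (default 19).
#' @param dims Bin-grid dimensions for the harness (default 12 x 10).
#' @param n_perm Permutations per test (default 1000).
#' @param seed Optional seed.
#' @return List with `fwer` and the logical `any_sig` vector.
#' @export
cluster_fwer <- function(n_datasets = 500, n_participants = 19,
                         dims = c(12, 10), n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- prod(dims)
  mask <- rep(TRUE, nb)
  any_sig <- vapply(seq_len(n_datasets), function(i) {
    data <- matrix(stats::rnorm(n_participants * nb), nrow = n_participants)
    r <- permutation_test(data, mask, dims, n_perm = n_perm)
    any(vapply(r$clusters, `[[`, TRUE, "significant"))
  }, TRUE)
  list(fwer = mean(any_sig), any_sig = any_sig)
}

#' Type-I error of the Wald test for the global-STD slope
#'
#' Simulates null cohorts (no STD effect, subject random intercepts
#' only), fits the binomial mixed model, and records the rejection rate
#' of the slope's Wald test at the 5% level. For this single-df test the
#' Wald chi-square equals the squared z statistic of the coefficient.
#'
#' @param n_reps Number of null replicates (default 500).
#' @param n_subjects,n_per_subject Null-cohort size (defaults 12 x 120).
#' @param tau SD of the subject intercepts on the logit scale.
#' @param seed Optional seed.
#' @return List with `rate` and the logical `reject` vector.
#' @export
wald_slope_type1 <- function(n_reps = 500, n_subjects = 12,
                             n_per_subject = 120, tau = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reject <- vapply(seq_len(n_reps), function(r) {
    d <- expand.grid(subject = factor(seq_len(n_subjects)),
                     i = seq_len(n_per_subject))
    d$std25 <- sample(c(0, 1, 2, 3, 4, 6), nrow(d), replace = TRUE)
    eta <- stats::qlogis(0.8) +
      stats::rnorm(n_subjects, 0, tau)[as.integer(d$subject)]
    d$correct <- stats::rbinom(nrow(d), 1, stats::plogis(eta))
    fit <- fit_glmm(correct ~ std25 + (1 | subject), d, family = "binomial")
    fit$fixed$p[fit$fixed$term == "std25"] < 0.05
  }, TRUE)
  list(rate = mean(reject), reject = reject)
}
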