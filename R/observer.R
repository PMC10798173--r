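# Parametric synthetic observer: a generative model of deviant
# discrimination whose accuracy, response times, and rhythmicity ratings
# carry the effect structure the analyses are designed to detect.
#
# Accuracy is linear in probability (not logistic) so that a planted
# "percentage points per 25 ms of STD" slope equals the average marginal
# effect that the logistic mixed model estimates on the response scale.

#' Observer parameters
#'
#' Defaults plant a decline of 0.6 percentage points of accuracy and an
#' increase of 5 ms of response time per 25 ms of global SOA STD, with no
#' local-statistics effects, a 2% lapse rate, and moderate between-subject
#' variability.
#'
#' @param p0 Baseline probability correct in the periodic condition.
#' @param acc_slope_global Accuracy decline per ms of global STD
#'   (probability scale; default 0.006/25).
#' @param acc_slope_local Accuracy decline per ms of local SOA STD.
#' @param mean_tuning_amp Amplitude of a Gaussian accuracy bonus for local
#'   mean SOA near 500 ms (probability scale; default 0 = off).
#' @param mean_tuning_width Width (SD, ms) of that tuning curve.
#' @param lapse Lapse rate: on a lapse the observer guesses (p = 0.5).
#' @param rt0 Baseline mean response time, ms.
#' @param rt_slope_global RT increase per ms of global STD (default 5/25).
#' @param rt_slope_local RT increase per ms of local SOA STD.
#' @param rt_gamma_shape Gamma shape of the RT distribution (CV ~ 22% at
#'   the default 20).
#' @param subj_acc_sd SD of subject accuracy offsets (probability scale).
#' @param subj_rt_sd SD of subject RT offsets, ms.
#' @param rating_intercept Expected rhythmicity rating (0-10 scale) in the
#'   periodic condition.
#' @param rating_slope Rating change per ms of global STD (negative).
#' @param rating_noise_sd SD of rating noise.
#' @param local_n Window length N whose local mean/STD drive the
#'   local-effect terms of the generative model.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(p0 = 0.80,
                            acc_slope_global = 0.006 / 25,
                            acc_slope_local = 0,
                            mean_tuning_amp = 0,
                            mean_tuning_width = 50,
                            lapse = 0.02,
                            rt0 = 500,
                            rt_slope_global = 5 / 25,
                            rt_slope_local = 0,
                            rt_gamma_shape = 20,
                            subj_acc_sd = 0.05,
                            subj_rt_sd = 50,
                            rating_intercept = 9,
                            rating_slope = -0.04,
                            rating_noise_sd = 1.5,
                            local_n = 4) {
  p <- as.list(environment())
  stopifnot(p$p0 >= 0, p$p0 <= 1, p$lapse >= 0, p$lapse <= 1,
            p$rt0 > 0, p$rt_gamma_shape > 0, p$subj_acc_sd >= 0,
            p$subj_rt_sd >= 0, p$rating_noise_sd >= 0,
            p$local_n %in% 2:7)
  structure(p, class = "observer_params")
}

# Zero-mean Gaussian tuning of accuracy around a 500 ms local mean: the
# kernel is centred by its average over the 400-600 ms reference range so
# turning the term on does not shift overall accuracy.
mean_tuning_term <- function(params, local_mean_ms) {
  if (params$mean_tuning_amp == 0) return(0)
  w <- params$mean_tuning_width
  kern <- function(x) exp(-(x - 500)^2 / (2 * w^2))
  centre <- stats::integrate(kern, 400, 600)$value / 200
  params$mean_tuning_amp * (kern(local_mean_ms) - centre)
}

#' Per-trial success probability
#'
#' Linear-probability model: baseline plus subject offset, minus global and
#' local STD penalties, plus the local-mean tuning term; mixed with the
#' lapse rate (`p <- (1 - lapse) p + lapse/2`) and clamped to
#' `[0.05, 0.95]`.
#'
#' @param params An [observer_params()].
#' @param subject_offset Subject accuracy offset (probability scale).
#' @param global_std_ms Condition STD, ms.
#' @param local_mean_ms,local_std_ms Local window statistics, ms.
#' @return Probability of a correct response.
#' @export
trial_success_probability <- function(params, subject_offset,
                                      global_std_ms,
                                      local_mean_ms = 500,
                                      local_std_ms = 0) {
  stopifnot(inherits(params, "observer_params"))
  p <- params$p0 + subject_offset -
    params$acc_slope_global * global_std_ms -
    params$acc_slope_local * local_std_ms +
    mean_tuning_term(params, local_mean_ms)
  p <- (1 - params$lapse) * p + params$lapse * 0.5
  pmin(0.95, pmax(0.05, p))
}

#' Expected response time on a target
#'
#' @inheritParams trial_success_probability
#' @param rt_offset Subject RT offset, ms.
#' @return Expected RT, ms (the mean of the gamma RT distribution).
#' @export
trial_expected_rt <- function(params, rt_offset, global_std_ms,
                              local_std_ms = 0) {
  params$rt0 + rt_offset +
    params$rt_slope_global * global_std_ms +
    params$rt_slope_local * local_std_ms
}

#' Simulate one subject's responses to a session
#'
#' For each target trial: a Bernoulli correct/incorrect draw at
#' [trial_success_probability()] and a gamma response time with shape
#' `rt_gamma_shape` and mean [trial_expected_rt()], with local statistics
#' taken from the `local_n`-trial history window.
#'
#' @param session An `oddball_session`.
#' @param params An [observer_params()].
#' @param acc_offset,rt_offset This subject's accuracy and RT offsets.
#' @return A tibble with one row per target: `block`, `condition_std_ms`,
#'   `trial_index`, `is_deviant`, history features (`last_soa_ms`,
#'   `mean_1..7`, `std_2..7`), `p_correct`, `correct`, `rt_ms`.
#' @export
simulate_session_responses <- function(session, params,
                                       acc_offset = 0, rt_offset = 0) {
  stopifnot(inherits(session, "oddball_session"),
            inherits(params, "observer_params"))
  rows <- lapply(seq_along(session$blocks), function(b) {
    blk <- session$blocks[[b]]
    feat <- compute_history_features(blk)
    std <- blk$condition$std_soa
    local_mean <- feat[[paste0("mean_", params$local_n)]]
    local_std <- feat[[paste0("std_", params$local_n)]]
    p <- trial_success_probability(params, acc_offset, std,
                                   local_mean, local_std)
    mu <- trial_expected_rt(params, rt_offset, std, local_std)
    k <- params$rt_gamma_shape
    tibble::tibble(
      block = b,
      condition_std_ms = std,
      feat,
      is_deviant = blk$trials$is_deviant[blk$trials$is_target],
      p_correct = p,
      correct = as.integer(stats::runif(nrow(feat)) < p),
      rt_ms = stats::rgamma(nrow(feat), shape = k, scale = mu / k)
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate per-block rhythmicity ratings
#'
#' Rating of how periodic a block sounded, on a 0-10 scale: a linear
#' decline in the condition STD plus Gaussian noise, clamped to the scale.
#'
#' @param session An `oddball_session`.
#' @param params An [observer_params()].
#' @param rating_slope Override of the subject's rating slope (rating
#'   units per ms); defaults to the population value in `params`.
#' @return A tibble with `block`, `condition_std_ms`, `rating`.
#' @export
simulate_ratings <- function(session, params,
                             rating_slope = params$rating_slope) {
  std <- session$condition_order
  rating <- params$rating_intercept + rating_slope * std +
    stats::rnorm(length(std), 0, params$rating_noise_sd)
  tibble::tibble(block = seq_along(std), condition_std_ms = std,
                 rating = pmin(10, pmax(0, rating)))
}

#' Simulate a full cohort
#'
#' Generates `n_subjects` sessions (12 blocks each by default), subject
#' random effects, target responses, and per-block ratings: the study
#' conditions of the design (19 subjects, 6 conditions, 2 blocks per
#' condition, 410 trials and 56 targets per block).
#'
#' @param n_subjects Number of subjects (default 19).
#' @param params An [observer_params()].
#' @param seed Optional integer seed; recorded in the result.
#' @param conditions Condition list, passed to [build_session()].
#' @return List of class `cohort` with tibbles `targets` (one row per
#'   target with responses and history features), `ratings`, `stream`
#'   (full per-trial timeline), the `params`, subject effect tables, and
#'   the `seed`.
#' @export
simulate_cohort <- function(n_subjects = 19, params = observer_params(),
                            seed = NULL,
                            conditions = default_conditions()) {
  if (!is.null(seed)) set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  acc_off <- stats::rnorm(n_subjects, 0, params$subj_acc_sd)
  rt_off <- stats::rnorm(n_subjects, 0, params$subj_rt_sd)
  targets <- list(); ratings <- list(); stream <- list()
  for (i in seq_len(n_subjects)) {
    ses <- build_session(subjects[i], conditions = conditions)
    resp <- simulate_session_responses(ses, params, acc_off[i], rt_off[i])
    targets[[i]] <- tibble::tibble(subject = subjects[i], resp)
    ratings[[i]] <- tibble::tibble(subject = subjects[i],
                                   simulate_ratings(ses, params))
    stream[[i]] <- session_trials(ses)
  }
  structure(list(
    targets = dplyr::bind_rows(targets),
    ratings = dplyr::bind_rows(ratings),
    stream = dplyr::bind_rows(stream),
    params = params,
    subject_effects = tibble::tibble(subject = subjects,
                                     acc_offset = acc_off,
                                     rt_offset = rt_off),
    seed = seed
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("simulated cohort: %d subjects, %d target trials, seed %s\n",
              length(unique(x$targets$subject)), nrow(x$targets),
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}
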