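# Adaptive staircase for setting the tone-in-noise signal-to-noise ratio.
# A transformed 3-down-1-up rule converges near 79.4% correct, matching
# the ~80% working point the discrimination task is calibrated to.

#' Psychometric function of a synthetic listener
#'
#' Cumulative-Gaussian psychometric function for the two-alternative
#' standard/deviant discrimination: chance floor 0.5, optional lapse.
#'
#' @param threshold_db SNR (dB) at the inflection of the curve.
#' @param slope_db Width (SD, dB) of the cumulative Gaussian.
#' @param lapse Lapse rate (the asymptote is `1 - lapse/...`); on a lapse
#'   the listener guesses.
#' @param floor Chance level; fixed at 0.5 for the binary discrimination.
#' @return An object of class `psychometric_spec`.
#' @export
psychometric_spec <- function(threshold_db = -15, slope_db = 3,
                              lapse = 0.02, floor = 0.5) {
  stopifnot(slope_db > 0, lapse >= 0, lapse <= 1, floor == 0.5)
  structure(list(threshold_db = threshold_db, slope_db = slope_db,
                 lapse = lapse, floor = floor),
            class = "psychometric_spec")
}

#' Probability correct at a given SNR
#'
#' @param psy A [psychometric_spec()].
#' @param snr_db SNR in dB (vectorized).
#' @return Probability of a correct discrimination.
#' @export
psychometric_p <- function(psy, snr_db) {
  stopifnot(inherits(psy, "psychometric_spec"))
  base <- psy$floor +
    (1 - psy$floor) * stats::pnorm((snr_db - psy$threshold_db) / psy$slope_db)
  (1 - psy$lapse) * base + psy$lapse * psy$floor
}

#' Expected percent correct at an SNR
#'
#' @inheritParams psychometric_p
#' @return Percent correct (0-100).
#' @export
expected_percent_correct <- function(psy, snr_db) 100 * psychometric_p(psy, snr_db)

#' Run a 3-down-1-up adaptive staircase
#'
#' Simulates the SNR calibration phase: a 75-tone periodic stream in which
#' a target occurs every 2-3 tones (uniform). After three consecutive
#' correct target responses the SNR drops by one step (harder); after any
#' error it rises by one step (easier). The step size is halved once,
#' after the first two reversals. The converged SNR is the mean SNR over
#' the final four reversals; with fewer than four reversals the run is
#' flagged and the last visited SNR is returned with a warning.
#'
#' @param psy A [psychometric_spec()] describing the simulated listener.
#' @param n_tones Number of tones in the calibration stream (default 75).
#' @param start_snr_db Starting SNR, dB.
#' @param step_db Initial step size, dB.
#' @return List of class `staircase_run`: `snr_db` (converged SNR),
#'   `reversals` (SNR at each reversal), `track` (per-target SNR and
#'   outcome), `converged` flag.
#' @export
run_staircase <- function(psy, n_tones = 75, start_snr_db = -5,
                          step_db = 4) {
  stopifnot(inherits(psy, "psychometric_spec"))
  # target positions: every 2-3 tones, uniformly
  pos <- integer(0); t <- 0L
  repeat {
    t <- t + sample(2:3, 1L)
    if (t > n_tones) break
    pos <- c(pos, t)
  }
  snr <- start_snr_db
  step <- step_db
  n_correct_run <- 0L
  last_dir <- 0L           # -1 going down, +1 going up
  reversal_snr <- numeric(0)
  track <- matrix(NA_real_, nrow = length(pos), ncol = 2,
                  dimnames = list(NULL, c("snr_db", "correct")))
  for (k in seq_along(pos)) {
    correct <- stats::runif(1) < psychometric_p(psy, snr)
    track[k, ] <- c(snr, as.numeric(correct))
    dir <- 0L
    if (!correct) {
      n_correct_run <- 0L
      dir <- +1L
    } else {
      n_correct_run <- n_correct_run + 1L
      if (n_correct_run == 3L) {
        n_correct_run <- 0L
        dir <- -1L
      }
    }
    if (dir != 0L) {
      if (last_dir != 0L && dir != last_dir) {
        reversal_snr <- c(reversal_snr, snr)
        if (length(reversal_snr) == 2L) step <- step / 2
      }
      last_dir <- dir
      snr <- snr + dir * step
    }
  }
  converged <- length(reversal_snr) >= 4L
  out_snr <- if (converged) {
    mean(utils::tail(reversal_snr, 4L))
  } else {
    warning("staircase did not reach 4 reversals; returning last SNR")
    snr
  }
  structure(list(snr_db = out_snr, reversals = reversal_snr,
                 track = tibble::as_tibble(track), converged = converged),
            class = "staircase_run")
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf("staircase: converged SNR %.2f dB (%d reversals%s)\n",
              x$snr_db, length(x$reversals),
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
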