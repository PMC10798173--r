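#' Define an SOA condition
#'
#' A condition is a discretized Gaussian distribution of stimulus-onset
#' asynchronies (SOAs): equal means (500 ms) but distinct standard
#' deviations, quantized on a 25 ms grid running from 100 to 900 ms.
#' `std_soa = 0` denotes the periodic condition (every SOA exactly at the
#' mean).
#'
#' @param std_soa Standard deviation of the generating Gaussian, in ms.
#'   One of 0, 25, 50, 75, 100, 150.
#' @param mean_soa Mean SOA in ms (default 500).
#' @param grid_min,grid_max,grid_step SOA grid, in ms. The grid must be
#'   symmetric about `mean_soa` and span an exact multiple of `grid_step`.
#' @return An object of class `condition_spec`.
#' @export
#' @examples
#' condition_spec(50)
condition_spec <- function(std_soa,
                           mean_soa = 500,
                           grid_min = 100,
                           grid_max = 900,
                           grid_step = 25) {
  allowed <- c(0, 25, 50, 75, 100, 150)
  if (length(std_soa) != 1 || !is.finite(std_soa) || !(std_soa %in% allowed)) {
    stop("`std_soa` must be one of ", paste(allowed, collapse = ", "),
         " ms, got ", std_soa, call. = FALSE)
  }
  if ((grid_min + grid_max) / 2 != mean_soa) {
    stop("SOA grid must be symmetric about the mean SOA", call. = FALSE)
  }
  if ((grid_max - grid_min) %% grid_step != 0) {
    stop("grid span must be an exact multiple of `grid_step`", call. = FALSE)
  }
  structure(
    list(
      label = if (std_soa == 0) "periodic" else sprintf("gaussian%d", std_soa),
      mean_soa = mean_soa,
      std_soa = std_soa,
      grid_min = grid_min,
      grid_max = grid_max,
      grid_step = grid_step
    ),
    class = "condition_spec"
  )
}

#' The six SOA-variability conditions
#'
#' @param stds Vector of condition STDs in ms; defaults to the full design.
#' @return A named list of [condition_spec()] objects.
#' @export
default_conditions <- function(stds = c(0, 25, 50, 75, 100, 150)) {
  specs <- lapply(stds, condition_spec)
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

#' Discretized Gaussian SOA distribution
#'
#' Evaluates the Gaussian density at each grid point and renormalizes. For
#' the periodic condition the distribution is a point mass at the mean. The
#' grid is symmetric about the mean, so the analytic mean of the discrete
#' distribution equals `mean_soa` exactly; truncation to the grid shrinks
#' the realized STD slightly below the nominal STD (noticeably so at
#' 150 ms).
#'
#' @param spec A [condition_spec()].
#' @return An object of class `soa_distribution` with fields `support`
#'   (grid points, ms) and `probs` (probabilities summing to one).
#' @export
#' @examples
#' d <- soa_distribution(condition_spec(150))
#' sum(d$support * d$probs)   # exactly 500
soa_distribution <- function(spec) {
  stopifnot(inherits(spec, "condition_spec"))
  if (spec$std_soa == 0) {
    out <- list(support = spec$mean_soa, probs = 1, spec = spec)
  } else {
    support <- seq(spec$grid_min, spec$grid_max, by = spec$grid_step)
    w <- exp(-(support - spec$mean_soa)^2 / (2 * spec$std_soa^2))
    out <- list(support = support, probs = w / sum(w), spec = spec)
  }
  structure(out, class = "soa_distribution")
}

#' Moments of a discrete SOA distribution
#'
#' @param dist An [soa_distribution()].
#' @return Named numeric vector with elements `mean` and `sd`
#'   (population SD), in ms.
#' @export
soa_distribution_moments <- function(dist) {
  stopifnot(inherits(dist, "soa_distribution"))
  m <- sum(dist$support * dist$probs)
  v <- sum((dist$support - m)^2 * dist$probs)
  c(mean = m, sd = sqrt(v))
}

#' Draw SOAs from a discrete distribution
#'
#' @param dist An [soa_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of SOAs in ms, each on the grid.
#' @export
sample_soas <- function(dist, n) {
  stopifnot(inherits(dist, "soa_distribution"), n >= 0)
  if (length(dist$support) == 1L) {
    rep(dist$support, n)
  } else {
    sample(dist$support, n, replace = TRUE, prob = dist$probs)
  }
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("SOA condition '%s': mean %g ms, STD %g ms, grid %g-%g by %g ms\n",
              x$label, x$mean_soa, x$std_soa, x$grid_min, x$grid_max,
              x$grid_step))
  invisible(x)
}
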