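# Mixed-model inference suite: global-STD models of accuracy and response
# time, likelihood-ratio model comparison, Type II Wald tests, Tukey
# post-hoc contrasts, local-vs-global variability odds ratios, the
# restricted-SOA analysis, rating models, and rating-based participant
# exclusion.
#
# Backends: lme4 for binomial (logit) and gaussian families; glmmTMB for
# gamma (its identity-link fits are more robust, and both accept the same
# downstream car/emmeans machinery). All fits maximize the (Laplace-
# approximate) marginal likelihood, so likelihood-ratio comparisons are
# valid within a family.

#' Fit a generalized linear mixed model
#'
#' Thin wrapper that dispatches to the appropriate backend and returns a
#' uniform `mixed_fit` object. Random-effect terms use the usual `lme4`
#' formula syntax, e.g. `correct ~ std25 + (1 | subject)`. If a grouping
#' factor has a single level the random term is dropped and an ordinary
#' GLM is fitted (flagged `degenerate`), which is the correct limit of the
#' mixed model.
#'
#' @param formula Model formula including random-effect terms.
#' @param data Data frame of observations.
#' @param family `"binomial"` (logit link), `"gamma"` (log or identity
#'   link), or `"gaussian"` (identity; fitted by ML, not REML).
#' @param link Link function; defaults to logit / log / identity by family.
#' @param start Optional fixed-effect start values (gamma family). For the
#'   identity-link gamma model, starts default to an ordinary gamma GLM
#'   fit of the fixed part, which keeps the optimizer in the positive-mean
#'   region.
#' @return Object of class `mixed_fit`: the backend `model`, `family`,
#'   `link`, tibble `fixed` (term, estimate, se, z, p), `ranef_var`,
#'   `loglik`, `df`, `n_obs`, `converged`, `singular` flags.
#' @export
fit_glmm <- function(formula, data,
                     family = c("binomial", "gamma", "gaussian"),
                     link = NULL, start = NULL) {
  family <- match.arg(family)
  link <- link %||% switch(family, binomial = "logit", gamma = "log",
                           gaussian = "identity")
  bars <- lme4::findbars(formula)
  degenerate <- FALSE
  if (length(bars)) {
    groups <- vapply(bars, function(b) deparse(b[[3]]), "")
    n_levels <- vapply(groups, function(g)
      length(unique(data[[g]])), 0L)
    if (any(n_levels < 2L)) {
      degenerate <- TRUE
      formula <- stats::as.formula(
        paste(deparse(formula[[2]]), "~",
              deparse(lme4::nobars(formula)[[3]])))
    }
  }
  has_re <- length(lme4::findbars(formula)) > 0 && !degenerate

  fam_obj <- switch(family,
    binomial = stats::binomial(link = link),
    gamma = stats::Gamma(link = link),
    gaussian = stats::gaussian(link = link))

  if (!has_re) {
    model <- if (family == "gaussian") {
      stats::lm(formula, data = data)
    } else {
      stats::glm(formula, data = data, family = fam_obj)
    }
  } else if (family == "binomial") {
    model <- lme4::glmer(formula, data = data, family = fam_obj,
                         control = lme4::glmerControl(optimizer = "bobyqa"))
  } else if (family == "gaussian") {
    model <- lme4::lmer(formula, data = data, REML = FALSE)
  } else {
    if (is.null(start) && link == "identity") {
      fixed_part <- lme4::nobars(formula)
      g0 <- stats::glm(fixed_part, data = data, family = fam_obj)
      start <- list(beta = unname(stats::coef(g0)))
    }
    model <- glmmTMB::glmmTMB(formula, data = data, family = fam_obj,
                              start = start)
  }
  new_mixed_fit(model, family, link, degenerate = degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_mixed_fit <- function(model, family, link, degenerate = FALSE) {
  co <- fixef_table(model)
  rv <- ranef_variances(model)
  conv <- fit_converged(model)
  structure(list(model = model, family = family, link = link,
                 fixed = co, ranef_var = rv,
                 loglik = as.numeric(stats::logLik(model)),
                 df = attr(stats::logLik(model), "df"),
                 n_obs = stats::nobs(model),
                 converged = conv,
                 singular = is_singular_fit(model),
                 degenerate = degenerate),
            class = "mixed_fit")
}

fixef_table <- function(model) {
  sm <- summary(model)
  co <- if (inherits(model, "glmmTMB")) sm$coefficients$cond else sm$coefficients
  co <- as.data.frame(co)
  tibble::tibble(term = rownames(co),
                 estimate = co[[1]], se = co[[2]],
                 statistic = co[[3]],
                 p = if (ncol(co) >= 4) co[[4]] else NA_real_)
}

ranef_variances <- function(model) {
  if (inherits(model, c("glmerMod", "lmerMod"))) {
    vc <- as.data.frame(lme4::VarCorr(model))
    tibble::tibble(group = vc$grp, term1 = vc$var1, term2 = vc$var2,
                   value = vc$vcov)
  } else if (inherits(model, "glmmTMB")) {
    vc <- glmmTMB::VarCorr(model)$cond
    rows <- lapply(names(vc), function(g) {
      v <- vc[[g]]
      d <- diag(as.matrix(v))
      tibble::tibble(group = g, term1 = names(d), term2 = NA_character_,
                     value = unname(d))
    })
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(group = character(), term1 = character(),
                   term2 = character(), value = numeric())
  }
}

fit_converged <- function(model) {
  if (inherits(model, c("glmerMod", "lmerMod"))) {
    length(model@optinfo$conv$lme4) == 0
  } else if (inherits(model, "glmmTMB")) {
    isTRUE(model$fit$convergence == 0) && isTRUE(model$sdr$pdHess)
  } else {
    TRUE
  }
}

is_singular_fit <- function(model) {
  if (inherits(model, c("glmerMod", "lmerMod"))) {
    lme4::isSingular(model)
  } else if (inherits(model, "glmmTMB")) {
    vc <- glmmTMB::VarCorr(model)$cond
    any(vapply(vc, function(v) any(diag(as.matrix(v)) < 1e-8), TRUE))
  } else {
    FALSE
  }
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("mixed fit (%s, %s link): %d obs, logLik %.2f%s%s\n",
              x$family, x$link, x$n_obs, x$loglik,
              if (!x$converged) " [NOT converged]" else "",
              if (x$singular) " [singular]" else ""))
  print(x$fixed)
  invisible(x)
}

#' @export
logLik.mixed_fit <- function(object, ...) stats::logLik(object$model)

#' Likelihood-ratio test between nested fits
#'
#' `chi2 = 2 (logLik_full - logLik_null)` (clamped at zero for boundary
#' cases), `df` the difference in parameter counts.
#'
#' @param fit_null,fit_full Nested [fit_glmm()] results on the same data.
#' @return List of class `lrt_result` with `chi2`, `df`, `p`.
#' @export
lrt <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "mixed_fit"), inherits(fit_full, "mixed_fit"))
  if (fit_null$n_obs != fit_full$n_obs) {
    stop("models were fitted to different numbers of observations",
         call. = FALSE)
  }
  if (fit_full$df < fit_null$df) {
    stop("`fit_full` has fewer parameters than `fit_null`; not nested",
         call. = FALSE)
  }
  chi2 <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  df <- fit_full$df - fit_null$df
  if (df == 0) {
    return(structure(list(chi2 = chi2, df = 0L, p = 1), class = "lrt_result"))
  }
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2(%d) = %.3f, p = %.4g\n", x$df, x$chi2, x$p))
  invisible(x)
}

#' Type II Wald chi-square tests of fixed effects
#'
#' Each fixed term is tested by the Wald quadratic form of its
#' coefficients given all other terms ([car::Anova()] with `type = "II"`).
#'
#' @param fit A [fit_glmm()] result.
#' @return Tibble with `term`, `chi2`, `df`, `p`.
#' @export
wald_type2 <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  a <- car::Anova(fit$model, type = "II")
  a <- as.data.frame(a)
  chi_col <- grep("Chisq|LR Chisq", names(a))[1]
  tibble::tibble(term = rownames(a),
                 chi2 = a[[chi_col]],
                 df = a[["Df"]],
                 p = a[[grep("^Pr", names(a))[1]]])
}

#' Tukey-adjusted pairwise contrasts of condition levels
#'
#' Estimated marginal means per factor level on the link scale, all
#' pairwise differences, p-values adjusted by the studentized-range
#' (Tukey) method with large-sample (normal) degrees of freedom.
#'
#' @param fit A [fit_glmm()] result whose fixed part contains `factor_name`
#'   as a factor.
#' @param factor_name Name of the condition factor (default `"condition"`).
#' @return Tibble with `contrast`, `estimate` (link scale), `se`,
#'   `statistic`, `p_tukey`.
#' @export
pairwise_tukey <- function(fit, factor_name = "condition") {
  stopifnot(inherits(fit, "mixed_fit"))
  em <- emmeans::emmeans(fit$model, stats::as.formula(paste("~", factor_name)))
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  stat_col <- intersect(c("z.ratio", "t.ratio"), names(pr))[1]
  tibble::tibble(contrast = as.character(pr$contrast),
                 estimate = pr$estimate, se = pr$SE,
                 statistic = pr[[stat_col]], p_tukey = pr$p.value)
}

#' Average marginal effect of a predictor
#'
#' Response-scale effect of adding `delta` to one predictor, averaged over
#' the observed data, with subject random effects included in the
#' prediction. For a cohort generated under a linear-probability model
#' this is the quantity that recovers the planted slope.
#'
#' @param fit A [fit_glmm()] result.
#' @param data The data the model was fitted to.
#' @param term Predictor column to perturb.
#' @param delta Increment (in the predictor's units; default 1).
#' @return The average marginal effect (response scale) per `delta`.
#' @export
average_marginal_effect <- function(fit, data, term, delta = 1) {
  stopifnot(inherits(fit, "mixed_fit"), term %in% names(data))
  data_hi <- data
  data_hi[[term]] <- data_hi[[term]] + delta
  pr <- function(d) {
    if (inherits(fit$model, "glmmTMB")) {
      stats::predict(fit$model, newdata = d, type = "response")
    } else if (inherits(fit$model, c("glmerMod", "lmerMod"))) {
      stats::predict(fit$model, newdata = d, type = "response",
                     re.form = NULL, allow.new.levels = TRUE)
    } else {
      stats::predict(fit$model, newdata = d, type = "response")
    }
  }
  mean(pr(data_hi) - pr(data))
}

#' Restrict a trial table to targets preceded by the mean SOA
#'
#' Keeps only targets whose immediately preceding SOA equals `target_soa`
#' (exactly representable on the 25 ms grid), removing hazard-rate and
#' last-interval confounds from the global-STD contrast.
#'
#' @param table Target-level trial table with a `last_soa_ms` column.
#' @param target_soa SOA to keep, ms (default 500).
#' @return The filtered table; warns if empty.
#' @export
restrict_to_mean_soa <- function(table, target_soa = 500) {
  out <- table[table$last_soa_ms == target_soa, , drop = FALSE]
  if (nrow(out) == 0) warning("no targets with last SOA == ", target_soa)
  out
}

#' Local-vs-global variability model for one history length
#'
#' Fits a mixed model with three predictors, each scaled per +25 ms:
#' global STD, local STD of the `N` previous SOAs, and the last SOA. For
#' accuracy (binomial) the result row reports odds ratios per +25 ms with
#' Wald 95% CIs, following the convention that an odds ratio above 1 means
#' better performance at *lower* STD (i.e. `OR = exp(-beta)` for the STD
#' terms, `exp(beta)` for the last-SOA term, where `beta` is the
#' log-odds slope per +25 ms).
#'
#' @param table Target-level table with `correct`, `rt_ms`,
#'   `condition_std_ms`, `std_<N>`, `last_soa_ms`, `subject`.
#' @param N History length (2..7) selecting the local STD column.
#' @param measure `"accuracy"` (binomial logit) or `"rt"` (gamma log).
#' @return One-row tibble: `N`, for each predictor the effect and CI
#'   (odds-ratio scale for accuracy, rate-ratio scale for RT), and the
#'   underlying `mixed_fit` in the `fit` list-column.
#' @export
fit_local_global <- function(table, N, measure = c("accuracy", "rt")) {
  stopifnot(N %in% 2:7)
  measure <- match.arg(measure)
  d <- data.frame(
    subject = table$subject,
    y = if (measure == "accuracy") table$correct else table$rt_ms,
    global25 = table$condition_std_ms / 25,
    local25 = table[[paste0("std_", N)]] / 25,
    last25 = table$last_soa_ms / 25
  )
  fit <- fit_glmm(y ~ global25 + local25 + last25 + (1 | subject), d,
                  family = if (measure == "accuracy") "binomial" else "gamma")
  fx <- fit$fixed
  eff <- function(term, flip) {
    b <- fx$estimate[fx$term == term]
    s <- fx$se[fx$term == term]
    sgn <- if (flip) -1 else 1
    c(exp(sgn * b), exp(sgn * b - 1.96 * s), exp(sgn * b + 1.96 * s))
  }
  g <- eff("global25", flip = TRUE)
  l <- eff("local25", flip = TRUE)
  s <- eff("last25", flip = FALSE)
  ci <- function(v) c(min(v[2:3]), max(v[2:3]))
  tibble::tibble(N = N, measure = measure,
                 or_global = g[1], or_global_lo = ci(g)[1], or_global_hi = ci(g)[2],
                 or_local = l[1], or_local_lo = ci(l)[1], or_local_hi = ci(l)[2],
                 or_last_soa = s[1], or_last_soa_lo = ci(s)[1],
                 or_last_soa_hi = ci(s)[2],
                 fit = list(fit))
}

#' Rating analyses
#'
#' Two exploratory analyses of the per-block rhythmicity ratings:
#' (1) does adding the rating as a fixed effect improve the global-STD
#' accuracy model (likelihood-ratio test)? (2) how does the rating depend
#' on the global STD (linear mixed model, ML)?
#'
#' @param targets Target-level table (`subject`, `block`,
#'   `condition_std_ms`, `correct`).
#' @param ratings Per-block ratings (`subject`, `block`, `rating`).
#' @return List with `lrt_rating` (the model-comparison [lrt()]),
#'   `fit_with_rating`, `fit_without_rating`, and `rating_on_std`
#'   (the rating ~ STD linear mixed fit).
#' @export
rating_models <- function(targets, ratings) {
  d <- dplyr::inner_join(targets, ratings[c("subject", "block", "rating")],
                         by = c("subject", "block"))
  d$std25 <- d$condition_std_ms / 25
  m0 <- fit_glmm(correct ~ std25 + (1 | subject), d, family = "binomial")
  m1 <- fit_glmm(correct ~ std25 + rating + (1 | subject), d,
                 family = "binomial")
  r <- unique(ratings[c("subject", "block", "condition_std_ms", "rating")])
  r$std25 <- r$condition_std_ms / 25
  if (stats::sd(r$rating) == 0) {
    warning("ratings are constant; rating-on-STD model is degenerate")
  }
  m_r <- fit_glmm(rating ~ std25 + (1 | subject), r, family = "gaussian")
  list(lrt_rating = lrt(m0, m1),
       fit_without_rating = m0, fit_with_rating = m1,
       rating_on_std = m_r)
}

#' Exclude subjects with outlier rating-vs-STD slopes
#'
#' Per subject, the ordinary least-squares slope of rating on condition
#' STD is computed; subjects whose slope lies beyond 1.5 interquartile
#' ranges from the cohort's slope quartiles (Tukey fences,
#' linear-interpolation quantiles) are excluded.
#'
#' @param ratings Per-block ratings (`subject`, `condition_std_ms`,
#'   `rating`).
#' @return List with `kept` and `excluded` subject vectors, the per-
#'   subject `slopes`, and the `fences`.
#' @export
exclude_outlier_raters <- function(ratings) {
  subjects <- unique(ratings$subject)
  if (length(subjects) < 4) {
    stop("at least 4 subjects are needed to define the quartile fences",
         call. = FALSE)
  }
  slopes <- vapply(subjects, function(s) {
    d <- ratings[ratings$subject == s, ]
    unname(stats::coef(stats::lm(rating ~ condition_std_ms, data = d))[2])
  }, 0)
  q <- stats::quantile(slopes, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  keep <- slopes >= fences["lower"] & slopes <= fences["upper"]
  list(kept = subjects[keep], excluded = subjects[!keep],
       slopes = tibble::tibble(subject = subjects, slope = slopes),
       fences = fences)
}
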