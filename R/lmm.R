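# Linearized mixed-model framework.
#
# The normalized indifference points are mapped to y = log((1 - SV')/SV'),
# which turns the hyperbolic curve into the offset line y = log k + log T and
# the two-parameter logistic curve into y = -a b + a log T. Models are fit by
# maximum likelihood (never REML) so likelihood-ratio tests and AIC/BIC
# comparisons across fixed-effect structures are valid.

#' Boundary clamp for the logit transform of a task grid
#'
#' Half the smallest step between adjacent levels on the normalized
#' subjective-value scale, computed from the task configuration: the transform
#' is infinite exactly at the boundary values the staircase can produce, so
#' they are pulled in by less than the grid can resolve.
#'
#' @param task a `dd_task`.
#' @return Clamp value in (0, 0.5).
#' @export
default_logit_eps <- function(task) {
  min(diff(task_levels_norm(task))) / 2
}

#' Log-odds transform of a normalized subjective value
#'
#' `y = log((1 - SV') / SV')` with `SV'` clamped to `[eps, 1 - eps]`; strictly
#' decreasing in `SV'`.
#'
#' @param sv_norm normalized subjective value in `[0, 1]`; vectorized.
#' @param eps clamp in (0, 0.5), typically [default_logit_eps()].
#' @export
logit_transform <- function(sv_norm, eps) {
  if (eps <= 0 || eps >= 0.5) stop("`eps` must be in (0, 0.5)", call. = FALSE)
  p <- pmin(pmax(sv_norm, eps), 1 - eps)
  log((1 - p) / p)
}

#' @rdname logit_transform
#' @param y transformed value.
#' @export
inv_logit_transform <- function(y) 1 / (1 + exp(y))

#' Assemble the mixed-model dataset from indifference points
#'
#' @param points indifference points with columns `participant_id`, `delay`,
#'   `sv_norm` (e.g. the `points` table of a [generate_study()] bundle,
#'   filtered to one task).
#' @param task the task configuration (supplies the clamp).
#' @param eps clamp override.
#' @return Data frame with `participant_id`, `log_delay`, `y`.
#' @export
make_lmm_data <- function(points, task, eps = default_logit_eps(task)) {
  data.frame(participant_id = points$participant_id,
             log_delay = log(points$delay),
             y = logit_transform(points$sv_norm, eps),
             stringsAsFactors = FALSE)
}

.lmm_params <- function(fit) as.integer(attr(stats::logLik(fit), "df"))

.fit_lmer_quiet <- function(formula, data) {
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(formula, data = data, REML = FALSE)),
    warning = function(w) invokeRestart("muffleWarning"))
  fit
}

.as_dd_lmm <- function(fit, model, data, re_covariate) {
  fe <- lme4::fixef(fit)
  # vcov can fail on perfectly degenerate (zero-variance) fits; flag, don't stop
  se <- tryCatch(suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit))))),
                 error = function(e) rep(NA_real_, length(fe)))
  vc <- lme4::VarCorr(fit)
  ll <- stats::logLik(fit)
  k <- .lmm_params(fit)
  n <- stats::nobs(fit)
  structure(
    list(model = model,
         fixed_effects = data.frame(term = names(fe), estimate = as.numeric(fe),
                                    se = as.numeric(se),
                                    t = as.numeric(fe) / as.numeric(se)),
         random_sd = stats::setNames(attr(vc[[1]], "stddev"),
                                     colnames(vc[[1]])),
         re_vcov = as.matrix(vc[[1]]),
         residual_sd = attr(vc, "sc"),
         loglik = as.numeric(ll),
         n_params = k,
         aic = -2 * as.numeric(ll) + 2 * k,
         bic = -2 * as.numeric(ll) + k * log(n),
         n_obs = n,
         n_groups = lme4::ngrps(fit)[[1]],
         singular = lme4::isSingular(fit),
         re_covariate = re_covariate,
         data = data,
         fit = fit),
    class = "dd_lmm")
}

#' Fit a discounting mixed model by maximum likelihood
#'
#' Three nested models of the transformed indifference points:
#' \describe{
#'   \item{null}{`y ~ 1 + (1 | participant)` — per-participant means, constant
#'     in delay.}
#'   \item{hyperbolic}{`y ~ 1 + offset(log_delay) + (1 | participant)` — the
#'     coefficient on log-delay is fixed to 1; the intercepts are the
#'     per-participant and group log discounting rates.}
#'   \item{logistic}{`y ~ log_delay + (log_delay | participant)` — free,
#'     correlated random intercept and slope; the fixed slope estimates the
#'     group slope-at-inflection `a` and the intercept `-a b`.}
#' }
#' Singular variance-component estimates are flagged (`$singular`), not raised.
#'
#' @param data output of [make_lmm_data()].
#' @param model `"null"`, `"hyperbolic"` or `"logistic"`.
#' @return An object of class `dd_lmm`.
#' @export
fit_lmm <- function(data, model = c("null", "hyperbolic", "logistic")) {
  model <- match.arg(model)
  need <- c("participant_id", "log_delay", "y")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (length(unique(data$participant_id)) < 2L) {
    stop("need at least 2 participants", call. = FALSE)
  }
  if (length(unique(data$log_delay)) < 2L) {
    stop("need at least 2 distinct delays", call. = FALSE)
  }
  f <- switch(model,
              null = y ~ 1 + (1 | participant_id),
              hyperbolic = y ~ 1 + offset(log_delay) + (1 | participant_id),
              logistic = y ~ log_delay + (log_delay | participant_id))
  fit <- .fit_lmer_quiet(f, data)
  .as_dd_lmm(fit, model, data,
             re_covariate = if (model == "logistic") "log_delay" else NULL)
}

#' Fit the pleasantness mixed model
#'
#' `Pleasantness ~ Occlusion` with a random intercept per participant and,
#' optionally, a random occlusion slope (the during-task variant restricts
#' occlusion to a fixed effect because choices limit the sampled range).
#'
#' @param data data frame with `participant_id`, `occlusion`, `pleasantness`.
#' @param random_slope include occlusion as a random effect as well.
#' @param null_model fit the intercepts-only null instead.
#' @return An object of class `dd_lmm`.
#' @export
fit_pleasantness <- function(data, random_slope = TRUE, null_model = FALSE) {
  need <- c("participant_id", "occlusion", "pleasantness")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  f <- if (null_model) {
    pleasantness ~ 1 + (1 | participant_id)
  } else if (random_slope) {
    pleasantness ~ occlusion + (occlusion | participant_id)
  } else {
    pleasantness ~ occlusion + (1 | participant_id)
  }
  model <- if (null_model) "pleasantness_null"
           else if (random_slope) "pleasantness_full" else "pleasantness_fixed"
  fit <- .fit_lmer_quiet(f, data)
  .as_dd_lmm(fit, model, data,
             re_covariate = if (!null_model && random_slope) "occlusion" else NULL)
}

.nested_pairs <- list(c("null", "hyperbolic"), c("null", "logistic"),
                      c("hyperbolic", "logistic"),
                      c("pleasantness_null", "pleasantness_fixed"),
                      c("pleasantness_null", "pleasantness_full"),
                      c("pleasantness_fixed", "pleasantness_full"))

#' Likelihood-ratio test between two nested mixed models
#'
#' `chi2 = 2 (logLik1 - logLik0)` (floored at zero) on `df` equal to the
#' parameter-count difference. Comparisons whose counted parameters coincide
#' (the hyperbolic model replaces the null's free mean structure with a fixed
#' offset, leaving the count unchanged) are reported with `df = 0` and a note;
#' under a point mass at zero any positive deviance has upper-tail p = 0.
#'
#' @param fit0 the restricted `dd_lmm`.
#' @param fit1 the more general `dd_lmm`, fit to the same data.
#' @return A list: `chi2`, `df`, `p`, `note`.
#' @export
compare_lmm <- function(fit0, fit1) {
  if (!inherits(fit0, "dd_lmm") || !inherits(fit1, "dd_lmm")) {
    stop("both arguments must be dd_lmm fits", call. = FALSE)
  }
  ok <- fit0$model == fit1$model ||
    any(vapply(.nested_pairs, function(p) identical(p, c(fit0$model, fit1$model)),
               logical(1)))
  if (!ok) {
    stop(sprintf("'%s' is not nested in '%s'", fit0$model, fit1$model), call. = FALSE)
  }
  if (fit0$n_obs != fit1$n_obs) stop("fits use different data", call. = FALSE)
  chi2 <- max(0, 2 * (fit1$loglik - fit0$loglik))
  df <- fit1$n_params - fit0$n_params
  if (df > 0) {
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
    note <- NA_character_
  } else {
    p <- if (chi2 > 0) 0 else 1
    note <- "df = 0 boundary comparison: models have equal counted parameters"
  }
  list(chi2 = chi2, df = as.integer(df), p = p, note = note)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed plus
#' random effects (conditional), each relative to the total of fixed, random
#' and residual variance. The random-effect variance for random-slope models is
#' the average over observations of the variance contributed by the
#' participant-level effects.
#'
#' @param fit a `dd_lmm`.
#' @return Named vector `c(marginal =, conditional =)`.
#' @export
nakagawa_r2 <- function(fit) {
  if (!inherits(fit, "dd_lmm")) stop("`fit` must be a dd_lmm", call. = FALSE)
  pred_fixed <- stats::predict(fit$fit, re.form = NA)
  var_f <- stats::var(pred_fixed)
  G <- fit$re_vcov
  if (is.null(fit$re_covariate)) {
    var_re <- G[1, 1]
  } else {
    x <- fit$data[[fit$re_covariate]]
    Z <- cbind(1, x)
    var_re <- mean(rowSums((Z %*% G) * Z))
  }
  var_e <- fit$residual_sd^2
  total <- var_f + var_re + var_e
  if (total <= 0) stop("undefined: total variance is zero", call. = FALSE)
  c(marginal = var_f / total, conditional = (var_f + var_re) / total)
}

#' @export
print.dd_lmm <- function(x, ...) {
  cat(sprintf("<dd_lmm: %s> logLik %.1f, AIC %.1f, BIC %.1f (n = %d, groups = %d)%s\n",
              x$model, x$loglik, x$aic, x$bic, x$n_obs, x$n_groups,
              if (x$singular) " [singular]" else ""))
  fe <- x$fixed_effects
  for (i in seq_len(nrow(fe))) {
    cat(sprintf("  %s = %.3f (SE %.3f)\n", fe$term[i], fe$estimate[i], fe$se[i]))
  }
  invisible(x)
}
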