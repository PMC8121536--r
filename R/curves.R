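#' Hyperbolic subjective value
#'
#' `SV = M / (1 + k T)` with the delayed magnitude normalized to `M = 1`:
#' the classic one-parameter discounting curve.
#'
#' @param T_ delay (> 0); vectorized.
#' @param k discount rate (>= 0), in 1/time-units.
#' @return Subjective value in (0, 1].
#' @export
sv_hyperbolic <- function(T_, k) {
  if (any(T_ < 0) || any(k < 0)) stop("`T_` and `k` must be non-negative", call. = FALSE)
  1 / (1 + k * T_)
}

#' Logistic subjective value on the log-delay axis
#'
#' `SV = 1 / (1 + exp(a (log T - b)))`: `b` is the log-delay at which the
#' chooser switches preference (SV = 0.5) and `a` the sharpness of that switch.
#' The hyperbolic curve is the special case `a = 1`, `b = -log k`.
#'
#' @param T_ delay (> 0); vectorized.
#' @param a slope at inflection (> 0).
#' @param b log-delay at inflection.
#' @return Subjective value in (0, 1).
#' @export
sv_logistic <- function(T_, a, b) {
  if (any(T_ <= 0)) stop("`T_` must be > 0", call. = FALSE)
  if (any(a <= 0)) stop("`a` must be > 0", call. = FALSE)
  1 / (1 + exp(a * (log(T_) - b)))
}

#' Rachlin power-function subjective value
#'
#' `SV = 1 / (1 + k T^s)`; equivalent to [sv_logistic()] with `a = s`,
#' `b = -log(k)/s`.
#' @param T_ delay (> 0).
#' @param k discount rate (> 0).
#' @param s exponent (> 0).
#' @export
sv_rachlin <- function(T_, k, s) {
  if (any(T_ <= 0) || k <= 0 || s <= 0) stop("inputs must be positive", call. = FALSE)
  1 / (1 + k * T_^s)
}

#' Normalize a subjective value so the lowest immediate level maps to 0
#'
#' `SV' = (SV - SV_min) / (1 - SV_min)`, where `SV_min` is the lowest
#' immediate option as a fraction of the delayed reward (0.13 for the
#' experiential grid, 0.01 for the hypothetical grid).
#'
#' @param sv subjective value in `[sv_min, 1]`.
#' @param sv_min lower anchor in `[0, 1)`.
#' @export
normalize_sv <- function(sv, sv_min) {
  if (sv_min < 0 || sv_min >= 1) stop("`sv_min` must be in [0, 1)", call. = FALSE)
  if (any(sv < sv_min - 1e-12) || any(sv > 1 + 1e-12)) {
    stop("`sv` outside [sv_min, 1]", call. = FALSE)
  }
  (sv - sv_min) / (1 - sv_min)
}

#' @rdname normalize_sv
#' @param sv_norm normalized value in `[0, 1]`.
#' @export
denormalize_sv <- function(sv_norm, sv_min) {
  if (sv_min < 0 || sv_min >= 1) stop("`sv_min` must be in [0, 1)", call. = FALSE)
  sv_norm * (1 - sv_min) + sv_min
}

#' Express a hyperbolic curve in the logistic framework
#'
#' The hyperbola `1/(1 + kT)` equals the logistic curve with slope fixed at 1
#' and inflection at the classic discounting rate: `(a, b) = (1, -log k)`.
#'
#' @param k discount rate (> 0).
#' @return Named vector `c(a = 1, b = -log(k))`.
#' @export
hyperbolic_as_logistic <- function(k) {
  if (any(k <= 0)) stop("`k` must be > 0", call. = FALSE)
  c(a = 1, b = -log(k))
}

#' Express a Rachlin power curve in the logistic framework
#'
#' `1/(1 + k T^s)` equals the logistic curve with `a = s` and
#' `b = -log(k)/s`.
#'
#' @param k discount rate (> 0).
#' @param s exponent (> 0).
#' @return Named vector `c(a = s, b = -log(k)/s)`.
#' @export
rachlin_as_logistic <- function(k, s) {
  if (any(k <= 0) || any(s <= 0)) stop("`k` and `s` must be > 0", call. = FALSE)
  c(a = s, b = -log(k) / s)
}

.curve_predict <- function(model, params, T_) {
  switch(model,
         hyperbolic = sv_hyperbolic(T_, params[["k"]]),
         logistic2 = sv_logistic(T_, params[["a"]], params[["b"]]),
         logistic3 = params[["c"]] +
           (1 - params[["c"]]) * sv_logistic(T_, params[["a"]], params[["b"]]),
         stop("unknown model: ", model, call. = FALSE))
}

#' Least-squares fit of a discounting curve to indifference points
#'
#' Minimizes the sum of squared residuals on the *normalized* subjective-value
#' scale over bounded parameters, restarting a local optimizer from a grid of
#' starting values and keeping the best solution (ties broken by lower RMSE,
#' then lower slope). `R^2 = 1 - SS_R/SS_Tot` is reported relative to the mean
#' of the points and may be negative (the mean then describes the data better
#' than the curve); `RMSE = sqrt(SS_R / n)`.
#'
#' @param points data frame with columns `delay` and `sv_norm` (both
#'   indifference points per delay enter as separate observations).
#' @param model `"hyperbolic"`, `"logistic2"` or `"logistic3"` (the latter adds
#'   a lower asymptote `c`: `SV = c + (1-c)/(1+exp(a(logT - b)))`; experimental,
#'   fit only on request).
#' @param a_starts,n_k_starts multi-start grids (see Details).
#' @return An object of class `dd_curve_fit` with `model`, `params`, `rmse`,
#'   `r2`, `n_points`, `converged`, `bounds_hit`.
#' @export
fit_curve <- function(points, model = c("logistic2", "hyperbolic", "logistic3"),
                      a_starts = c(0.25, 1, 4, 16), n_k_starts = 9L) {
  model <- match.arg(model)
  if (!all(c("delay", "sv_norm") %in% names(points))) {
    stop("`points` must have columns `delay` and `sv_norm`", call. = FALSE)
  }
  T_ <- points$delay
  y <- points$sv_norm
  if (length(y) < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(unique(T_)) < 2L) {
    stop("degenerate input: need at least 2 distinct delays", call. = FALSE)
  }
  lt <- log(range(T_))
  ssr <- function(par) {
    p <- stats::setNames(as.list(par), par_names)
    sum((y - .curve_predict(model, p, T_))^2)
  }
  if (model == "hyperbolic") {
    par_names <- "k"
    lower <- 1e-8; upper <- 100
    starts <- matrix(exp(seq(log(1e-6), log(10), length.out = n_k_starts)), ncol = 1)
  } else {
    par_names <- c("a", "b")
    lower <- c(1e-3, lt[1] - 10); upper <- c(1e4, lt[2] + 10)
    b_starts <- seq(lt[1] - 2, lt[2] + 2, length.out = 5)
    starts <- as.matrix(expand.grid(a = a_starts, b = b_starts))
    if (model == "logistic3") {
      par_names <- c("a", "b", "c")
      lower <- c(lower, 0); upper <- c(upper, 0.95)
      starts <- cbind(starts, c = 0.1)
    }
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], ssr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[1] < best$par[1])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("curve fit failed from every start", call. = FALSE)
  params <- stats::setNames(as.numeric(best$par), par_names)
  ss_r <- best$value
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(model = model,
         params = params,
         rmse = sqrt(ss_r / length(y)),
         r2 = if (ss_tot > 0) 1 - ss_r / ss_tot
              else if (ss_r > 0) -Inf else NA_real_,
         n_points = length(y),
         converged = best$convergence == 0,
         bounds_hit = params <= lower + 1e-9 | params >= upper - 1e-9),
    class = "dd_curve_fit")
}

#' @export
print.dd_curve_fit <- function(x, ...) {
  cat(sprintf("<dd_curve_fit: %s> %s | RMSE %.4f, R2 %.3f (n = %d)%s\n",
              x$model,
              paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
              x$rmse, x$r2, x$n_points,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Model-based area under the discounting curve
#'
#' Integrates the fitted two-parameter logistic curve over the delay interval
#' on the linear time axis and normalizes by the interval length, so the result
#' lies in `[0, 1]`; greater AUC indicates greater willingness to wait. The
#' quadrature is split at the inflection delay `exp(b)` so that arbitrarily
#' sharp switch curves integrate accurately.
#'
#' @param fit a `dd_curve_fit` with `model = "logistic2"`, or a named vector /
#'   list carrying `a` and `b`.
#' @param t_min,t_max integration interval, `t_max > t_min > 0`.
#' @return AUC in `[0, 1]`.
#' @export
model_auc <- function(fit, t_min, t_max) {
  if (inherits(fit, "dd_curve_fit")) {
    if (fit$model != "logistic2") stop("`fit` must be a logistic2 fit", call. = FALSE)
    a <- fit$params[["a"]]; b <- fit$params[["b"]]
  } else {
    a <- fit[["a"]]; b <- fit[["b"]]
  }
  if (!(t_max > t_min && t_min > 0)) {
    stop("require t_max > t_min > 0", call. = FALSE)
  }
  f <- function(T_) sv_logistic(T_, a, b)
  cut <- exp(b)
  pieces <- if (cut > t_min && cut < t_max) c(t_min, cut, t_max) else c(t_min, t_max)
  total <- 0
  for (i in seq_len(length(pieces) - 1L)) {
    total <- total + stats::integrate(f, pieces[i], pieces[i + 1L],
                                      rel.tol = 1e-9, abs.tol = 1e-12,
                                      subdivisions = 500L)$value
  }
  min(max(total / (t_max - t_min), 0), 1)
}
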