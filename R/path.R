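# Recursive path models linking anxiety to discounting, estimated by maximum
# likelihood under multivariate normality. Models are parameterized in
# regression (RAM) form: Sigma = (I - B)^-1 Psi (I - B)^-T, with free
# parameters the regression paths, the exogenous variances/covariance, the
# residual variances and the residual covariance between the two task AUCs.
# For recursive systems the ML path estimates coincide with equation-wise
# least squares whenever the cross-equation residual covariances are fixed at
# zero or the model is saturated; the optimizer is started there.

#' Specify an anxiety path model
#'
#' Without mediation: state and trait anxiety predict experiential and
#' hypothetical AUC. With mediation, reward sensitivity is added as mediator of
#' the state-anxiety effect on experiential AUC (state and trait predict reward
#' sensitivity, which predicts experiential AUC alongside the direct paths).
#' Both variants free the exogenous variances and covariance, the outcome
#' residual variances, and the residual covariance between the two AUCs.
#'
#' @param mediation include reward sensitivity as mediator.
#' @return An object of class `dd_path_spec`.
#' @export
path_spec <- function(mediation = FALSE) {
  if (mediation) {
    vars <- c("state", "trait", "rs", "auc_exp", "auc_hyp")
    eqs <- list(rs = c("state", "trait"),
                auc_exp = c("state", "trait", "rs"),
                auc_hyp = c("state", "trait"))
  } else {
    vars <- c("state", "trait", "auc_exp", "auc_hyp")
    eqs <- list(auc_exp = c("state", "trait"),
                auc_hyp = c("state", "trait"))
  }
  structure(list(vars = vars, exog = c("state", "trait"), equations = eqs,
                 resid_cov = list(c("auc_exp", "auc_hyp")),
                 mediation = mediation),
            class = "dd_path_spec")
}

.spec_parameters <- function(spec) {
  pars <- list()
  for (out in names(spec$equations)) {
    for (pred in spec$equations[[out]]) {
      pars[[length(pars) + 1L]] <- list(lhs = out, op = "~", rhs = pred)
    }
  }
  exo <- spec$exog
  pars[[length(pars) + 1L]] <- list(lhs = exo[1], op = "~~", rhs = exo[1])
  pars[[length(pars) + 1L]] <- list(lhs = exo[2], op = "~~", rhs = exo[2])
  pars[[length(pars) + 1L]] <- list(lhs = exo[1], op = "~~", rhs = exo[2])
  for (out in names(spec$equations)) {
    pars[[length(pars) + 1L]] <- list(lhs = out, op = "~~", rhs = out)
  }
  for (rc in spec$resid_cov) {
    pars[[length(pars) + 1L]] <- list(lhs = rc[1], op = "~~", rhs = rc[2])
  }
  pars
}

.implied_sigma <- function(theta, pars, vars) {
  p <- length(vars)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  for (i in seq_along(pars)) {
    pr <- pars[[i]]
    if (pr$op == "~") {
      B[pr$lhs, pr$rhs] <- theta[i]
    } else {
      Psi[pr$lhs, pr$rhs] <- theta[i]
      Psi[pr$rhs, pr$lhs] <- theta[i]
    }
  }
  IB <- solve(diag(p) - B)
  list(Sigma = IB %*% Psi %*% t(IB), B = B, Psi = Psi)
}

.fml <- function(Sigma, S) {
  p <- nrow(S)
  cS <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS)) return(1e10)
  ldS <- 2 * sum(log(diag(cS)))
  as.numeric(ldS + sum(diag(S %*% chol2inv(cS))) -
               determinant(S, logarithm = TRUE)$modulus - p)
}

#' Fit an anxiety path model by maximum likelihood
#'
#' Starts from equation-wise least squares (exact for recursive systems with
#' independent equations, and for saturated models) and minimizes the normal-
#' theory ML discrepancy. Standard errors come from the observed information
#' matrix. Standardized estimates are reported in two conventions: `std_all`
#' (predictor and outcome both scaled by their model-implied SDs) and `std_x`
#' (predictor scaled only), since print conventions differ on whether outcomes
#' are rescaled.
#'
#' @param data data frame containing the spec's variables (`state`, `trait`,
#'   `auc_exp`, `auc_hyp`, plus `rs` for mediation models); complete cases.
#' @param spec a [path_spec()].
#' @return An object of class `dd_path_fit`: estimates table, implied
#'   covariance, log-likelihood, `df`, ML discrepancy and `r2` per outcome.
#' @export
fit_path <- function(data, spec = path_spec()) {
  if (!inherits(spec, "dd_path_spec")) stop("`spec` must be a dd_path_spec", call. = FALSE)
  miss <- setdiff(spec$vars, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(data[, spec$vars])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  pars <- .spec_parameters(spec)
  if (n <= length(pars)) stop("need n greater than the number of free parameters", call. = FALSE)
  p <- ncol(X)
  S <- stats::cov(X) * (n - 1) / n
  if (min(eigen(S, only.values = TRUE, symmetric = TRUE)$values) <= 0) {
    stop("sample covariance is not positive definite", call. = FALSE)
  }
  # equation-wise least-squares start
  theta0 <- numeric(length(pars))
  resid_list <- list()
  for (out in names(spec$equations)) {
    f <- stats::reformulate(spec$equations[[out]], response = out)
    lmfit <- stats::lm(f, data = as.data.frame(X))
    cf <- stats::coef(lmfit)
    resid_list[[out]] <- stats::resid(lmfit)
    for (i in seq_along(pars)) {
      pr <- pars[[i]]
      if (pr$op == "~" && pr$lhs == out) theta0[i] <- cf[[pr$rhs]]
    }
  }
  for (i in seq_along(pars)) {
    pr <- pars[[i]]
    if (pr$op != "~~") next
    if (pr$lhs %in% spec$exog && pr$rhs %in% spec$exog) {
      theta0[i] <- S[pr$lhs, pr$rhs]
    } else if (pr$lhs == pr$rhs) {
      theta0[i] <- mean(resid_list[[pr$lhs]]^2)
    } else {
      theta0[i] <- mean(resid_list[[pr$lhs]] * resid_list[[pr$rhs]])
    }
  }
  obj <- function(th) .fml(.implied_sigma(th, pars, spec$vars)$Sigma, S)
  opt <- stats::optim(theta0, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
  theta <- opt$par
  mats <- .implied_sigma(theta, pars, spec$vars)
  Sigma <- mats$Sigma
  loglik <- -n / 2 * (p * log(2 * pi) +
                        as.numeric(determinant(Sigma, TRUE)$modulus) +
                        sum(diag(S %*% solve(Sigma))))
  nll <- function(th) {
    Sg <- .implied_sigma(th, pars, spec$vars)$Sigma
    cS <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(cS)) return(1e10)
    n / 2 * (p * log(2 * pi) + 2 * sum(log(diag(cS))) + sum(diag(S %*% chol2inv(cS))))
  }
  H <- pracma::hessian(nll, theta)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(theta), length(theta)))
  se <- sqrt(pmax(diag(V), 0))
  sds <- sqrt(diag(Sigma))
  names(sds) <- spec$vars
  est <- do.call(rbind, lapply(seq_along(pars), function(i) {
    pr <- pars[[i]]
    std_all <- if (pr$op == "~") theta[i] * sds[pr$rhs] / sds[pr$lhs]
               else theta[i] / (sds[pr$lhs] * sds[pr$rhs])
    std_x <- if (pr$op == "~") theta[i] * sds[pr$rhs] else std_all
    data.frame(lhs = pr$lhs, op = pr$op, rhs = pr$rhs,
               est = theta[i], se = se[i],
               z = theta[i] / se[i],
               p = 2 * stats::pnorm(abs(theta[i] / se[i]), lower.tail = FALSE),
               std_all = unname(std_all), std_x = unname(std_x),
               stringsAsFactors = FALSE)
  }))
  r2 <- vapply(names(spec$equations), function(out) {
    psi <- est$est[est$op == "~~" & est$lhs == out & est$rhs == out]
    1 - psi / Sigma[out, out]
  }, numeric(1))
  df <- p * (p + 1) / 2 - length(pars)
  structure(
    list(spec = spec, estimates = est, implied = Sigma, sample = S,
         B = mats$B, Psi = mats$Psi,
         n = n, df = as.integer(df), fmin = obj(theta), loglik = loglik,
         r2 = r2, converged = opt$convergence == 0, vcov = V),
    class = "dd_path_fit")
}

#' Fit indices of a path model
#'
#' Comparative fit index against the independence baseline, RMSEA from the
#' noncentral chi-square, and SRMR from standardized residual moments. A
#' saturated model (df = 0) returns CFI = 1 and RMSEA = 0 exactly.
#'
#' @param fit a `dd_path_fit`.
#' @return Named vector `c(chisq =, df =, cfi =, rmsea =, srmr =)`.
#' @export
fit_indices <- function(fit) {
  if (!inherits(fit, "dd_path_fit")) stop("`fit` must be a dd_path_fit", call. = FALSE)
  S <- fit$sample
  n <- fit$n
  p <- nrow(S)
  T_m <- n * fit$fmin
  df_m <- fit$df
  F_b <- .fml(diag(diag(S)), S)
  T_b <- n * F_b
  df_b <- p * (p + 1) / 2 - p
  cfi <- if (df_m == 0) 1 else {
    1 - max(T_m - df_m, 0) / max(T_m - df_m, T_b - df_b, .Machine$double.eps)
  }
  rmsea <- if (df_m == 0) 0 else sqrt(max((T_m - df_m) / (df_m * n), 0))
  D <- fit$sample - fit$implied
  sc <- sqrt(diag(S))
  Dstd <- D / tcrossprod(sc)
  srmr <- sqrt(mean(Dstd[lower.tri(Dstd, diag = TRUE)]^2))
  c(chisq = T_m, df = df_m, cfi = cfi, rmsea = rmsea, srmr = srmr)
}

.get_path <- function(fit, lhs, rhs) {
  i <- which(fit$estimates$op == "~" & fit$estimates$lhs == lhs &
               fit$estimates$rhs == rhs)
  if (length(i) != 1) {
    stop(sprintf("path %s ~ %s is not in the model", lhs, rhs), call. = FALSE)
  }
  fit$estimates[i, ]
}

#' Indirect (mediated) effect
#'
#' Product of the predictor-to-mediator and mediator-to-outcome paths with a
#' delta-method standard error.
#'
#' @param fit a `dd_path_fit` from a mediation [path_spec()].
#' @param from predictor (default `"state"`).
#' @param via mediator (default `"rs"`).
#' @param to outcome (default `"auc_exp"`).
#' @param standardized return the product of fully standardized paths instead.
#' @return List: `estimate`, `se`, `z`, `p`.
#' @export
indirect_effect <- function(fit, from = "state", via = "rs", to = "auc_exp",
                            standardized = FALSE) {
  if (!fit$spec$mediation) stop("model has no mediator", call. = FALSE)
  pa <- .get_path(fit, via, from)
  pb <- .get_path(fit, to, via)
  if (standardized) {
    est <- pa$std_all * pb$std_all
    ra <- pa$std_all / pa$est; rb <- pb$std_all / pb$est
    se <- sqrt((pb$std_all * ra * pa$se)^2 + (pa$std_all * rb * pb$se)^2)
  } else {
    est <- pa$est * pb$est
    se <- sqrt((pb$est * pa$se)^2 + (pa$est * pb$se)^2)
  }
  z <- if (se > 0) est / se else NA_real_
  list(estimate = est, se = se, z = z,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' State-by-trait moderation regression on AUC
#'
#' Ordinary least squares of AUC on state anxiety, trait anxiety and their raw
#' (uncentered) product, as the interaction is conventionally reported on the
#' raw anxiety scale.
#'
#' @param auc,state,trait equal-length numeric vectors (n >= 10).
#' @return List: `coefficients` (term, estimate, se, t, p), `f`, `df`, `r2`.
#' @export
moderation_regression <- function(auc, state, trait) {
  n <- length(auc)
  if (n < 10 || length(state) != n || length(trait) != n) {
    stop("need equal-length vectors with n >= 10", call. = FALSE)
  }
  X <- cbind(1, state, trait, state * trait)
  if (qr(X)$rank < 4) stop("regressors are collinear", call. = FALSE)
  fit <- stats::lm(auc ~ state + trait + I(state * trait))
  sm <- summary(fit)
  co <- sm$coefficients
  list(coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                 se = co[, 2], t = co[, 3], p = co[, 4],
                                 row.names = NULL, stringsAsFactors = FALSE),
       f = unname(sm$fstatistic[1]),
       df = unname(sm$fstatistic[2:3]),
       r2 = sm$r.squared)
}

#' Split-half illustration of the state-by-trait interaction
#'
#' Median split on trait anxiety; within each half, the Pearson correlation of
#' state anxiety with AUC. Warns when median ties put more than 60% of the
#' sample in one half.
#'
#' @param trait,auc,state equal-length numeric vectors (n >= 10).
#' @return Data frame with one row per half: `group`, `n`, `r`, `p`.
#' @export
split_half_groups <- function(trait, auc, state) {
  n <- length(trait)
  if (n < 10 || length(auc) != n || length(state) != n) {
    stop("need equal-length vectors with n >= 10", call. = FALSE)
  }
  med <- stats::median(trait)
  low <- trait <= med
  if (max(sum(low), sum(!low)) > 0.6 * n) {
    warning("median ties place more than 60% of the sample in one half")
  }
  one <- function(sel, label) {
    ct <- stats::cor.test(state[sel], auc[sel])
    data.frame(group = label, n = sum(sel), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }
  rbind(one(low, "low_trait"), one(!low, "high_trait"))
}

#' @export
print.dd_path_fit <- function(x, ...) {
  cat(sprintf("<dd_path_fit>%s n = %d, df = %d, logLik = %.1f\n",
              if (x$spec$mediation) " (mediation)" else "", x$n, x$df, x$loglik))
  reg <- x$estimates[x$estimates$op == "~", ]
  for (i in seq_len(nrow(reg))) {
    cat(sprintf("  %s ~ %s: %.4f (std %.3f, p = %.3f)\n",
                reg$lhs[i], reg$rhs[i], reg$est[i], reg$std_all[i], reg$p[i]))
  }
  invisible(x)
}
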