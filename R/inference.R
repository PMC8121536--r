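#' Welch's t test from summary statistics
#'
#' Two-sided Welch test computed from group means, SDs and sizes, with
#' Welch-Satterthwaite degrees of freedom (reported as the floor, as is usual
#' in print; the exact value is retained). Cohen's d standardizes by the root
#' mean square of the two SDs (the unweighted-variance pooling appropriate when
#' the groups differ greatly in size).
#'
#' @param m1,sd1,n1 first group summary (sd > 0, n >= 2).
#' @param m2,sd2,n2 second group summary.
#' @return List: `t`, `df` (floored), `df_exact`, `p`, `cohens_d`.
#' @export
welch_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be > 0", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df_exact <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df_exact, lower.tail = FALSE)
  list(t = t, df = floor(df_exact), df_exact = df_exact, p = p,
       cohens_d = abs(m1 - m2) / sqrt((sd1^2 + sd2^2) / 2))
}

#' Pearson correlation with t test
#'
#' @param x,y equal-length numeric vectors (n >= 3), neither constant.
#' @return List: `r`, `t`, `df`, `p`.
#' @export
pearson_with_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value)
}

# Exact sampling density of the Pearson correlation r given the population
# correlation rho at sample size n (Hotelling 1953), using the Gauss
# hypergeometric series (argument (1 + rho r)/2 < 1; the large third parameter
# keeps the series convergent and fast).
.hyp2f1 <- function(a, b, cc, z, tol = 1e-13, maxit = 20000L) {
  term <- 1; s <- 1
  for (k in 0:maxit) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) return(s)
  }
  s
}

.dpearson <- function(r, rho, n) {
  lc <- log(n - 2) + lgamma(n - 1) - 0.5 * log(2 * pi) - lgamma(n - 0.5)
  ld <- (n - 1) / 2 * log1p(-rho^2) + (n - 4) / 2 * log1p(-r^2) -
    (n - 1.5) * log1p(-rho * r)
  exp(lc + ld) * .hyp2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
}

.dstretched_beta <- function(rho, scale) {
  a <- 1 / scale
  stats::dbeta((rho + 1) / 2, a, a) / 2
}

#' Default-prior Bayes factor for a Pearson correlation
#'
#' Evidence for a nonzero correlation against the null, computed by numerical
#' integration of the exact sampling density of `r` under a stretched-beta
#' prior on the population correlation (shape `1/prior_scale` on each side;
#' `prior_scale = 1/3` is the conventional "medium" default for correlation
#' tests). The posterior median of the correlation is obtained from the same
#' quadrature, so no MCMC is required.
#'
#' @param r sample Pearson correlation, |r| < 1.
#' @param n sample size (>= 4).
#' @param prior_scale width of the stretched-beta prior (default 1/3).
#' @param posterior also compute the posterior median (default TRUE).
#' @return List: `bf10`, `posterior_median_r`, `prior_scale`.
#' @export
jzs_correlation_bf <- function(r, n, prior_scale = 1/3, posterior = TRUE) {
  if (abs(r) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (n < 4) stop("`n` must be >= 4", call. = FALSE)
  f <- function(rho) {
    vapply(rho, function(p) .dpearson(r, p, n), numeric(1)) *
      .dstretched_beta(rho, prior_scale)
  }
  marg <- stats::integrate(f, -1, 1, rel.tol = 1e-9)$value
  bf10 <- marg / .dpearson(r, 0, n)
  med <- NA_real_
  if (posterior) {
    cdf_half <- function(q) stats::integrate(f, -1, q, rel.tol = 1e-9)$value / marg - 0.5
    med <- stats::uniroot(cdf_half, c(-0.9999, 0.9999), tol = 1e-8)$root
  }
  list(bf10 = bf10, posterior_median_r = med, prior_scale = prior_scale)
}

#' Paired Wilcoxon signed-rank test
#'
#' Exact distribution for n <= 25 informative pairs (without ties), normal
#' approximation above. All-zero differences are degenerate and flagged rather
#' than tested.
#'
#' @param x,y equal-length paired vectors (n >= 5).
#' @return List: `V`, `p`, `degenerate`.
#' @export
paired_signed_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 5) {
    stop("`x` and `y` must have equal length >= 5", call. = FALSE)
  }
  d <- x - y
  if (all(d == 0)) {
    return(list(V = 0, p = NA_real_, degenerate = TRUE))
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = exact))
  list(V = unname(wt$statistic), p = wt$p.value, degenerate = FALSE)
}

#' Perceptual reward sensitivity of one participant
#'
#' The absolute Pearson correlation between occlusion level and pleasantness
#' rating: 1 for perfectly linear ratings, near 0 for ratings unrelated to
#' occlusion. Invariant to affine rescaling of the ratings. Constant ratings
#' yield sensitivity 0 with a flag.
#'
#' @param ratings data frame with columns `occlusion_level` (or `occlusion`)
#'   and `rating`; needs >= 3 distinct occlusion levels.
#' @return List: `sensitivity` in `[0, 1]`, `r` (signed), `constant` flag.
#' @export
reward_sensitivity <- function(ratings) {
  occ <- if ("occlusion_level" %in% names(ratings)) ratings$occlusion_level
         else ratings$occlusion
  if (length(unique(occ)) < 3) {
    stop("need at least 3 distinct occlusion levels", call. = FALSE)
  }
  if (stats::sd(ratings$rating) == 0) {
    return(list(sensitivity = 0, r = NA_real_, constant = TRUE))
  }
  r <- stats::cor(occ, ratings$rating)
  list(sensitivity = abs(r), r = r, constant = FALSE)
}

#' Normative anxiety summaries for female college students
#'
#' Published normative means for the state and trait scales of the State-Trait
#' Anxiety Inventory in female college samples, used as comparison groups for
#' Welch tests on a study sample.
#'
#' @return List of two summary lists (`state`, `trait`), each with `mean`,
#'   `sd`, `n`.
#' @export
normative_anxiety <- function() {
  list(state = list(mean = 38.8, sd = 12.0, n = 481),
       trait = list(mean = 40.4, sd = 10.2, n = 531))
}
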