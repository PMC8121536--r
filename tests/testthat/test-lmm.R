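test_that("the log-odds transform hits its anchors and inverts", {
  expect_equal(logit_transform(0.5, 0.01), 0)
  expect_equal(logit_transform(1 / (1 + exp(1)), 0.01), 1)
  expect_equal(logit_transform(1, 0.01), log(0.01 / 0.99))
  expect_equal(logit_transform(0, 0.01), log(0.99 / 0.01))
  expect_error(logit_transform(0.5, 0.7), "eps")
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(inv_logit_transform(logit_transform(p, 0.01)), p)
  # strictly decreasing in the normalized value
  expect_true(all(diff(logit_transform(p, 0.01)) < 0))
})

test_that("the clamp is derived from the task grid", {
  eps <- default_logit_eps(experiential_task())
  vn <- task_levels_norm(experiential_task())
  expect_equal(eps, min(diff(vn)) / 2)
  expect_gt(eps, 0)
  expect_lt(eps, min(diff(vn)))
})

test_that("the offset mixed model recovers a simulated group log discount rate", {
  set.seed(101)
  dat <- sim_y_direct(n_id = 44, b0_mean = -6.7, b0_sd = 1, b1_mean = 1,
                      b1_sd = 0, sigma = 0.4)
  fit <- fit_lmm(dat, "hyperbolic")
  ic <- fit$fixed_effects[1, ]
  expect_lt(abs(ic$estimate - (-6.7)), 2 * ic$se)
  expect_equal(fit$n_params, 3L)
})

test_that("the random-slope mixed model recovers simulated group fixed effects", {
  set.seed(102)
  dat <- sim_y_direct(n_id = 44, b0_mean = -13.5, b0_sd = 0.5, b1_mean = 4.3,
                      b1_sd = 1, sigma = 0.4)
  fit <- fit_lmm(dat, "logistic")
  fe <- fit$fixed_effects
  expect_lt(abs(fe$estimate[fe$term == "(Intercept)"] - (-13.5)),
            2 * fe$se[fe$term == "(Intercept)"])
  expect_lt(abs(fe$estimate[fe$term == "log_delay"] - 4.3),
            2 * fe$se[fe$term == "log_delay"])
  expect_equal(fit$n_params, 6L)
})

test_that("zero between-participant variance is estimated at the boundary", {
  set.seed(103)
  dat <- sim_y_direct(n_id = 30, b0_mean = -2, b0_sd = 0, b1_mean = 1,
                      b1_sd = 0, sigma = 0.5)
  fit <- fit_lmm(dat, "hyperbolic")
  expect_lt(unname(fit$random_sd[1]), 0.1)
  expect_true(fit$singular)  # flagged, not raised
})

test_that("information criteria satisfy their bookkeeping identities", {
  set.seed(104)
  dat <- sim_y_direct(n_id = 12, sigma = 0.5)
  for (m in c("null", "hyperbolic", "logistic")) {
    fit <- fit_lmm(dat, m)
    expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
    expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(fit$n_obs))
  }
})

test_that("likelihood-ratio comparisons respect nesting and the chi-square tail", {
  set.seed(105)
  dat <- sim_y_direct(n_id = 20, b1_mean = 2, b1_sd = 0.5, sigma = 0.4)
  f_null <- fit_lmm(dat, "null")
  f_hyp <- fit_lmm(dat, "hyperbolic")
  f_log <- fit_lmm(dat, "logistic")

  same <- compare_lmm(f_log, f_log)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # null vs hyperbolic trade a free mean for a fixed offset: df = 0 with a note
  lrt0 <- compare_lmm(f_null, f_hyp)
  expect_equal(lrt0$df, 0L)
  expect_false(is.na(lrt0$note))

  lrt <- compare_lmm(f_hyp, f_log)
  expect_equal(lrt$df, 3L)
  expect_lt(lrt$p, 0.001)

  expect_error(compare_lmm(f_log, f_hyp), "not nested")
  expect_equal(stats::pchisq(10, 3, lower.tail = FALSE), 0.01857, tolerance = 1e-3)
})

test_that("model comparison selects the generating model at the study size", {
  # data truly logistic (free slope 4): the logistic model must win
  set.seed(106)
  wins <- 0L
  for (i in 1:20) {
    dat <- sim_y_direct(n_id = 44, b0_mean = -10, b0_sd = 1, b1_mean = 4,
                        b1_sd = 0.8, sigma = 0.5)
    lrt <- compare_lmm(fit_lmm(dat, "hyperbolic"), fit_lmm(dat, "logistic"))
    if (lrt$p < 0.001) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("marginal and conditional R2 follow the variance decomposition", {
  set.seed(107)
  dat <- sim_y_direct(n_id = 25, b0_mean = -5, b0_sd = 1.5, b1_mean = 1,
                      b1_sd = 0, sigma = 0.6)
  f_null <- fit_lmm(dat, "null")
  r2_null <- nakagawa_r2(f_null)
  expect_equal(unname(r2_null["marginal"]), 0, tolerance = 1e-10)
  expect_gte(r2_null[["conditional"]], r2_null[["marginal"]])

  f_hyp <- fit_lmm(dat, "hyperbolic")
  r2 <- nakagawa_r2(f_hyp)
  # hand-computed from the same components
  vf <- var(predict(f_hyp$fit, re.form = NA))
  vr <- f_hyp$re_vcov[1, 1]
  ve <- f_hyp$residual_sd^2
  expect_equal(unname(r2["marginal"]), vf / (vf + vr + ve), tolerance = 1e-6)
  expect_equal(unname(r2["conditional"]), (vf + vr) / (vf + vr + ve),
               tolerance = 1e-6)
  expect_gt(r2[["conditional"]], r2[["marginal"]])

  # nearly noiseless, homogeneous data: both approach 1
  set.seed(108)
  dat1 <- sim_y_direct(n_id = 10, b0_mean = -5, b0_sd = 0.001, b1_mean = 1,
                       b1_sd = 0, sigma = 0.001)
  r2_one <- nakagawa_r2(fit_lmm(dat1, "hyperbolic"))
  expect_gt(r2_one[["marginal"]], 0.99)
  expect_gt(r2_one[["conditional"]], 0.99)
})

test_that("pleasantness models estimate the occlusion effect", {
  occ <- rep(1:10, each = 6)
  ids <- sprintf("p%02d", 1:20)
  # noise-free common slope -0.55 with varying intercepts
  set.seed(109)
  b0 <- rnorm(20, 2.5, 0.5)
  dat <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(participant_id = ids[i], occlusion = occ,
               pleasantness = b0[i] - 0.55 * occ)
  }))
  fit <- fit_pleasantness(dat, random_slope = TRUE)
  sl <- fit$fixed_effects[fit$fixed_effects$term == "occlusion", ]
  expect_lt(abs(sl$estimate - (-0.55)), 1e-3)

  # constant ratings: slope indistinguishable from zero
  dat0 <- dat; dat0$pleasantness <- 1
  fit0 <- fit_pleasantness(dat0, random_slope = FALSE)
  expect_lt(abs(fit0$fixed_effects$estimate[2]), 1e-8)

  # heterogeneous slopes: the random-slope model wins the LRT
  set.seed(110)
  b1 <- rnorm(20, -0.5, 0.3)
  dath <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(participant_id = ids[i], occlusion = occ,
               pleasantness = b0[i] + b1[i] * occ + rnorm(60, 0, 0.5))
  }))
  lrt <- compare_lmm(fit_pleasantness(dath, random_slope = FALSE),
                     fit_pleasantness(dath, random_slope = TRUE))
  expect_lt(lrt$p, 0.01)
})
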