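test_that("deterministic choices follow the value comparison with ties to waiting", {
  ag <- agent_params("logistic", a = 1, b = log(10), tau = 0)
  # at T = e^b the delayed value is exactly 0.5
  expect_equal(sv_logistic(10, 1, log(10)), 0.5)
  expect_equal(simulate_choice(ag, 0.6, 1, 10), "immediate")
  expect_equal(simulate_choice(ag, 0.4, 1, 10), "delayed")
  expect_equal(simulate_choice(ag, 0.5, 1, 10), "delayed")  # tie -> wait
  hy <- agent_params("hyperbolic", k = 0.1, tau = 0)
  expect_equal(simulate_choice(hy, 0.51, 1, 10), "immediate")
  expect_error(simulate_choice(ag, 0.5, 1, -1), "> 0")
  expect_error(agent_params("hyperbolic", k = -1), "k > 0")
  expect_error(agent_params("logistic", a = 1), "requires")
})

test_that("choice noise is symmetric at equal values", {
  ag <- agent_params("logistic", a = 1, b = log(10), tau = 0.5)
  set.seed(123)
  draws <- replicate(4000, simulate_choice(ag, 0.5, 1, 10))
  p_hat <- mean(draws == "immediate")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("the population generator reproduces the requested anxiety structure", {
  pop <- population_params(n = 2000L, seed = 10L)
  tab <- generate_population(pop)
  expect_equal(cor(tab$state_anxiety, tab$trait_anxiety), 0.59, tolerance = 0.04)
  expect_equal(mean(tab$state_anxiety), 34.3, tolerance = 3 * 10.1 / sqrt(2000))
  expect_equal(mean(tab$trait_anxiety), 43.0, tolerance = 3 * 10.8 / sqrt(2000))
  expect_equal(sd(tab$state_anxiety), 10.1, tolerance = 0.5)

  tab2 <- generate_population(pop)
  expect_identical(tab, tab2)
})

test_that("a null path structure leaves discounting independent of anxiety", {
  null_pc <- list(state_rs = 0, trait_rs = 0, rs_b_exp = 0, state_b_exp = 0,
                  trait_b_exp = 0, statextrait_b_exp = 0, state_b_hyp = 0,
                  trait_b_hyp = 0)
  tab <- generate_population(population_params(n = 2000L,
                                               path_coefficients = null_pc,
                                               seed = 4L))
  expect_lt(abs(cor(tab$b_exp, tab$state_anxiety)), 0.05)
  expect_lt(abs(cor(tab$b_exp, tab$trait_anxiety)), 0.05)
  expect_lt(abs(cor(tab$b_hyp, tab$state_anxiety)), 0.05)
  expect_lt(abs(cor(tab$sensitivity_target, tab$state_anxiety)), 0.05)
})

test_that("population parameters are validated", {
  expect_error(population_params(n = 1), ">= 2")
  expect_error(population_params(r_state_trait = 1.2), "r_state_trait")
  expect_error(population_params(state_sd = -1), "SDs")
  expect_error(population_params(path_coefficients = list(state_rs = 0)),
               "missing")
})

test_that("rating generation respects the design and the Likert bounds", {
  p <- generate_population(population_params(n = 2L, seed = 2L))[1, ]
  set.seed(5)
  r <- generate_ratings(p)
  expect_equal(nrow(r), 60L)  # 6 trials x 10 occlusion levels
  expect_true(all(r$rating >= -4 & r$rating <= 4))
  expect_true(all(r$rating == round(r$rating)))

  # bounds hold even under extreme noise
  p_noisy <- p; p_noisy$rating_noise_sd <- 50
  rn <- generate_ratings(p_noisy)
  expect_true(all(rn$rating >= -4 & rn$rating <= 4))

  # noise-free negative slope: perfect negative correlation before rounding
  p0 <- p; p0$rating_noise_sd <- 0
  r0 <- generate_ratings(p0, round = FALSE)
  expect_equal(cor(r0$occlusion_level, r0$rating), -1)
})

test_that("the generator is calibrated to the target reward-sensitivity level", {
  tab <- generate_population(population_params(n = 300L, seed = 6L))
  set.seed(6)
  sens <- vapply(seq_len(nrow(tab)), function(i) {
    reward_sensitivity(generate_ratings(tab[i, ]))$sensitivity
  }, numeric(1))
  expect_equal(mean(sens), 0.73, tolerance = 0.05)
})

test_that("the pooled rating slope matches the generating fixed effect", {
  tab <- generate_population(population_params(n = 44L, seed = 9L))
  set.seed(9)
  raw <- do.call(rbind, lapply(seq_len(nrow(tab)),
                               function(i) generate_ratings(tab[i, ], round = FALSE)))
  dat <- data.frame(participant_id = raw$participant_id,
                    occlusion = raw$occlusion_level,
                    pleasantness = raw$rating)
  fit <- fit_pleasantness(dat, random_slope = TRUE)
  sl <- fit$fixed_effects[fit$fixed_effects$term == "occlusion", ]
  expect_lt(abs(sl$estimate - (-0.55)), 2 * sl$se)

  # rounding and clipping to the Likert grid attenuate the slope only mildly
  set.seed(9)
  lik <- do.call(rbind, lapply(seq_len(nrow(tab)),
                               function(i) generate_ratings(tab[i, ])))
  datl <- data.frame(participant_id = lik$participant_id,
                     occlusion = lik$occlusion_level,
                     pleasantness = lik$rating)
  sll <- fit_pleasantness(datl, random_slope = TRUE)$fixed_effects
  est <- sll$estimate[sll$term == "occlusion"]
  expect_lt(est, -0.55 * 0.85)
  expect_gt(est, -0.55 * 1.15)
})

test_that("parameter recovery closes the loop for grid-representable groups", {
  # logistic group with a moderate switch inside the delay range
  rec <- recovery_experiment("logistic", n = 44, slope_mean = 1.5, slope_sd = 0.3,
                             intercept_mean = -3.3, intercept_sd = 0.4, seed = 21)
  fe <- rec$fit$fixed_effects
  sl <- fe[fe$term == "log_delay", ]
  expect_lt(abs(sl$estimate - 1.5), 2 * max(sl$se, 0.15))

  # hyperbolic group with log k = -3 (switch near 20 s); the staircase reports
  # the lowest accepted level, so estimates carry a quantization offset of up
  # to about half a grid step on the log-odds scale (~0.3 here)
  rec_h <- recovery_experiment("hyperbolic", n = 44, intercept_mean = -3,
                               intercept_sd = 0.5, seed = 22)
  ic <- rec_h$fit$fixed_effects[1, ]
  expect_lt(abs(ic$estimate - (-3)), 0.5)
})

test_that("a full synthetic study is complete, consistent and deterministic", {
  pop <- population_params(n = 6L, seed = 31L)
  study <- generate_study(pop)
  expect_equal(nrow(study$points), 6 * 22 * 2)  # both tasks
  expect_equal(sum(study$points$task_kind == "experiential"), 6 * 22)
  expect_equal(nrow(study$ratings), 6 * 60)
  expect_setequal(unique(study$points$participant_id),
                  study$participants$participant_id)
  expect_setequal(unique(study$trials$participant_id),
                  study$participants$participant_id)
  study2 <- generate_study(pop)
  expect_identical(study, study2)
})

test_that("large dispersion in the inflection parameter produces boundary agents", {
  pop <- population_params(n = 30L, exp_b_sd = 2.5, seed = 12L)
  study <- generate_study(pop, configs = list(experiential_task()))
  expect_true(any(study$points$at_boundary == "always_delayed"))
})
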