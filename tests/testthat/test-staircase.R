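test_that("session initialization spans the full level range and is reproducible", {
  s_exp <- init_session(experiential_task(), seed = 11)
  iv <- uncertainty_intervals(s_exp)
  expect_equal(nrow(iv), 22L)
  expect_true(all(iv$lo == 1L & iv$hi == 10L))
  expect_false(any(iv$converged))

  s_hyp <- init_session(hypothetical_task(), seed = 11)
  iv_h <- uncertainty_intervals(s_hyp)
  expect_equal(nrow(iv_h), 22L)
  expect_true(all(iv_h$lo == 1L & iv_h$hi == 14L))

  t1 <- select_next_trial(init_session(experiential_task(), seed = 5))
  t2 <- select_next_trial(init_session(experiential_task(), seed = 5))
  expect_identical(t1$level_index, t2$level_index)
  expect_identical(t1$delay_index, t2$delay_index)
  expect_true(t1$level_index %in% 4:6)
})

test_that("invalid task configurations name the violated invariant", {
  expect_error(task_config("experiential", c(0.5, 0.3), 1, 1:3, "s", start_pool = 1),
               "strictly increasing")
  expect_error(task_config("experiential", c(0.5, 0.9), 1, 1:3, "s", start_pool = 1),
               "delayed_value")
  expect_error(task_config("experiential", c(0.5, 1), 1, c(3, 2), "s", start_pool = 1),
               "delays")
  expect_error(task_config("experiential", c(0.5, 1), 1, 1:3, "s", start_pool = 5),
               "start_pool")
  expect_error(task_config("experiential", c(0.5, 1), 1, 1:3, "s", n_runs = 0,
                           start_pool = 1), "n_runs")
})

test_that("choices halve the uncertainty bracket in the consistent direction", {
  # one-delay, one-run config with a pinned start level of 5
  cfg <- task_config("experiential", experiential_task()$immediate_values, 1,
                     delays = 10, delay_units = "s", n_runs = 1, start_pool = 5L)
  st <- init_session(cfg, seed = 1)
  tr <- select_next_trial(st)
  expect_equal(tr$level_index, 5L)

  # waiting at 5 means the immediate option was not good enough: bracket rises
  st_wait <- record_choice(tr$state, tr, "delayed")
  expect_equal(uncertainty_intervals(st_wait)[, c("lo", "hi")],
               data.frame(lo = 5L, hi = 10L))
  expect_equal(select_next_trial(st_wait)$level_index, 7L)

  # taking the immediate option at 5 caps the bracket from above
  st_take <- record_choice(tr$state, tr, "immediate")
  expect_equal(uncertainty_intervals(st_take)[, c("lo", "hi")],
               data.frame(lo = 1L, hi = 5L))
  expect_equal(select_next_trial(st_take)$level_index, 3L)
})

test_that("recording against a converged interval is a state error", {
  cfg <- task_config("experiential", experiential_task()$immediate_values, 1,
                     delays = 10, delay_units = "s", n_runs = 1, start_pool = 5L)
  st <- init_session(cfg, seed = 1)
  last_trial <- NULL
  repeat {
    tr <- tryCatch(select_next_trial(st), dd_session_complete = function(e) NULL)
    if (is.null(tr)) break
    st <- record_choice(tr$state, tr, "immediate")
    last_trial <- tr
  }
  expect_true(all(st$cells$converged))
  expect_error(record_choice(st, last_trial, "immediate"), "converged")
  expect_error(select_next_trial(st), class = "dd_session_complete")
})

test_that("every threshold agent is recovered exactly from every start level", {
  cen <- staircase_trial_census(experiential_task())
  vis <- experiential_task()$immediate_values
  expect_equal(cen$value, vis[pmin(cen$threshold_level, 10L)])
  expect_true(all(cen$n_trials %in% 3:4))
  expect_true(all(cen$at_boundary[cen$threshold_level == 11L] == "always_delayed"))
  expect_true(all(cen$at_boundary[cen$threshold_level == 1L] == "always_immediate"))
  expect_true(all(cen$at_boundary[cen$threshold_level %in% 2:9] == "none"))

  cen_h <- staircase_trial_census(hypothetical_task())
  vals <- hypothetical_task()$immediate_values
  expect_equal(cen_h$value, vals[pmin(cen_h$threshold_level, 14L)])
})

test_that("brackets narrow monotonically even under inconsistent choices", {
  set.seed(42)
  cfg <- experiential_task()
  st <- init_session(cfg, seed = 99)
  widths <- function(s) {
    iv <- uncertainty_intervals(s)
    iv$hi - iv$lo
  }
  w <- widths(st)
  n <- 0
  repeat {
    tr <- tryCatch(select_next_trial(st), dd_session_complete = function(e) NULL)
    if (is.null(tr)) break
    st <- record_choice(tr$state, tr, sample(c("immediate", "delayed"), 1))
    w2 <- widths(st)
    expect_true(all(w2 <= w))
    w <- w2
    n <- n + 1
    expect_lt(n, 22 * 10 + 1)  # bounded by levels x cells
  }
  expect_true(all(st$cells$converged))
})

test_that("processing screen duration follows the five-plus-forgone-delays rule", {
  win <- data.frame(delay = c(2, 4, 6, 8, 10),
                    choice = rep("delayed", 5))
  expect_equal(processing_screen_duration(win), 5)
  win$choice <- "immediate"
  expect_equal(processing_screen_duration(win), 35)
  win$choice <- ifelse(win$delay %in% c(4, 6), "immediate", "delayed")
  expect_equal(processing_screen_duration(win), 15)
  expect_error(processing_screen_duration(win[1:4, ]), "exactly 5")

  # additivity over disjoint windows (minus the shared 5 s base)
  set.seed(1)
  w1 <- data.frame(delay = sample(1:25, 5),
                   choice = sample(c("immediate", "delayed"), 5, TRUE))
  w2 <- data.frame(delay = sample(1:25, 5),
                   choice = sample(c("immediate", "delayed"), 5, TRUE))
  both <- processing_screen_duration(w1) + processing_screen_duration(w2) - 5
  combined <- 5 + sum(c(w1$delay[w1$choice == "immediate"],
                        w2$delay[w2$choice == "immediate"]))
  expect_equal(both, combined)
})

test_that("a full session yields two points per delay and a reproducible log", {
  agent <- agent_params("threshold", threshold_level = 5L)
  res <- run_session(experiential_task(), agent, seed = 3L)
  expect_equal(nrow(res$points), 22L)
  expect_equal(as.integer(table(res$points$delay)), rep(2L, 11))
  expect_true(all(res$points$value == 0.70))  # level 5 reveals 70%
  expect_gte(nrow(res$trials), 66)
  expect_lte(nrow(res$trials), 88)

  res2 <- run_session(experiential_task(), agent, seed = 3L)
  expect_identical(res$trials, res2$trials)
  expect_identical(res$points, res2$points)
})

test_that("an agent that always waits is retained at the boundary, not dropped", {
  agent <- agent_params("threshold", threshold_level = 11L)
  res <- run_session(experiential_task(), agent, seed = 8L)
  expect_true(all(res$points$at_boundary == "always_delayed"))
  expect_true(all(res$points$value == 1.0))
  expect_true(all(res$points$sv_norm == 1.0))
})
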