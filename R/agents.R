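#' Simulated decision agent
#'
#' An agent carries a discounting model and a choice-noise temperature. The
#' `"logistic"` and `"hyperbolic"` agents value the delayed reward on the
#' normalized subjective-value scale; the `"threshold"` agent is a
#' deterministic level rule (accept the immediate option at or above a fixed
#' level index) used for exact-recovery analyses of the staircase.
#'
#' @param model `"logistic"`, `"hyperbolic"` or `"threshold"`.
#' @param k discount rate (hyperbolic, > 0).
#' @param a slope at inflection (logistic, > 0).
#' @param b log-delay at inflection (logistic).
#' @param threshold_level level index (threshold agent); `L + 1` encodes an
#'   agent that always waits.
#' @param tau choice-noise temperature on the normalized value scale
#'   (0 = deterministic argmax with ties broken toward waiting).
#' @return An object of class `dd_agent`.
#' @export
agent_params <- function(model = c("logistic", "hyperbolic", "threshold"),
                         k = NULL, a = NULL, b = NULL,
                         threshold_level = NULL, tau = 0.02) {
  model <- match.arg(model)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  if (model == "hyperbolic" && (is.null(k) || k <= 0)) {
    stop("hyperbolic agent requires k > 0", call. = FALSE)
  }
  if (model == "logistic" && (is.null(a) || a <= 0 || is.null(b))) {
    stop("logistic agent requires a > 0 and b", call. = FALSE)
  }
  if (model == "threshold" && is.null(threshold_level)) {
    stop("threshold agent requires `threshold_level`", call. = FALSE)
  }
  structure(list(model = model, k = k, a = a, b = b,
                 threshold_level = threshold_level, tau = tau),
            class = "dd_agent")
}

#' Simulate one choice between an immediate and a delayed option
#'
#' Computes the delayed option's subjective value under the agent's model (on
#' the normalized scale) and compares it with the normalized immediate value.
#' With `tau = 0` the larger value wins and ties go to the delayed option; with
#' `tau > 0` the immediate option is chosen with probability
#' `plogis((v_immediate - sv_delayed) / tau)`.
#'
#' @param agent an [agent_params()] object.
#' @param immediate_value immediate-option magnitude (raw units).
#' @param delayed_value delayed-reward magnitude (raw units).
#' @param delay delay of the delayed option (> 0).
#' @param sv_min task lower anchor for normalization (see [task_sv_min()]).
#' @param level presented level index (used by threshold agents).
#' @return `"immediate"` or `"delayed"`.
#' @export
simulate_choice <- function(agent, immediate_value, delayed_value, delay,
                            sv_min = 0, level = NULL) {
  if (!inherits(agent, "dd_agent")) stop("`agent` must be a dd_agent", call. = FALSE)
  if (delay <= 0) stop("`delay` must be > 0", call. = FALSE)
  if (agent$model == "threshold") {
    if (is.null(level)) stop("threshold agent requires `level`", call. = FALSE)
    return(if (level >= agent$threshold_level) "immediate" else "delayed")
  }
  v_imm <- normalize_sv(immediate_value / delayed_value, sv_min)
  sv_del <- switch(agent$model,
                   logistic = sv_logistic(delay, agent$a, agent$b),
                   hyperbolic = sv_hyperbolic(delay, agent$k))
  if (agent$tau == 0) {
    return(if (v_imm > sv_del) "immediate" else "delayed")
  }
  p_imm <- stats::plogis((v_imm - sv_del) / agent$tau)
  if (stats::runif(1) < p_imm) "immediate" else "delayed"
}

#' Population parameters for the synthetic study
#'
#' Defaults are anchored to the study conditions: 44 participants, state
#' anxiety (mean 34.3, SD 10.1), trait anxiety (mean 43.0, SD 10.8) correlated
#' at 0.59, group logistic discounting parameters matching the experiential
#' (slope 4.3, inflection 13.5/4.3) and hypothetical (1.8, 12.4/1.8) mixed-model
#' fixed effects, mean perceptual reward sensitivity 0.73 (SD 0.16) and a group
#' pleasantness-rating slope of -0.55 per occlusion level. Anxiety affects
#' discounting through the inflection parameter `b` (willingness to wait), with
#' reward sensitivity as a mediator; path coefficients are in standardized
#' units.
#'
#' @param n number of participants (>= 2).
#' @param state_mean,state_sd,trait_mean,trait_sd anxiety-scale moments.
#' @param r_state_trait state-trait correlation in `[-1, 1]`.
#' @param exp_slope_mean,exp_slope_sd,exp_b_mean,exp_b_sd experiential logistic
#'   parameter distribution (slope `a`, inflection `b` in log seconds).
#' @param hyp_slope_mean,hyp_slope_sd,hyp_b_mean,hyp_b_sd hypothetical-task
#'   counterpart (`b` in log days).
#' @param sensitivity_mean,sensitivity_sd reward-sensitivity distribution.
#' @param path_coefficients named list of standardized structural coefficients
#'   (`state_rs`, `trait_rs`, `rs_b_exp`, `state_b_exp`, `trait_b_exp`,
#'   `statextrait_b_exp`, `state_b_hyp`, `trait_b_hyp`). Set all to 0 for a
#'   null structure.
#' @param rating_intercept,rating_intercept_sd,rating_slope_mean,rating_slope_sd
#'   pleasantness-rating generation (Likert units; slope per occlusion level).
#' @param rating_noise_sd trial noise SD; if `NULL` (default) it is derived per
#'   participant so that the expected absolute occlusion-rating correlation
#'   equals that participant's target reward sensitivity.
#' @param tau agent choice-noise temperature.
#' @param seed default seed used by [generate_population()] / [generate_study()].
#' @return An object of class `dd_population`.
#' @export
population_params <- function(n = 44L,
                              state_mean = 34.3, state_sd = 10.1,
                              trait_mean = 43.0, trait_sd = 10.8,
                              r_state_trait = 0.59,
                              exp_slope_mean = 4.3, exp_slope_sd = 1.0,
                              exp_b_mean = 13.5 / 4.3, exp_b_sd = 0.5,
                              hyp_slope_mean = 1.8, hyp_slope_sd = 0.5,
                              hyp_b_mean = 12.4 / 1.8, hyp_b_sd = 0.7,
                              sensitivity_mean = 0.73, sensitivity_sd = 0.16,
                              path_coefficients = list(
                                state_rs = -0.44, trait_rs = 0.22,
                                rs_b_exp = 0.53, state_b_exp = -0.10,
                                trait_b_exp = 0.36, statextrait_b_exp = 0.20,
                                state_b_hyp = 0.05, trait_b_hyp = -0.27),
                              rating_intercept = 3.0, rating_intercept_sd = 0.5,
                              rating_slope_mean = -0.55, rating_slope_sd = 0.15,
                              rating_noise_sd = NULL,
                              tau = 0.02,
                              seed = 1L) {
  args <- mget(names(formals(population_params)))
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  sds <- c(state_sd, trait_sd, exp_slope_sd, exp_b_sd, hyp_slope_sd, hyp_b_sd,
           sensitivity_sd, rating_intercept_sd, rating_slope_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (abs(r_state_trait) > 1) stop("|r_state_trait| must be <= 1", call. = FALSE)
  required <- c("state_rs", "trait_rs", "rs_b_exp", "state_b_exp", "trait_b_exp",
                "statextrait_b_exp", "state_b_hyp", "trait_b_hyp")
  miss <- setdiff(required, names(path_coefficients))
  if (length(miss)) {
    stop("path_coefficients missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(args, class = "dd_population")
}

# expected absolute correlation inverted for the rating-noise SD:
# |r| = |slope| sd(occ) / sqrt(slope^2 var(occ) + sigma^2)
.rating_noise_for_sensitivity <- function(slope, sens, occ_levels = 1:10) {
  sd_occ <- sqrt(mean((occ_levels - mean(occ_levels))^2))
  abs(slope) * sd_occ * sqrt(pmax(1 / sens^2 - 1, 1e-6))
}

#' Draw a synthetic participant population
#'
#' State and trait anxiety come from a bivariate normal; reward sensitivity and
#' the per-task discounting parameters follow linear structural equations in
#' the standardized anxiety scores (plus their product) with Gaussian
#' disturbances scaled so each structural composite has roughly unit variance.
#'
#' @param pop a [population_params()] object.
#' @param seed integer seed (defaults to `pop$seed`).
#' @return Data frame with one row per participant: anxiety scores, target
#'   reward sensitivity, per-task logistic parameters `(a, b)`, rating
#'   parameters and the choice temperature.
#' @export
generate_population <- function(pop, seed = pop$seed) {
  if (!inherits(pop, "dd_population")) stop("`pop` must be a dd_population", call. = FALSE)
  set.seed(seed)
  r <- pop$r_state_trait
  Sigma <- matrix(c(1, r, r, 1), 2)
  if (min(eigen(Sigma, only.values = TRUE)$values) <= 0) {
    stop("implied anxiety covariance is not positive definite", call. = FALSE)
  }
  z <- MASS::mvrnorm(pop$n, mu = c(0, 0), Sigma = Sigma)
  z_s <- z[, 1]; z_t <- z[, 2]
  z_int <- z_s * z_t - r   # centred interaction score
  pc <- pop$path_coefficients

  disturb <- function(explained) stats::rnorm(pop$n, 0, sqrt(max(1 - explained, 0.05)))
  expl_rs <- pc$state_rs^2 + pc$trait_rs^2 + 2 * pc$state_rs * pc$trait_rs * r
  z_rs <- pc$state_rs * z_s + pc$trait_rs * z_t + disturb(expl_rs)
  sens <- pmin(pmax(pop$sensitivity_mean + pop$sensitivity_sd * z_rs, 0.05), 0.98)

  expl_be <- pc$rs_b_exp^2 + pc$state_b_exp^2 + pc$trait_b_exp^2 +
    pc$statextrait_b_exp^2
  z_be <- pc$rs_b_exp * z_rs + pc$state_b_exp * z_s + pc$trait_b_exp * z_t +
    pc$statextrait_b_exp * z_int + disturb(expl_be)
  expl_bh <- pc$state_b_hyp^2 + pc$trait_b_hyp^2 +
    2 * pc$state_b_hyp * pc$trait_b_hyp * r
  z_bh <- pc$state_b_hyp * z_s + pc$trait_b_hyp * z_t + disturb(expl_bh)

  slope_exp <- pmax(stats::rnorm(pop$n, pop$exp_slope_mean, pop$exp_slope_sd), 0.2)
  slope_hyp <- pmax(stats::rnorm(pop$n, pop$hyp_slope_mean, pop$hyp_slope_sd), 0.2)
  rating_slope <- pmin(stats::rnorm(pop$n, pop$rating_slope_mean, pop$rating_slope_sd),
                       -0.05)
  noise <- if (is.null(pop$rating_noise_sd)) {
    .rating_noise_for_sensitivity(rating_slope, sens)
  } else {
    rep(pop$rating_noise_sd, pop$n)
  }
  data.frame(
    participant_id = sprintf("p%03d", seq_len(pop$n)),
    state_anxiety = pop$state_mean + pop$state_sd * z_s,
    trait_anxiety = pop$trait_mean + pop$trait_sd * z_t,
    sensitivity_target = sens,
    a_exp = slope_exp,
    b_exp = pop$exp_b_mean + pop$exp_b_sd * z_be,
    a_hyp = slope_hyp,
    b_hyp = pop$hyp_b_mean + pop$hyp_b_sd * z_bh,
    rating_intercept = stats::rnorm(pop$n, pop$rating_intercept, pop$rating_intercept_sd),
    rating_slope = rating_slope,
    rating_noise_sd = noise,
    tau = pop$tau,
    stringsAsFactors = FALSE)
}

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Generate pleasantness ratings for one participant
#'
#' Ratings are linear in occlusion level with Gaussian trial noise, then
#' rounded half away from zero and clipped to the Likert grid `[-4, 4]`.
#' Occlusion levels are indexed 1 (no occlusion, photograph fully visible) to
#' 10 (heaviest occlusion, 13% visible).
#'
#' @param participant one row of [generate_population()] output.
#' @param occlusion_levels occlusion grid (default 1:10).
#' @param reps trials per level (default 6: 60 rating trials in total).
#' @param round round/clip to the Likert grid (set `FALSE` to inspect the raw
#'   linear response).
#' @return Data frame of `reps * length(occlusion_levels)` rating records.
#' @export
generate_ratings <- function(participant, occlusion_levels = 1:10, reps = 6L,
                             round = TRUE) {
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  occ <- rep(occlusion_levels, each = reps)
  raw <- participant$rating_intercept + participant$rating_slope * occ +
    stats::rnorm(length(occ), 0, participant$rating_noise_sd)
  rating <- if (round) pmin(pmax(.round_half_away(raw), -4), 4) else raw
  vis <- rev(experiential_task()$immediate_values)
  data.frame(participant_id = participant$participant_id,
             occlusion_level = occ,
             occlusion_fraction = (1 - vis)[occ],
             rating = rating,
             stringsAsFactors = FALSE)
}

.derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) + 7919 * i + 104729 * j) %% 2147483629)
}

#' Generate a complete synthetic study
#'
#' Draws a participant population, runs the staircase for every participant in
#' both tasks (logistic agents with per-participant `(a, b)`), and generates
#' the 60-trial pleasantness-rating session.
#'
#' @param pop a [population_params()] object.
#' @param configs list of task configs (default: experiential + hypothetical).
#' @param seed integer seed (defaults to `pop$seed`).
#' @return An object of class `dd_study`: a list of tables `participants`,
#'   `trials`, `points`, `ratings`.
#' @export
generate_study <- function(pop,
                           configs = list(experiential_task(), hypothetical_task()),
                           seed = pop$seed) {
  participants <- generate_population(pop, seed = .derive_seed(seed, 0L))
  trials <- list(); points <- list(); ratings <- list()
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    for (j in seq_along(configs)) {
      cfg <- configs[[j]]
      ab <- if (cfg$task_kind == "experiential") c(p$a_exp, p$b_exp) else c(p$a_hyp, p$b_hyp)
      agent <- agent_params("logistic", a = ab[1], b = ab[2], tau = p$tau)
      res <- run_session(cfg, agent, seed = .derive_seed(seed, i, j))
      res$trials$participant_id <- p$participant_id
      res$trials$task_kind <- cfg$task_kind
      res$trials$delay_units <- cfg$delay_units
      res$trials$seed <- .derive_seed(seed, i, j)
      res$points$participant_id <- p$participant_id
      res$points$task_kind <- cfg$task_kind
      trials[[length(trials) + 1L]] <- res$trials
      points[[length(points) + 1L]] <- res$points
    }
    set.seed(.derive_seed(seed, i, 99L))
    ratings[[i]] <- generate_ratings(p)
  }
  structure(list(participants = participants,
                 trials = do.call(rbind, trials),
                 points = do.call(rbind, points),
                 ratings = do.call(rbind, ratings),
                 seed = as.integer(seed)),
            class = "dd_study")
}

#' @export
print.dd_study <- function(x, ...) {
  cat(sprintf("<dd_study> %d participants, %d trials, %d indifference points, %d ratings\n",
              nrow(x$participants), nrow(x$trials), nrow(x$points), nrow(x$ratings)))
  invisible(x)
}
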