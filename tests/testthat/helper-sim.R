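# Simulation helpers shared across test files.

# Direct (ungridded) simulation of the linearized discounting response:
# y_ij = b0_i + b1_i * log T_j + noise, bypassing the staircase entirely.
sim_y_direct <- function(n_id = 44, b0_mean = -6.7, b0_sd = 1, b1_mean = 1,
                         b1_sd = 0, sigma = 0.3,
                         delays = experiential_task()$delays, runs = 2) {
  b0 <- rnorm(n_id, b0_mean, b0_sd)
  b1 <- if (b1_sd > 0) rnorm(n_id, b1_mean, b1_sd) else rep(b1_mean, n_id)
  lt <- rep(log(delays), times = runs)
  do.call(rbind, lapply(seq_len(n_id), function(i) {
    data.frame(participant_id = sprintf("p%03d", i),
               log_delay = lt,
               y = b0[i] + b1[i] * lt + rnorm(length(lt), 0, sigma))
  }))
}

# Noise-free indifference points from a known curve at the experiential delays.
sim_curve_points <- function(model, params, delays = experiential_task()$delays) {
  sv <- switch(model,
               logistic2 = sv_logistic(delays, params[["a"]], params[["b"]]),
               hyperbolic = sv_hyperbolic(delays, params[["k"]]))
  data.frame(delay = delays, sv_norm = sv)
}

# Simple recursive path data generator on standardized scales. Disturbance
# variances account for the full predictor covariance so every variable has
# unit model-implied variance and the generating coefficients ARE the
# standardized coefficients.
sim_path_data <- function(n, b_state_rs = 0, b_trait_rs = 0, b_rs_auc = 0,
                          b_state_auc = 0, b_trait_auc = 0,
                          b_state_hyp = 0, b_trait_hyp = 0, r_st = 0.59) {
  z <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, r_st, r_st, 1), 2))
  state <- z[, 1]; trait <- z[, 2]

  c_rs <- c(b_state_rs, b_trait_rs)
  S2 <- matrix(c(1, r_st, r_st, 1), 2)
  expl_rs <- drop(t(c_rs) %*% S2 %*% c_rs)
  rs <- b_state_rs * state + b_trait_rs * trait +
    rnorm(n, 0, sqrt(max(1 - expl_rs, 0.05)))

  cov_rs_s <- b_state_rs + b_trait_rs * r_st
  cov_rs_t <- b_trait_rs + b_state_rs * r_st
  S3 <- rbind(c(1, cov_rs_s, cov_rs_t),
              c(cov_rs_s, 1, r_st),
              c(cov_rs_t, r_st, 1))
  c_exp <- c(b_rs_auc, b_state_auc, b_trait_auc)
  expl_exp <- drop(t(c_exp) %*% S3 %*% c_exp)
  auc_exp <- b_rs_auc * rs + b_state_auc * state + b_trait_auc * trait +
    rnorm(n, 0, sqrt(max(1 - expl_exp, 0.05)))

  c_hyp <- c(b_state_hyp, b_trait_hyp)
  expl_hyp <- drop(t(c_hyp) %*% S2 %*% c_hyp)
  auc_hyp <- b_state_hyp * state + b_trait_hyp * trait +
    rnorm(n, 0, sqrt(max(1 - expl_hyp, 0.05)))

  data.frame(state = state, trait = trait, rs = rs,
             auc_exp = auc_exp, auc_hyp = auc_hyp)
}
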