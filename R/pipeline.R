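# End-to-end orchestration: simulate (or accept) a study, elicit indifference
# points, fit curves and mixed models, compute model-based AUC, run the scalar
# statistics and the anxiety path analyses, and bundle everything into a
# reproducible report.

.pipeline_keys <- c("pop", "seed", "tasks", "study", "out_dir",
                    "bf_prior_scale", "min_n_paths", "fit_logistic3")

.validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config
}

.fit_participant_curves <- function(points, tasks) {
  out <- list()
  for (task in tasks) {
    pts <- points[points$task_kind == task$task_kind, ]
    for (id in unique(pts$participant_id)) {
      pp <- pts[pts$participant_id == id, ]
      for (model in c("hyperbolic", "logistic2")) {
        f <- fit_curve(pp[, c("delay", "sv_norm")], model = model)
        pr <- f$params
        out[[length(out) + 1L]] <- data.frame(
          participant_id = id, task_kind = task$task_kind, model = model,
          k = if ("k" %in% names(pr)) pr[["k"]] else NA_real_,
          a = if ("a" %in% names(pr)) pr[["a"]] else NA_real_,
          b = if ("b" %in% names(pr)) pr[["b"]] else NA_real_,
          rmse = f$rmse, r2 = f$r2, converged = f$converged,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

.auc_table <- function(fits, tasks) {
  out <- list()
  for (task in tasks) {
    fl <- fits[fits$task_kind == task$task_kind & fits$model == "logistic2", ]
    rng <- range(task$delays)
    out[[length(out) + 1L]] <- data.frame(
      participant_id = fl$participant_id, task_kind = task$task_kind,
      auc = vapply(seq_len(nrow(fl)),
                   function(i) model_auc(c(a = fl$a[i], b = fl$b[i]), rng[1], rng[2]),
                   numeric(1)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.lmm_report <- function(points, task) {
  dat <- make_lmm_data(points[points$task_kind == task$task_kind, ], task)
  fits <- list(null = fit_lmm(dat, "null"),
               hyperbolic = fit_lmm(dat, "hyperbolic"),
               logistic = fit_lmm(dat, "logistic"))
  tab <- do.call(rbind, lapply(fits, function(f) {
    r2 <- nakagawa_r2(f)
    data.frame(model = f$model, loglik = f$loglik, n_params = f$n_params,
               aic = f$aic, bic = f$bic,
               marginal_r2 = r2[["marginal"]], conditional_r2 = r2[["conditional"]],
               singular = f$singular, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(fits = fits, table = tab,
       lrt = list(null_vs_hyperbolic = compare_lmm(fits$null, fits$hyperbolic),
                  hyperbolic_vs_logistic = compare_lmm(fits$hyperbolic, fits$logistic)))
}

#' Run the full analysis pipeline
#'
#' In synthetic mode (the default) a study is generated from a population
#' specification; alternatively an existing study bundle (simulated or read
#' from CSVs) is analyzed. Stages: elicit indifference points, per-participant
#' least-squares curve fits, model-based AUC, the three discounting mixed
#' models with comparisons, the pleasantness mixed model and reward
#' sensitivity, AUC correlation statistics (Pearson + Bayes factor) and
#' normative Welch comparisons, and the path analyses with and without
#' mediation plus the moderation regression and split-half illustration.
#'
#' @param config named list. Recognized keys: `pop` ([population_params()]),
#'   `seed`, `tasks` (list of task configs), `study` (an existing [generate_study()]
#'   bundle; skips simulation), `out_dir` (write CSV/JSON report files there),
#'   `bf_prior_scale`, `min_n_paths` (path analyses are skipped below this n;
#'   default 16, since the mediation model frees 14 parameters),
#'   `fit_logistic3` (unused placeholder for the experimental
#'   three-parameter fit). Unknown keys raise a validation error.
#' @return An object of class `dd_report`.
#' @export
run_pipeline <- function(config = list()) {
  config <- .validate_pipeline_config(config)
  pop <- config$pop %||% population_params()
  seed <- config$seed %||% pop$seed
  tasks <- config$tasks %||% list(experiential_task(), hypothetical_task())
  names(tasks) <- vapply(tasks, function(t) t$task_kind, character(1))
  # the mediation model frees 14 parameters, so path analyses need n above that
  min_n <- config$min_n_paths %||% 16L
  bf_scale <- config$bf_prior_scale %||% (1 / 3)

  study <- config$study %||% generate_study(pop, configs = tasks, seed = seed)
  notes <- character()

  fits <- .fit_participant_curves(study$points, tasks)
  auc <- .auc_table(fits, tasks)

  lmm <- lapply(tasks, function(task) .lmm_report(study$points, task))

  # pleasantness + reward sensitivity
  rat <- data.frame(participant_id = study$ratings$participant_id,
                    occlusion = study$ratings$occlusion_level,
                    pleasantness = study$ratings$rating,
                    stringsAsFactors = FALSE)
  pleas <- list(full = fit_pleasantness(rat, random_slope = TRUE),
                null = fit_pleasantness(rat, null_model = TRUE))
  pleas$lrt <- compare_lmm(pleas$null, pleas$full)
  sens <- do.call(rbind, lapply(split(study$ratings, study$ratings$participant_id),
                                function(d) {
    s <- reward_sensitivity(d)
    data.frame(participant_id = d$participant_id[1], sensitivity = s$sensitivity,
               r = s$r, stringsAsFactors = FALSE)
  }))
  rownames(sens) <- NULL

  # participant-level merge for stats and paths
  wide <- merge(auc[auc$task_kind == "experiential", c("participant_id", "auc")],
                auc[auc$task_kind == "hypothetical", c("participant_id", "auc")],
                by = "participant_id", suffixes = c("_exp", "_hyp"))
  wide <- merge(wide, sens[, c("participant_id", "sensitivity")], by = "participant_id")
  wide <- merge(wide, study$participants[, c("participant_id", "state_anxiety",
                                             "trait_anxiety")], by = "participant_id")

  norms <- normative_anxiety()
  stats_out <- list(
    auc_correlation = pearson_with_test(wide$auc_exp, wide$auc_hyp),
    auc_bayes_factor = if (nrow(wide) >= 4) jzs_correlation_bf(
      stats::cor(wide$auc_exp, wide$auc_hyp), nrow(wide), prior_scale = bf_scale),
    state_vs_normative = welch_t_from_summary(
      mean(wide$state_anxiety), stats::sd(wide$state_anxiety), nrow(wide),
      norms$state$mean, norms$state$sd, norms$state$n),
    trait_vs_normative = welch_t_from_summary(
      mean(wide$trait_anxiety), stats::sd(wide$trait_anxiety), nrow(wide),
      norms$trait$mean, norms$trait$sd, norms$trait$n),
    r2_signed_rank = local({
      r2e <- fits$r2[fits$task_kind == "experiential" & fits$model == "logistic2"]
      r2h <- fits$r2[fits$task_kind == "hypothetical" & fits$model == "logistic2"]
      if (length(r2e) == length(r2h) && length(r2e) >= 5) {
        paired_signed_rank(r2e, r2h)
      } else NULL
    }),
    state_trait_correlation = pearson_with_test(wide$state_anxiety, wide$trait_anxiety))

  paths <- NULL
  if (nrow(wide) >= min_n) {
    pd <- data.frame(state = wide$state_anxiety, trait = wide$trait_anxiety,
                     rs = wide$sensitivity, auc_exp = wide$auc_exp,
                     auc_hyp = wide$auc_hyp)
    fit0 <- fit_path(pd, path_spec(mediation = FALSE))
    fit1 <- fit_path(pd, path_spec(mediation = TRUE))
    paths <- list(
      no_mediation = fit0, mediation = fit1,
      indices = list(no_mediation = fit_indices(fit0), mediation = fit_indices(fit1)),
      indirect = indirect_effect(fit1),
      moderation = moderation_regression(wide$auc_exp, wide$state_anxiety,
                                         wide$trait_anxiety),
      split_half = split_half_groups(wide$trait_anxiety, wide$auc_exp,
                                     wide$state_anxiety))
  } else {
    notes <- c(notes, sprintf(
      "path analysis skipped: insufficient n (%d < %d)", nrow(wide), min_n))
  }

  report <- structure(
    list(study = study, fits = fits, auc = auc, lmm = lmm,
         pleasantness = pleas, sensitivity = sens, participant_summary = wide,
         stats = stats_out, paths = paths, notes = notes,
         manifest = list(seed = seed, n = nrow(study$participants),
                         tasks = names(tasks),
                         package_version = as.character(utils::packageVersion("delaydisc")))),
    class = "dd_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a report bundle to plain-text files
#'
#' CSVs for trials, indifference points, ratings, participants, curve fits,
#' AUC and model-comparison tables; JSON for the scalar statistics, the path
#' results and the run manifest.
#'
#' @param report a `dd_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  wcsv(report$study$participants, "participants.csv")
  wcsv(report$study$trials, "trials.csv")
  wcsv(report$study$points, "indifference_points.csv")
  wcsv(report$study$ratings, "ratings.csv")
  wcsv(report$fits, "curve_fits.csv")
  wcsv(report$auc, "auc.csv")
  cmp <- do.call(rbind, lapply(names(report$lmm), function(k) {
    tab <- report$lmm[[k]]$table; tab$task_kind <- k; tab
  }))
  wcsv(cmp, "model_comparison.csv")
  wcsv(report$sensitivity, "reward_sensitivity.csv")
  stats_json <- report$stats
  if (!is.null(report$paths)) {
    stats_json$paths <- list(
      no_mediation = report$paths$no_mediation$estimates,
      mediation = report$paths$mediation$estimates,
      indices = report$paths$indices,
      indirect = report$paths$indirect,
      moderation = report$paths$moderation$coefficients,
      split_half = report$paths$split_half)
  }
  stats_json$notes <- report$notes
  stats_json$manifest <- report$manifest
  jsonlite::write_json(stats_json, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write small deterministic fixture tables
#'
#' A three-participant synthetic study plus one deterministic threshold-agent
#' session (threshold level 6, whose experiential indifference value is 0.80),
#' written as CSVs for use by tests and examples.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pop <- population_params(n = 3L, seed = seed)
  study <- generate_study(pop, seed = seed)
  utils::write.csv(study$participants, file.path(dir, "participants.csv"), row.names = FALSE)
  utils::write.csv(study$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(study$points, file.path(dir, "indifference_points.csv"), row.names = FALSE)
  utils::write.csv(study$ratings, file.path(dir, "ratings.csv"), row.names = FALSE)
  thr <- run_session(experiential_task(),
                     agent_params("threshold", threshold_level = 6L), seed = seed)
  thr$points$participant_id <- "threshold6"
  thr$points$task_kind <- "experiential"
  utils::write.csv(thr$points, file.path(dir, "threshold_points.csv"), row.names = FALSE)
  invisible(list.files(dir, full.names = TRUE))
}

#' @export
print.dd_report <- function(x, ...) {
  cat(sprintf("<dd_report> %d participants (seed %d)\n",
              x$manifest$n, x$manifest$seed))
  cat(sprintf("  AUC correlation: r = %.3f (p = %.3f), BF10 = %.3f\n",
              x$stats$auc_correlation$r, x$stats$auc_correlation$p,
              x$stats$auc_bayes_factor$bf10))
  if (!is.null(x$paths)) {
    ie <- x$paths$indirect
    cat(sprintf("  indirect state -> sensitivity -> experiential AUC: %.4f (p = %.3f)\n",
                ie$estimate, ie$p))
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}
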