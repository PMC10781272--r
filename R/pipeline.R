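# End-to-end per-participant pipeline: preprocessing grid -> optimisation ->
# overall best model -> explanation bundle -> anomaly rule comparison.

#' Run the full pipeline for one participant
#'
#' Chains the stages: the experiment grid over preprocessing schemes,
#' problem types and optimisation metrics; overall-best selection by mean
#' test MAE; a refit of the winner with retained fold models; the
#' fold-averaged mean-|SHAP| top-feature ranking (wearable/EMA features);
#' ALE curves for the top features; anomaly detection on the mood series;
#' and anchor rule pairs around each anomaly (classification winners only).
#'
#' Budgets default to desk scale; raise `budget`, `population` and `epochs`
#' for a full study-scale run.
#'
#' @param table a raw `participant_table`.
#' @param schemes,methods,budget,population,epochs,k_folds,patience grid
#'   settings (see [run_experiment_grid()]).
#' @param shap_k top-feature count (default 5).
#' @param n_coalitions kernel-SHAP coalitions per instance.
#' @param max_features,precision_target,n_perturbations anchor settings.
#' @param min_jump,max_hours anomaly definition.
#' @param seed integer seed for every stage.
#' @return object of class `participant_report`.
#' @export
run_participant_pipeline <- function(table,
                                     schemes = c("deletion", "manual",
                                                 "automatic"),
                                     methods = c("random", "de"),
                                     budget = 5L, population = 4L,
                                     epochs = 20L, k_folds = 5L,
                                     patience = 10L, shap_k = 5L,
                                     n_coalitions = 200L, max_features = 5L,
                                     precision_target = 0.95,
                                     n_perturbations = 1000L,
                                     min_jump = 2L, max_hours = 24,
                                     seed = 1L) {
  grid <- run_experiment_grid(table, schemes = schemes, methods = methods,
                              budget = budget, population = population,
                              epochs = epochs, k_folds = k_folds,
                              patience = patience, seed = seed)
  best <- select_overall_best(grid, table)
  cell <- best$cell

  # refit the winner on its preprocessed table, keeping fold models
  pp <- preprocess(table, cell$scheme)
  arch <- cell$cv_report$arch
  cv <- train_with_cv(pp$table, arch, loss_kind = cell$loss_kind,
                      epochs = cell$train_settings$epochs,
                      k = cell$train_settings$k_folds,
                      patience = cell$train_settings$patience,
                      seed = cell$seed, keep_models = TRUE)

  ranking <- rank_features_by_shap(cv, pp$table, k = shap_k,
                                   n_coalitions = n_coalitions,
                                   seed = derive_seed(seed, "shap"))
  ale <- lapply(ranking$feature, function(fn)
    ale_curve_cv(cv, pp$table, fn))
  names(ale) <- ranking$feature

  anomalies <- detect_mood_anomalies(pp$table$y, pp$table$timestamps,
                                     min_jump = min_jump,
                                     max_hours = max_hours)
  anomaly_explanations <- list()
  if (arch$problem_type == "classification" && nrow(anomalies) > 0L) {
    fm <- cv$fold_models[[1L]]
    for (e in seq_len(nrow(anomalies))) {
      anomaly_explanations[[e]] <- explain_anomaly(
        fm$model, fm$scaler, pp$table, anomalies[e, ],
        max_features = max_features, precision_target = precision_target,
        n_perturbations = n_perturbations,
        seed = derive_seed(seed, "anomaly", e))
    }
  }

  structure(list(
    participant_id = table$participant_id,
    grid = grid, best_cell = cell, cv_report = cv,
    shap_ranking = ranking, ale_curves = ale,
    anomalies = anomalies, anomaly_explanations = anomaly_explanations,
    seed = seed
  ), class = "participant_report")
}

#' @export
print.participant_report <- function(x, ...) {
  present <- Filter(function(c) !c$absent, x$grid)
  maes <- vapply(present, function(c) unname(c$cv_report$mean$test[["mae"]]), 0)
  # consistency cross-check: the selected cell must attain the grid minimum
  stopifnot(abs(unname(x$best_cell$cv_report$mean$test[["mae"]]) -
                min(maes)) < 1e-12)
  cat("== Participant ", x$participant_id, " ==\n", sep = "")
  cat("Grid: ", length(x$grid), " cells (", length(present),
      " present)\n", sep = "")
  cat("Overall best: ", x$best_cell$problem_type, " / ",
      x$best_cell$scheme, " / optimised on ", x$best_cell$metric,
      " via ", x$best_cell$best_method, "\n", sep = "")
  cat(sprintf("  mean test MAE %.3f, MAPE %.1f%%\n",
              x$best_cell$cv_report$mean$test[["mae"]],
              x$best_cell$cv_report$mean$test[["mape"]]))
  cat("Top features by mean |SHAP|:\n")
  print(x$shap_ranking, row.names = FALSE)
  cat(nrow(x$anomalies), " anomalous mood jump(s) detected\n", sep = "")
  for (ae in x$anomaly_explanations) {
    if (isTRUE(ae$skipped)) cat("  [skipped: ", ae$reason, "]\n", sep = "")
    else cat(ae$rendered)
  }
  invisible(x)
}

#' Serialise a participant report to JSON
#'
#' @param report a `participant_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  present <- Filter(function(c) !c$absent, report$grid)
  out <- list(
    participant_id = report$participant_id,
    grid = lapply(report$grid, function(c) {
      if (c$absent) list(problem_type = c$problem_type, scheme = c$scheme,
                         metric = c$metric, absent = TRUE, reason = c$reason)
      else list(problem_type = c$problem_type, scheme = c$scheme,
                metric = c$metric, absent = FALSE,
                best_method = c$best_method, candidate = c$candidate,
                mean_test = as.list(c$cv_report$mean$test))
    }),
    best = list(problem_type = report$best_cell$problem_type,
                scheme = report$best_cell$scheme,
                metric = report$best_cell$metric,
                candidate = report$best_cell$candidate,
                mean_test = as.list(report$best_cell$cv_report$mean$test),
                sd_test = as.list(report$best_cell$cv_report$sd$test)),
    shap_top_features = report$shap_ranking,
    ale_curves = lapply(report$ale_curves, function(c)
      list(feature = c$feature, edges = c$edges, effect = c$effect)),
    anomalies = report$anomalies,
    anomaly_rules = lapply(report$anomaly_explanations, function(ae) {
      if (isTRUE(ae$skipped)) list(skipped = TRUE, reason = ae$reason)
      else list(skipped = FALSE, before = format_anchor(ae$before),
                after = format_anchor(ae$after),
                changed_features = ae$changed_features)
    }),
    seed = report$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
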