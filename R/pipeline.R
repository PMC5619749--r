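#' Run the full classification–prediction–optimization study
#'
#' Orchestrates every stage on one table: boundary labelling, SMOTE
#' rebalancing, both classifiers with and without SMOTE, the repeated
#' 16/4 holdout evaluation of the yield regressor, and repeated
#' train-then-GA optimization runs. One master seed deterministically
#' derives every stage seed, so two calls with the same arguments are
#' identical in every output.
#'
#' @param seed Master seed.
#' @param data A culture table; defaults to the packaged experiments.
#' @param boundary Yield boundary in μg/ml; `NULL` selects the per-group
#'   balanced boundary computed from the data. The study profile uses
#'   1273.
#' @param smote_k,smote_target SMOTE neighbour count and minority target.
#' @param n_train,n_test,repeats Holdout protocol (16/4, 7 repeats).
#' @param ga_runs Number of independent train-then-optimize runs.
#' @param ga_parameters A [ga_params()] object.
#' @param specs Factor specifications.
#' @return An object of class `fermopt_study`: a list with `boundary`,
#'   `counts`, `confusion` (tibble of accuracy summaries per model and
#'   SMOTE state), `confusion_matrices` (the four `confusion_matrix`
#'   objects), `holdout` (the 28-row report), `holdout_summary`,
#'   `ga_runs` (one row per run: conditions, predicted yield,
#'   iterations), and `ga_summary`.
#' @export
#' @examples
#' \donttest{
#' study <- run_study(seed = 1)
#' study$ga_summary
#' }
run_study <- function(seed = 1, data = phellinus_experiments(),
                      boundary = 1273, smote_k = 5, smote_target = 30,
                      n_train = 16, n_test = 4, repeats = 7,
                      ga_runs = 7, ga_parameters = ga_params(specs = specs),
                      specs = phellinus_factors()) {
  stage_seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max %/% 2, 4 + ga_runs)
  })

  interval <- NULL
  if (is.null(boundary)) {
    pg <- per_group_boundary(data)
    boundary <- pg$threshold
    interval <- c(pg$interval_lower, pg$interval_upper)
  }
  labelled <- assign_labels(data, boundary)
  counts <- class_counts(labelled)

  augmented <- smote_oversample(labelled, k = smote_k, target = smote_target,
                                seed = stage_seeds[1], specs = specs)

  # Reproduction protocol: fit on the available labelled set; the plain
  # models are scored on the original records, the SMOTE models on the
  # augmented set (the shape of the printed reports).
  cms <- list(
    logistic_plain = evaluate_classifier(fit_logistic(labelled, specs), labelled),
    logistic_smote = evaluate_classifier(fit_logistic(augmented, specs), augmented),
    bp_plain = evaluate_classifier(
      fit_bp_classifier(labelled, seed = stage_seeds[2], specs = specs), labelled),
    bp_smote = evaluate_classifier(
      fit_bp_classifier(augmented, seed = stage_seeds[3], specs = specs), augmented)
  )
  confusion <- purrr::imap_dfr(cms, function(cm, nm) {
    dplyr::mutate(glance(cm),
                  model = sub("_.*", "", nm),
                  smote = grepl("smote", nm),
                  .before = 1)
  })

  high <- dplyr::filter(labelled, .data$label == 1, !.data$synthetic)
  holdout <- repeated_holdout(high, n_train = n_train, n_test = n_test,
                              repeats = repeats, seed = stage_seeds[4],
                              spec = network_spec(specs = specs))
  holdout_summary <- aggregate_errors(holdout)

  ga_tbl <- purrr::map_dfr(seq_len(ga_runs), function(i) {
    s <- stage_seeds[4 + i]
    net <- train_network(high, seed = s, spec = network_spec(specs = specs))
    res <- run_ga(net, ga_parameters, seed = s)
    dplyr::mutate(tidy(res), run = i, .before = 1)
  })
  ga_summary <- tibble::tibble(
    runs = ga_runs,
    mean_yield = mean(ga_tbl$predicted_yield),
    best_yield = max(ga_tbl$predicted_yield),
    mean_iterations = mean(ga_tbl$iterations)
  )

  structure(
    list(
      seed = seed,
      boundary = boundary,
      boundary_interval = interval,
      counts = counts,
      confusion = confusion,
      confusion_matrices = cms,
      holdout = holdout,
      holdout_summary = holdout_summary,
      ga_runs = ga_tbl,
      ga_summary = ga_summary
    ),
    class = "fermopt_study"
  )
}

#' @export
print.fermopt_study <- function(x, ...) {
  cat("Fermentation condition study (seed ", x$seed, ")\n", sep = "")
  cat("boundary: ", x$boundary, " ug/ml -> ", x$counts$n_high,
      " high / ", x$counts$n_low, " low\n", sep = "")
  cat("\nclassifier accuracy (%):\n")
  print(as.data.frame(x$confusion[, c("model", "smote", "accuracy_pct")]))
  cat("\nholdout forecast: mean error ",
      round(x$holdout_summary$mean_error, 2), " ug/ml, mean pct error ",
      round(x$holdout_summary$mean_pct_error, 2), "% (accuracy ",
      round(x$holdout_summary$forecast_accuracy, 1), "%)\n", sep = "")
  cat("\nGA optima over ", x$ga_summary$runs, " runs: mean ",
      round(x$ga_summary$mean_yield, 1), " ug/ml, best ",
      round(x$ga_summary$best_yield, 1), " ug/ml\n", sep = "")
  invisible(x)
}

#' @method glance fermopt_study
#' @export
glance.fermopt_study <- function(x, ...) {
  tibble::tibble(
    boundary = x$boundary,
    n_high = x$counts$n_high,
    n_low = x$counts$n_low,
    logistic_smote_accuracy = x$confusion$accuracy_pct[
      x$confusion$model == "logistic" & x$confusion$smote],
    bp_smote_accuracy = x$confusion$accuracy_pct[
      x$confusion$model == "bp" & x$confusion$smote],
    forecast_accuracy = x$holdout_summary$forecast_accuracy,
    ga_mean_yield = x$ga_summary$mean_yield
  )
}

#' Screen proposed culture conditions
#'
#' The deployment protocol for new conditions: the classifier decides
#' whether a condition is high-yield; only class-1 conditions get a yield
#' forecast from the regressor (the regressor was trained on high-yield
#' records only, so its forecasts are not trusted elsewhere). Malformed
#' rows are reported per row and do not stop the batch.
#'
#' @param classifier A fitted `yield_logistic` or `yield_nn_classifier`.
#' @param net A trained `yield_network`.
#' @param conditions A data frame of condition rows (factor columns).
#' @return A tibble: the conditions plus `predicted_class`,
#'   `predicted_yield` (`NA` for class-0 rows) and `note` (`NA` or the
#'   row's error message).
#' @export
screen_conditions <- function(classifier, net, conditions) {
  purrr::map_dfr(seq_len(nrow(conditions)), function(i) {
    row <- conditions[i, ]
    res <- tryCatch({
      if (anyNA(row[intersect(factor_cols(), names(row))])) {
        stop("missing factor value", call. = FALSE)
      }
      cls <- predict(classifier, row, type = "class")
      yld <- if (cls == 1) predict_yield(net, row) else NA_real_
      dplyr::mutate(row, predicted_class = cls, predicted_yield = yld,
                    note = NA_character_)
    }, error = function(e) {
      dplyr::mutate(row, predicted_class = NA_real_,
                    predicted_yield = NA_real_,
                    note = conditionMessage(e))
    })
    res
  })
}
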