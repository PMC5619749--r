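#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the single-factor yield series
#'
#' One panel per single-factor group, yield against the varied factor —
#' the standard diagnostic view of a single-factor campaign, showing each
#' factor's unimodal response.
#'
#' @param data A culture table with `group` and yields.
#' @return A ggplot.
#' @export
plot_yield_series <- function(data) {
  validate_culture_table(data)
  long <- purrr::map_dfr(unique(stats::na.omit(data$group)), function(g) {
    rows <- dplyr::filter(data, .data$group == g)
    fac <- if (g %in% names(rows)) g else factor_cols()[1]
    tibble::tibble(
      group = g,
      level = rows[[fac]],
      yield_ug_ml = rows$yield_ug_ml
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$level, .data$yield_ug_ml)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::labs(x = "factor level", y = "flavonoid yield (µg/ml)")
}

#' @rdname autoplot_fermopt
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(truth = c("0", "1"), predicted = c("0", "1"))
  df$n <- as.numeric(t(object$counts))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = c("1", "0")) +
    ggplot2::labs(
      title = sprintf("overall accuracy %.1f%%", object$overall),
      x = "predicted class", y = "true class"
    ) +
    ggplot2::guides(fill = "none")
}

#' Diagnostic plots for pipeline results
#'
#' `autoplot()` methods: a tile plot for a [confusion_matrix()], actual vs
#' forecast with the error band for a [repeated_holdout()] report, and the
#' best-so-far fitness trajectory for a [run_ga()] result.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot_fermopt
NULL

#' @rdname autoplot_fermopt
#' @method autoplot holdout_report
#' @export
autoplot.holdout_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$actual, .data$forecast)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$repeat_id))) +
    ggplot2::labs(x = "actual yield (µg/ml)",
                  y = "forecast yield (µg/ml)",
                  colour = "holdout repeat")
}

#' @rdname autoplot_fermopt
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  df <- tibble::tibble(
    generation = seq_along(object$history) - 1,
    best_yield = object$history
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$best_yield)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$converged_at, linetype = 3) +
    ggplot2::labs(x = "generation",
                  y = "best predicted yield (µg/ml)")
}
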