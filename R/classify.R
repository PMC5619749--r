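#' Build a 2x2 confusion matrix with per-class accuracies
#'
#' The report layout used throughout the classification stage: rows are
#' true classes, columns predicted classes, and each row carries its
#' percent correct (diagonal over row total); the overall accuracy is the
#' trace over the grand total.
#'
#' @param truth,predicted Vectors of 0/1 labels of equal length.
#' @return An object of class `confusion_matrix`: a list with `counts`
#'   (2x2 matrix), `per_class` (percent correct for class 0 and 1) and
#'   `overall` (percent).
#' @export
#' @examples
#' cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' tidy(cm)
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.numeric(truth)
  predicted <- as.numeric(predicted)
  stopifnot(all(truth %in% c(0, 1)), all(predicted %in% c(0, 1)))
  counts <- matrix(
    c(sum(truth == 0 & predicted == 0), sum(truth == 0 & predicted == 1),
      sum(truth == 1 & predicted == 0), sum(truth == 1 & predicted == 1)),
    nrow = 2, byrow = TRUE,
    dimnames = list(truth = c("0", "1"), predicted = c("0", "1"))
  )
  row_tot <- rowSums(counts)
  per_class <- unname(ifelse(row_tot > 0, 100 * diag(counts) / row_tot,
                             NA_real_))
  overall <- 100 * sum(diag(counts)) / sum(counts)
  structure(
    list(counts = counts, per_class = per_class, overall = overall),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted)\n")
  print(cbind(x$counts, `correct %` = round(x$per_class, 1)))
  cat("overall:", round(x$overall, 1), "%\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname confusion_matrix
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    truth = c("0", "1", "total"),
    predicted_0 = c(x$counts[1, 1], x$counts[2, 1], NA_real_),
    predicted_1 = c(x$counts[1, 2], x$counts[2, 2], NA_real_),
    correct_pct = c(x$per_class, x$overall)
  )
}

#' @rdname confusion_matrix
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    n = sum(x$counts),
    accuracy_pct = x$overall,
    class0_pct = x$per_class[[1]],
    class1_pct = x$per_class[[2]]
  )
}

# Standardized design matrix over the seven factors in gradient units;
# constant columns carry no information and break standardization, so they
# are dropped with a warning (pH is constant within several subsets).
classifier_features <- function(data, specs) {
  g <- to_gradient_units(data, specs)
  keep <- apply(g, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(g)[!keep], collapse = ", "), call. = FALSE)
  }
  g[, keep, drop = FALSE]
}

#' Fit a logistic high/low-yield classifier
#'
#' Maximum-likelihood binary logistic regression with intercept over the
#' seven condition factors in gradient units, standardized internally to
#' zero mean and unit variance; constant features are dropped with a
#' warning. Perfect separation produces the usual fitted-probability
#' warning but still returns the capped-iteration fit.
#'
#' @param data A labelled culture table.
#' @param specs Factor specifications.
#' @param tol Convergence tolerance for the deviance (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `yield_logistic` with a [predict] method.
#' @export
#' @examples
#' labelled <- assign_labels(phellinus_experiments(), 1273)
#' fit <- fit_logistic(labelled)
#' glance(evaluate_classifier(fit, labelled))
fit_logistic <- function(data, specs = phellinus_factors(),
                         tol = 1e-8, max_iter = 100) {
  if (!"label" %in% names(data) || anyNA(data$label)) {
    stop("table must be fully labelled", call. = FALSE)
  }
  if (dplyr::n_distinct(data$label) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  x <- classifier_features(data, specs)
  centers <- colMeans(x)
  scales <- apply(x, 2, stats::sd)
  xs <- scale(x, center = centers, scale = scales)
  df <- as.data.frame(xs)
  df$.label <- data$label
  fit <- withCallingHandlers(
    stats::glm(.label ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(
    list(fit = fit, features = colnames(x), centers = centers,
         scales = scales, specs = specs),
    class = "yield_logistic"
  )
}

#' @rdname fit_logistic
#' @param object A fitted `yield_logistic`.
#' @param newdata A culture table to classify.
#' @param type `"class"` for 0/1 labels (0.5 cutoff) or `"prob"` for
#'   class-1 probabilities.
#' @param ... Unused.
#' @export
predict.yield_logistic <- function(object, newdata, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  g <- to_gradient_units(newdata, object$specs)
  xs <- scale(g[, object$features, drop = FALSE],
              center = object$centers, scale = object$scales)
  p <- stats::predict(object$fit, newdata = as.data.frame(xs),
                      type = "response")
  p <- unname(p)
  if (type == "prob") p else as.numeric(p >= 0.5)
}

#' @method tidy yield_logistic
#' @export
tidy.yield_logistic <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, 1],
    std_error = co[, 2],
    statistic = co[, 3],
    p_value = co[, 4]
  )
}

#' Fit a feed-forward neural-network classifier
#'
#' The same multilayer architecture as the yield regressor (two hidden
#' layers of 9 units, tanh then logistic) with a logistic output unit
#' trained against 0/1 labels by Levenberg–Marquardt; predicted class is 1
#' when the output exceeds 0.5. Inputs are scaled to \[-1, 1\] by the
#' declared factor bounds.
#'
#' @param data A labelled culture table (synthetic records allowed; labels
#'   are the targets).
#' @param seed Integer seed for weight initialization.
#' @param specs Factor specifications.
#' @param max_epochs,sse_target Training limits (see [train_network()]).
#' @return An object of class `yield_nn_classifier`.
#' @export
fit_bp_classifier <- function(data, seed = 1, specs = phellinus_factors(),
                              max_epochs = 1000, sse_target = 1e-5) {
  if (!"label" %in% names(data) || anyNA(data$label)) {
    stop("table must be fully labelled", call. = FALSE)
  }
  if (dplyr::n_distinct(data$label) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  spec <- network_spec(
    factors = factor_cols(), specs = specs,
    output = "logistic", max_epochs = max_epochs, sse_target = sse_target
  )
  net <- build_network(spec, seed = seed)
  x <- scale_inputs(data, spec)
  net <- lm_train(net, x, data$label)
  structure(list(net = net, spec = spec), class = "yield_nn_classifier")
}

#' @rdname fit_bp_classifier
#' @param object A fitted `yield_nn_classifier`.
#' @param newdata A culture table to classify.
#' @param type `"class"` (0.5 cutoff) or `"prob"`.
#' @param ... Unused.
#' @export
predict.yield_nn_classifier <- function(object, newdata,
                                        type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- scale_inputs(newdata, object$spec)
  p <- as.numeric(forward_pass(object$net, x)$output)
  if (type == "prob") p else as.numeric(p >= 0.5)
}

#' Evaluate a classifier on a labelled table
#'
#' @param model A `yield_logistic` or `yield_nn_classifier`.
#' @param data A labelled culture table.
#' @return A [confusion_matrix()].
#' @export
evaluate_classifier <- function(model, data) {
  if (!"label" %in% names(data) || anyNA(data$label)) {
    stop("table must be fully labelled", call. = FALSE)
  }
  confusion_matrix(data$label, predict(model, data, type = "class"))
}
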