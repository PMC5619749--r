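#' Specify the feed-forward yield network
#'
#' The regression surrogate is a feed-forward network with two hidden
#' layers of 9 units (tanh then logistic transfer functions) and a tanh
#' output unit — the three transfer functions tansig, logsig, tansig over
#' the layer layout (9, 9, 1) — trained by Levenberg–Marquardt to a
#' sum-squared error target of 1e-5 (scaled units) within 1000 epochs.
#' Inputs are scaled to \[-1, 1\] by the declared factor bounds — not the
#' sample range — so the optimizer can query the surrogate anywhere in
#' the condition box; training yields are min-max scaled to
#' \[-0.9, 0.9\] (see [train_network()]), which keeps the tanh output
#' off its asymptotes and bounds extrapolated yields to about 5% beyond
#' the training range. For yield regression the input dimension is 6: pH
#' is excluded because every high-yield record sits at pH 6 and a
#' constant input carries no information.
#'
#' @param factors Character vector of input factor names; defaults to the
#'   free (non-fixed) factors of `specs`.
#' @param specs Factor specifications providing the scaling bounds.
#' @param hidden Hidden layer sizes, default `c(9, 9)`.
#' @param activations Hidden transfer functions, default
#'   `c("tanh", "logistic")`.
#' @param output Output unit: `"tanh"` (bounded regression, the default),
#'   `"logistic"` (classification) or `"linear"`.
#' @param max_epochs Training epoch cap, default 1000.
#' @param sse_target Stop once the training sum-squared error (scaled
#'   units) falls below this, default 1e-5.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(factors = NULL, specs = phellinus_factors(),
                         hidden = c(9, 9),
                         activations = c("tanh", "logistic"),
                         output = c("tanh", "logistic", "linear"),
                         max_epochs = 1000, sse_target = 1e-5) {
  output <- match.arg(output)
  validate_factor_specs(specs)
  if (is.null(factors)) factors <- specs$factor[!specs$fixed]
  unknown <- setdiff(factors, specs$factor)
  if (length(unknown) > 0) {
    stop("unknown factor(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  stopifnot(length(hidden) == length(activations), all(hidden >= 1))
  stopifnot(all(activations %in% c("tanh", "logistic", "linear")))
  stopifnot(output %in% c("tanh", "logistic", "linear"))
  idx <- match(factors, specs$factor)
  structure(
    list(
      factors = factors,
      lower = specs$lower[idx],
      upper = specs$upper[idx],
      hidden = as.integer(hidden),
      activations = activations,
      output = output,
      max_epochs = max_epochs,
      sse_target = sse_target
    ),
    class = "network_spec"
  )
}

# Layer sizes including input and output.
layer_sizes <- function(spec) c(length(spec$factors), spec$hidden, 1L)

#' Number of free parameters of a network layout
#'
#' Each layer contributes `units * inputs` weights plus `units` biases
#' (in the back-propagation literature the bias is often called a
#' "threshold").
#'
#' @param spec A `network_spec`.
#' @return Integer parameter count.
#' @export
#' @examples
#' n_parameters(network_spec())  # (6*9+9)+(9*9+9)+(9+1) = 163
n_parameters <- function(spec) {
  sz <- layer_sizes(spec)
  sum(sz[-1] * (sz[-length(sz)] + 1L))
}

# Map condition columns onto [-1, 1] by the declared bounds.
scale_inputs <- function(data, spec) {
  missing <- setdiff(spec$factors, names(data))
  if (length(missing) > 0) {
    stop("culture table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(as.data.frame(data)[, spec$factors, drop = FALSE])
  scale_condition_matrix(m, spec)
}

scale_condition_matrix <- function(m, spec) {
  lo <- spec$lower
  hi <- spec$upper
  t(2 * (t(m) - lo) / (hi - lo) - 1)
}

act_fun <- function(name) {
  switch(name,
    tanh = tanh,
    logistic = function(z) 1 / (1 + exp(-z)),
    linear = identity
  )
}

# Derivative expressed through the activation value.
act_deriv <- function(name, a) {
  switch(name,
    tanh = 1 - a^2,
    logistic = a * (1 - a),
    linear = matrix(1, nrow(a), ncol(a))
  )
}

#' Initialize a network with seeded small-random parameters
#'
#' @param spec A `network_spec`.
#' @param seed Integer seed; the same seed always produces bitwise
#'   identical parameters.
#' @param init_scale Half-width of the uniform initialization interval.
#' @return An untrained object of class `yield_network`.
#' @export
build_network <- function(spec, seed = 1, init_scale = 0.5) {
  stopifnot(inherits(spec, "network_spec"))
  sz <- layer_sizes(spec)
  nlayer <- length(sz) - 1
  pars <- withr::with_seed(seed, {
    W <- vector("list", nlayer)
    b <- vector("list", nlayer)
    for (l in seq_len(nlayer)) {
      W[[l]] <- matrix(stats::runif(sz[l + 1] * sz[l], -init_scale, init_scale),
                       nrow = sz[l + 1])
      b[[l]] <- stats::runif(sz[l + 1], -init_scale, init_scale)
    }
    list(W = W, b = b)
  })
  structure(
    list(spec = spec, W = pars$W, b = pars$b,
         y_center = 0, y_half = 1, y_gain = 1,
         seed = seed, trained = FALSE, epochs = 0L,
         sse = NA_real_, sse_history = numeric(0)),
    class = "yield_network"
  )
}

# Forward pass on a matrix of scaled inputs; returns activations per layer.
forward_pass <- function(net, x) {
  spec <- net$spec
  acts <- c(spec$activations, spec$output)
  A <- vector("list", length(acts) + 1)
  A[[1]] <- x
  for (l in seq_along(acts)) {
    z <- A[[l]] %*% t(net$W[[l]]) + matrix(net$b[[l]], nrow(x),
                                           length(net$b[[l]]), byrow = TRUE)
    A[[l + 1]] <- act_fun(acts[l])(z)
  }
  list(output = A[[length(A)]], A = A)
}

pack_params <- function(net) {
  unlist(c(lapply(net$W, as.numeric), net$b), use.names = FALSE)
}

unpack_params <- function(net, theta) {
  sz <- layer_sizes(net$spec)
  pos <- 1
  for (l in seq_along(net$W)) {
    n <- length(net$W[[l]])
    net$W[[l]] <- matrix(theta[pos:(pos + n - 1)], nrow = sz[l + 1])
    pos <- pos + n
  }
  for (l in seq_along(net$b)) {
    n <- length(net$b[[l]])
    net$b[[l]] <- theta[pos:(pos + n - 1)]
    pos <- pos + n
  }
  net
}

# Batched Jacobian of the scalar output w.r.t. every parameter: one row per
# sample. Sensitivities propagate backwards layer by layer; the column block
# for W_l follows column-major order of the weight matrix.
output_jacobian <- function(net, fw) {
  spec <- net$spec
  acts <- c(spec$activations, spec$output)
  L <- length(acts)
  n <- nrow(fw$A[[1]])
  S <- vector("list", L)
  S[[L]] <- act_deriv(acts[L], fw$A[[L + 1]])
  for (l in seq(L - 1, 1)) {
    S[[l]] <- (S[[l + 1]] %*% net$W[[l + 1]]) * act_deriv(acts[l], fw$A[[l + 1]])
  }
  wblocks <- vector("list", L)
  bblocks <- vector("list", L)
  for (l in seq_len(L)) {
    p <- ncol(S[[l]])
    q <- ncol(fw$A[[l]])
    wblocks[[l]] <- S[[l]][, rep(seq_len(p), times = q), drop = FALSE] *
      fw$A[[l]][, rep(seq_len(q), each = p), drop = FALSE]
    bblocks[[l]] <- S[[l]]
  }
  do.call(cbind, c(wblocks, bblocks))
}

# Levenberg-Marquardt minimization of sum((yhat - t)^2) on scaled targets.
# Damping: start 1e-3, x10 on a rejected step, /10 on an accepted one; the
# SSE history therefore records only accepted (non-increasing) values.
lm_train <- function(net, x, targets, lambda0 = 1e-3, lambda_max = 1e10) {
  spec <- net$spec
  theta <- pack_params(net)
  fw <- forward_pass(net, x)
  r <- as.numeric(fw$output) - targets
  sse <- sum(r^2)
  if (!is.finite(sse)) stop("non-finite training loss at epoch 0", call. = FALSE)
  history <- sse
  lambda <- lambda0
  epoch <- 0L
  while (epoch < spec$max_epochs && sse > spec$sse_target) {
    J <- output_jacobian(net, fw)
    g <- crossprod(J, r)
    if (sqrt(sum(g^2)) < 1e-12) break
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (!accepted && lambda <= lambda_max) {
      delta <- tryCatch(
        solve(JtJ + diag(lambda, ncol(J)), -g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        cand <- unpack_params(net, theta + as.numeric(delta))
        fw_cand <- forward_pass(cand, x)
        r_cand <- as.numeric(fw_cand$output) - targets
        sse_cand <- sum(r_cand^2)
        if (!is.finite(sse_cand)) {
          stop("non-finite training loss at epoch ", epoch + 1L, call. = FALSE)
        }
        if (sse_cand < sse) {
          net <- cand
          theta <- pack_params(net)
          fw <- fw_cand
          r <- r_cand
          sse <- sse_cand
          lambda <- lambda / 10
          accepted <- TRUE
        }
      }
      if (!accepted) lambda <- lambda * 10
    }
    if (!accepted) break  # damping exhausted: local minimum
    epoch <- epoch + 1L
    history <- c(history, sse)
  }
  net$trained <- TRUE
  net$epochs <- epoch
  net$sse <- sse
  net$sse_history <- history
  net
}

#' Train the yield-regression network
#'
#' Fits the surrogate on original (non-synthetic) records with measured
#' yields: inputs are the free factors scaled to \[-1, 1\] by their
#' bounds, targets are yields min-max scaled to \[-0.9, 0.9\] over the
#' training set, and training is Levenberg–Marquardt on the sum-squared
#' scaled error (accepted steps are strictly decreasing) until the 1e-5
#' error target or the 1000-epoch cap. The 0.9 gain keeps the extreme
#' training yields away from the tanh output's asymptotes, so the fit can
#' converge while predictions stay bounded within about 5% beyond the
#' observed yield range — the surrogate can propose conditions slightly
#' better than the best experiment but cannot run away where no data
#' constrain it. Synthetic records are refused — their yields were never
#' measured.
#'
#' @param data A culture table of training records with yields.
#' @param seed Integer seed for weight initialization.
#' @param spec A `network_spec`; the default is the 6-input regression
#'   layout.
#' @param target_gain Scaled-target half-range (default 0.9): training
#'   yields map onto \[-target_gain, target_gain\].
#' @param ... Passed to [network_spec()] when `spec` is `NULL`.
#' @return A trained `yield_network`.
#' @export
#' @examples
#' high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273), label == 1)
#' net <- train_network(high, seed = 1)
#' glance(net)
train_network <- function(data, seed = 1, spec = NULL, target_gain = 0.9, ...) {
  if (is.null(spec)) spec <- network_spec(...)
  if ("synthetic" %in% names(data) && any(data$synthetic)) {
    stop("synthetic records have no measured yield and cannot train the regressor",
         call. = FALSE)
  }
  validate_culture_table(data, require_yield = TRUE)
  if (nrow(data) < 2) stop("at least 2 training records are required", call. = FALSE)
  stopifnot(target_gain > 0, target_gain <= 1)
  x <- scale_inputs(data, spec)
  y <- data$yield_ug_ml
  center <- (max(y) + min(y)) / 2
  half <- (max(y) - min(y)) / 2
  targets <- if (half > 0) target_gain * (y - center) / half else rep(0, length(y))
  net <- build_network(spec, seed = seed)
  net <- lm_train(net, x, targets)
  net$y_center <- center
  net$y_half <- half
  net$y_gain <- target_gain
  net
}

#' Predict flavonoid yield for culture conditions
#'
#' Deterministic forward pass of the trained surrogate; conditions outside
#' the declared factor bounds are allowed with a warning (the network
#' extrapolates there).
#'
#' @param net A trained `yield_network`.
#' @param newdata A culture table (or any data frame with the input factor
#'   columns).
#' @return Numeric vector of predicted yields in μg/ml.
#' @export
predict_yield <- function(net, newdata) {
  stopifnot(inherits(net, "yield_network"))
  if (!isTRUE(net$trained)) stop("network is not trained", call. = FALSE)
  x <- scale_inputs(newdata, net$spec)
  if (any(x < -1 - 1e-9) || any(x > 1 + 1e-9)) {
    warning("condition outside the declared factor bounds; extrapolating",
            call. = FALSE)
  }
  o <- as.numeric(forward_pass(net, x)$output)
  out <- net$y_center + (o / net$y_gain) * net$y_half
  stopifnot(all(is.finite(out)))
  out
}

#' @export
predict.yield_network <- function(object, newdata, ...) {
  predict_yield(object, newdata)
}

#' @export
print.yield_network <- function(x, ...) {
  sz <- layer_sizes(x$spec)
  cat("Feed-forward yield network ", paste(sz, collapse = "-"),
      " (", n_parameters(x$spec), " parameters)\n", sep = "")
  if (x$trained) {
    cat("trained: ", x$epochs, " epochs, final SSE ",
        signif(x$sse, 4), " (scaled units)\n", sep = "")
  } else {
    cat("untrained\n")
  }
  invisible(x)
}

#' @method glance yield_network
#' @export
glance.yield_network <- function(x, ...) {
  tibble::tibble(
    n_parameters = n_parameters(x$spec),
    epochs = x$epochs,
    sse = x$sse,
    converged = isTRUE(x$trained) && !is.na(x$sse) &&
      x$sse <= x$spec$sse_target,
    seed = x$seed
  )
}

#' @method tidy yield_network
#' @export
tidy.yield_network <- function(x, ...) {
  purrr::map2_dfr(seq_along(x$W), x$W, function(l, W) {
    tibble::tibble(
      layer = l,
      unit = rep(seq_len(nrow(W)), ncol(W) + 1),
      input = c(rep(seq_len(ncol(W)), each = nrow(W)), rep(NA_integer_, nrow(W))),
      term = c(rep("weight", length(W)), rep("bias", nrow(W))),
      value = c(as.numeric(W), x$b[[l]])
    )
  })
}

#' Absolute and percentage forecast errors
#'
#' For actual yield x and forecast y, the error is z = |x - y| and the
#' percentage error is z / x, reported in percent.
#'
#' @param actual,forecast Numeric vectors (μg/ml); `actual` must be > 0.
#' @return A tibble: `actual`, `forecast`, `error`, `pct_error` (percent).
#' @export
#' @examples
#' error_metrics(1447.519173, 1587.9)  # error 140.38, pct 9.7
error_metrics <- function(actual, forecast) {
  stopifnot(length(actual) == length(forecast))
  if (any(actual <= 0)) stop("actual yield must be > 0", call. = FALSE)
  z <- abs(actual - forecast)
  tibble::tibble(
    actual = actual,
    forecast = forecast,
    error = z,
    pct_error = 100 * z / actual
  )
}

#' Repeated random holdout evaluation of the yield regressor
#'
#' Repeats a seeded random train/test split of the supplied records
#' (default 16 train / 4 test over the 20 high-yield records, 7 repeats),
#' trains a fresh network on each training split, and concatenates the
#' per-test-record error metrics — 28 rows under the defaults.
#'
#' @param data Records with yields; `n_train + n_test` must equal
#'   `nrow(data)`.
#' @param n_train,n_test Split sizes.
#' @param repeats Number of independent splits.
#' @param seed Master seed; drives both the splits and the per-repeat
#'   weight initializations.
#' @param spec Optional `network_spec`.
#' @return A tibble of class `holdout_report`: `repeat_id`, `record`,
#'   `actual`, `forecast`, `error`, `pct_error`.
#' @export
repeated_holdout <- function(data, n_train = 16, n_test = 4, repeats = 7,
                             seed = 1, spec = NULL) {
  if (n_train + n_test != nrow(data)) {
    stop("n_train + n_test must equal the record count (",
         nrow(data), ")", call. = FALSE)
  }
  splits <- withr::with_seed(seed, {
    list(
      test = purrr::map(seq_len(repeats), ~sample.int(nrow(data), n_test)),
      net_seed = sample.int(.Machine$integer.max %/% 2, repeats)
    )
  })
  rows <- purrr::map_dfr(seq_len(repeats), function(rep) {
    test_idx <- splits$test[[rep]]
    net <- train_network(data[-test_idx, ], seed = splits$net_seed[rep],
                         spec = spec)
    test <- data[test_idx, ]
    metrics <- error_metrics(test$yield_ug_ml, predict_yield(net, test))
    dplyr::mutate(metrics, repeat_id = rep, record = test_idx,
                  .before = 1)
  })
  class(rows) <- c("holdout_report", class(rows))
  rows
}

#' Aggregate a holdout (or any) error report
#'
#' @param report A tibble with `error` and `pct_error` columns, e.g. from
#'   [repeated_holdout()] or [error_metrics()].
#' @return A one-row tibble: `n`, `mean_error` (μg/ml), `mean_pct_error`
#'   (percent), `forecast_accuracy` (= 100 - mean_pct_error).
#' @export
#' @examples
#' aggregate_errors(with(holdout_reference(), error_metrics(actual, forecast)))
aggregate_errors <- function(report) {
  if (nrow(report) == 0) stop("empty report", call. = FALSE)
  tibble::tibble(
    n = nrow(report),
    mean_error = mean(report$error),
    mean_pct_error = mean(report$pct_error),
    forecast_accuracy = 100 - mean(report$pct_error)
  )
}
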