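test_that("parameter counts follow the weights-plus-biases closed form", {
  expect_equal(n_parameters(network_spec()), 163)  # 6-9-9-1
  # the three-hidden-layer variant of the same family
  deep <- network_spec(hidden = c(9, 9, 9),
                       activations = c("tanh", "logistic", "tanh"),
                       output = "linear")
  expect_equal(n_parameters(deep), 253)
  # arbitrary layouts against the closed form computed independently
  for (h in list(c(3), c(4, 2), c(5, 5, 5, 5))) {
    sp <- network_spec(hidden = h, activations = rep("tanh", length(h)))
    sizes <- c(6, h, 1)
    expect_equal(n_parameters(sp),
                 sum(sizes[-1] * sizes[-length(sizes)]) + sum(sizes[-1]))
  }
})

test_that("initialization is seed-deterministic and zero weights give the
           output-scaler offset", {
  sp <- network_spec()
  expect_identical(build_network(sp, seed = 7), build_network(sp, seed = 7))
  expect_false(identical(build_network(sp, seed = 7),
                         build_network(sp, seed = 8)))

  net <- build_network(sp, seed = 1)
  net$W <- lapply(net$W, function(w) w * 0)
  net$b <- lapply(net$b, function(b) b * 0)
  net$trained <- TRUE
  net$y_center <- 1500
  net$y_half <- 400
  high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273),
                        label == 1)
  expect_equal(predict_yield(net, high), rep(1500, nrow(high)))
})

test_that("error metrics reproduce the printed per-record arithmetic", {
  m1 <- error_metrics(1447.519173, 1587.9)
  expect_equal(m1$error, 140.3808272)
  expect_equal(round(m1$pct_error, 1), 9.7)

  m23 <- error_metrics(1320.794994, 1317.00)
  expect_equal(m23$error, 3.794994)
  expect_equal(round(m23$pct_error, 2), 0.29)

  same <- error_metrics(1500, 1500)
  expect_equal(same$error, 0)
  expect_equal(same$pct_error, 0)
  expect_error(error_metrics(0, 10), "> 0")
})

test_that("the reference holdout table aggregates to the published means", {
  ref <- holdout_reference()
  expect_equal(nrow(ref), 28)
  agg <- aggregate_errors(error_metrics(ref$actual, ref$forecast))
  expect_equal(agg$mean_error, 133.53, tolerance = 1e-4)
  expect_equal(round(agg$mean_pct_error, 1), 8.7)
  expect_error(aggregate_errors(error_metrics(numeric(0), numeric(0))),
               "empty")
})

test_that("training interpolates tiny sets and respects degenerate targets", {
  high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273),
                        label == 1)
  two <- high[c(1, 10), ]
  net <- train_network(two, seed = 1)
  pred <- predict_yield(net, two)
  expect_equal(pred, two$yield_ug_ml, tolerance = 1e-2)

  const <- dplyr::mutate(high[1:5, ], yield_ug_ml = 1600)
  cnet <- train_network(const, seed = 1)
  expect_equal(predict_yield(cnet, const), rep(1600, 5), tolerance = 1e-6)

  expect_error(train_network(high[1, ]), "at least 2")
  syn <- dplyr::mutate(high, synthetic = TRUE, yield_ug_ml = NA_real_)
  expect_error(train_network(syn), "synthetic")
})

test_that("accepted Levenberg-Marquardt steps never increase the loss", {
  high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273),
                        label == 1)
  net <- train_network(high, seed = 2)
  expect_true(all(diff(net$sse_history) <= 0))
  expect_gt(length(net$sse_history), 1)
})

test_that("prediction is deterministic, finite, and guards its inputs", {
  high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273),
                        label == 1)
  net <- train_network(high, seed = 1)
  p1 <- predict_yield(net, high)
  expect_identical(p1, predict_yield(net, high))
  expect_true(all(is.finite(p1)))

  out_of_box <- dplyr::mutate(high[1, ], temperature_C = 60)
  expect_warning(predict_yield(net, out_of_box), "bounds")

  raw <- build_network(network_spec(), seed = 1)
  expect_error(predict_yield(raw, high), "not trained")
})

test_that("repeated holdout produces the 7x4 evaluation protocol", {
  high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273),
                        label == 1)
  rep1 <- repeated_holdout(high, seed = 5)
  expect_equal(nrow(rep1), 28)
  expect_equal(length(unique(rep1$repeat_id)), 7)
  expect_true(all(table(rep1$repeat_id) == 4))
  # actuals are drawn from the training table's yields
  expect_true(all(rep1$actual %in% high$yield_ug_ml))
  expect_identical(rep1, repeated_holdout(high, seed = 5))
  expect_error(repeated_holdout(high, n_train = 10, n_test = 4), "record count")
})

test_that("the regressor generalizes on a noiseless unimodal surface", {
  specs <- phellinus_factors()
  model <- response_model(specs, peaks = c(temperature_C = 31), noise_sd = 0)
  train_tbl <- simulate_yields(make_design(specs, steps_per_factor = 7),
                               model, seed = 2)
  net <- train_network(train_tbl, seed = 3)
  test_tbl <- simulate_yields(make_design(specs, steps_per_factor = 5),
                              model, seed = 4)
  agg <- aggregate_errors(
    error_metrics(test_tbl$yield_ug_ml, predict_yield(net, test_tbl)))
  expect_lt(agg$mean_pct_error, 10)
})
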