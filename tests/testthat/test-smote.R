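high_set <- function() {
  dplyr::filter(assign_labels(phellinus_experiments(), 1273), label == 1)
}

test_that("nearest neighbours match a brute-force all-pairs oracle", {
  minority <- high_set()
  g <- to_gradient_units(minority)
  for (i in c(1, 7, nrow(minority))) {
    d <- sqrt(colSums((t(g) - g[i, ])^2))
    d[i] <- Inf
    oracle <- order(d)[1:5]
    expect_equal(smote_neighbors(minority, i, k = 5), oracle)
  }
  expect_error(smote_neighbors(minority, 1, k = nrow(minority)), "smaller")
})

test_that("nearest neighbour picks duplicates and inner points first", {
  tbl <- mk_table(rep(NA_real_, 3))
  tbl$yield_ug_ml <- NULL
  tbl$inoculum_pct <- c(2, 2, 10)   # rows 1 and 2 identical
  tbl$yield_ug_ml <- 1
  expect_equal(smote_neighbors(tbl, 1, k = 1), 2)

  collinear <- mk_table(rep(1, 3))
  collinear$inoculum_pct <- c(2, 8, 14)
  expect_equal(smote_neighbors(collinear, 1, k = 1), 2)  # middle point
})

test_that("interpolation lies on the segment between parent records", {
  minority <- high_set()
  x <- minority[1, ]
  xn <- minority[5, ]

  expect_equal(smote_interpolate(x, xn, 0)[, names(x)[1:7]],
               x[, names(x)[1:7]])
  mid <- smote_interpolate(x, xn, 0.5)
  for (col in c("inoculum_pct", "fermentation_time", "initial_volume_ml")) {
    expect_equal(mid[[col]], (x[[col]] + xn[[col]]) / 2)
  }
  same <- smote_interpolate(x, x, 0.7)
  expect_equal(same$inoculum_pct, x$inoculum_pct)

  child <- smote_interpolate(x, xn, 0.3)
  expect_true(child$synthetic)
  expect_equal(child$label, 1)
  expect_true(is.na(child$yield_ug_ml))

  expect_error(smote_interpolate(x, xn, 1), "\\[0, 1\\)")
  expect_error(smote_interpolate(x, xn, -0.1), "\\[0, 1\\)")
})

test_that("oversampling raises the minority to the target and only appends", {
  lab <- assign_labels(phellinus_experiments(), 1273)
  aug <- smote_oversample(lab, k = 5, target = 30, seed = 11)

  expect_equal(nrow(aug), 61)
  expect_equal(sum(aug$synthetic), 10)
  cc <- class_counts(aug)
  expect_equal(cc$n_high, 30)
  expect_equal(cc$n_low, 31)

  # originals (and in particular the whole majority class) pass through
  # bitwise unchanged, in order
  expect_equal(aug[seq_len(nrow(lab)), ], lab)

  # every synthetic record is a coordinate-wise convex combination of two
  # original minority records: each factor lies within the minority range
  minority <- dplyr::filter(lab, label == 1)
  syn <- dplyr::filter(aug, synthetic)
  for (col in c("ph", "temperature_C", "initial_volume_ml",
                "rotation_speed_rpm", "inoculum_pct", "seed_age_d",
                "fermentation_time")) {
    expect_true(all(syn[[col]] >= min(minority[[col]])))
    expect_true(all(syn[[col]] <= max(minority[[col]])))
  }
  expect_true(all(is.na(syn$yield_ug_ml)))

  # target equal to the current minority count is a no-op
  expect_equal(smote_oversample(lab, target = 20, seed = 1), lab)
})

test_that("a two-point minority forces children onto the joining segment", {
  tbl <- mk_table(c(1, 1, 1, 1, 1, 1), labels = c(0, 0, 0, 0, 1, 1))
  tbl$inoculum_pct <- c(2, 4, 6, 8, 10, 14)
  aug <- smote_oversample(tbl, k = 1, target = 4, seed = 3)
  syn <- dplyr::filter(aug, synthetic)
  expect_equal(nrow(syn), 2)
  expect_true(all(syn$inoculum_pct >= 10 & syn$inoculum_pct <= 14))
})

test_that("oversampling is reproducible for a fixed seed", {
  lab <- assign_labels(phellinus_experiments(), 1273)
  expect_identical(smote_oversample(lab, seed = 42),
                   smote_oversample(lab, seed = 42))
  a <- smote_oversample(lab, seed = 1)
  b <- smote_oversample(lab, seed = 2)
  expect_false(identical(a, b))
})

test_that("degenerate class structures are refused", {
  lab <- assign_labels(phellinus_experiments(), 1273)
  single <- dplyr::mutate(lab, label = 0)
  expect_error(smote_oversample(single), "two classes")
  expect_error(smote_oversample(lab, target = 10), "target_minority_count")
  expect_error(smote_oversample(lab, k = 20, target = 30), "smaller")
})
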