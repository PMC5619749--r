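test_that("initial populations are uniform inside the bounds box", {
  params <- ga_params(pop_size = 50)
  pop <- ga_init_population(params, seed = 4)
  expect_equal(dim(pop), c(50, 6))
  for (j in seq_along(params$genes)) {
    expect_true(all(pop[, j] >= params$lower[j]))
    expect_true(all(pop[, j] <= params$upper[j]))
  }
  expect_identical(pop, ga_init_population(params, seed = 4))
})

test_that("fitness is the predicted yield of the decoded conditions", {
  high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273),
                        label == 1)
  net <- train_network(high, seed = 1)
  genes <- as.matrix(high[3, net$spec$factors])
  expect_equal(as.numeric(ga_fitness(genes, net)),
               predict_yield(net, high[3, ]))
  # decoding pins pH at its baseline
  decoded <- ga_decode(genes[1, ])
  expect_equal(decoded$ph, 6)
})

test_that("crossover and mutation behave at their parameter extremes", {
  p <- matrix(runif(12), nrow = 2)
  lo <- rep(0, 6)
  hi <- rep(2, 6)
  withr::with_seed(1, {
    same <- ga_crossover(p, p, rate = 1, lo, hi)
    expect_equal(same, p)  # blending identical parents changes nothing
  })
  withr::with_seed(1, {
    copied <- ga_crossover(p, p * 2, rate = 0, lo, hi)
    expect_equal(copied, p)  # rate 0 copies the first parent
  })
  withr::with_seed(1, {
    kids <- ga_crossover(p, p * 2, rate = 1, lo, hi)
    expect_true(all(kids >= 0 & kids <= 2))  # children are clipped to bounds
  })
  withr::with_seed(1, {
    unmutated <- ga_mutate(p, rate = 0, lower = rep(0, 6), upper = rep(1, 6))
    expect_identical(unmutated, p)
  })
  withr::with_seed(1, {
    mutated <- ga_mutate(p, rate = 1, lower = rep(5, 6), upper = rep(6, 6))
    expect_true(all(mutated >= 5 & mutated <= 6))
  })
})

test_that("selection under equal fitness is uniform", {
  draws <- withr::with_seed(2, ga_select(rep(10, 8), 8000))
  tab <- table(factor(draws, levels = 1:8))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("the GA finds the maximizing corner of a linear fitness", {
  specs <- phellinus_factors()
  free <- specs[!specs$fixed, ]
  coefs <- c(2, -1, 0.5, 1.5, -0.7, 1)
  net <- linear_network(coefs, specs)

  # corner-enumeration oracle over the 2^6 bound corners (scaled inputs
  # are monotone in the raw factors, so the optimum is a corner)
  corners <- expand.grid(lapply(seq_len(6),
                                function(j) c(free$lower[j], free$upper[j])))
  names(corners) <- free$factor
  corner_best <- max(predict_yield(net, tibble::as_tibble(corners)))

  res <- run_ga(net, ga_params(pop_size = 100, generations = 300,
                               stall = 60), seed = 1)
  expect_gt(res$best_yield, corner_best - 0.02 * abs(corner_best))
  # each gene should sit near the bound its coefficient points to
  for (j in seq_len(6)) {
    target <- if (coefs[j] > 0) free$upper[j] else free$lower[j]
    span <- free$upper[j] - free$lower[j]
    expect_lt(abs(res$best[j] - target), 0.15 * span)
  }
})

test_that("elitist best-so-far fitness is monotone and beats random search", {
  high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273),
                        label == 1)
  net <- train_network(high, seed = 1)
  res <- run_ga(net, ga_params(pop_size = 120, generations = 200, stall = 40),
                seed = 3)
  expect_true(all(diff(res$history) >= 0))
  # history[1] is the best of the random initial population
  expect_gte(res$best_yield, res$history[1])
  expect_equal(res$best_yield, max(res$history))
  expect_equal(res$best_yield,
               as.numeric(ga_fitness(matrix(res$best, nrow = 1,
                                            dimnames = list(NULL, names(res$best))),
                                     net)))
  # every reported gene respects its bounds
  ord <- match(names(res$best), res$params$genes)
  expect_true(all(res$best >= res$params$lower[ord]))
  expect_true(all(res$best <= res$params$upper[ord]))
})

test_that("a fixed seed reproduces the whole GA run bitwise", {
  high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273),
                        label == 1)
  net <- train_network(high, seed = 2)
  p <- ga_params(pop_size = 80, generations = 120, stall = 30)
  r1 <- run_ga(net, p, seed = 11)
  r2 <- run_ga(net, p, seed = 11)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$converged_at, r2$converged_at)
})

test_that("tidy and glance expose the optimum and its trajectory", {
  high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273),
                        label == 1)
  net <- train_network(high, seed = 1)
  res <- run_ga(net, ga_params(pop_size = 60, generations = 80, stall = 20),
                seed = 1)
  td <- tidy(res)
  expect_true(all(c("ph", "predicted_yield", "iterations") %in% names(td)))
  expect_equal(td$predicted_yield, res$best_yield)
  expect_equal(glance(res)$generations_run, res$generations_run)
})
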