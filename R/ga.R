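#' Genetic-algorithm parameters for condition optimization
#'
#' Defaults follow the study profile: population 300, a 6-gene real-coded
#' chromosome (one gene per free factor; pH stays pinned at its baseline),
#' a 1000-generation cap, crossover rate 1 (every child is a whole-
#' arithmetic blend of two parents), per-gene mutation rate 0.01 (uniform
#' resample within bounds), single-elite survival, and a stall stop after
#' 100 generations without improvement — which is why observed runs
#' converge within tens to hundreds of generations despite the cap.
#'
#' @param pop_size Population size.
#' @param generations Generation cap.
#' @param crossover_rate Probability a child is blended rather than copied.
#' @param mutation_rate Per-gene uniform-resample probability.
#' @param elitism Number of best individuals copied unchanged (>= 1 keeps
#'   the best-so-far fitness monotone).
#' @param stall Stop after this many generations without best-fitness
#'   improvement.
#' @param specs Factor specifications; the free factors become the genes
#'   and supply the per-gene bounds.
#' @return An object of class `ga_params`.
#' @export
ga_params <- function(pop_size = 300, generations = 1000,
                      crossover_rate = 1, mutation_rate = 0.01,
                      elitism = 1, stall = 100,
                      specs = phellinus_factors()) {
  validate_factor_specs(specs)
  stopifnot(pop_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism >= 0, elitism < pop_size, stall >= 1)
  free <- specs[!specs$fixed, ]
  if (nrow(free) == 0) stop("no free factors to optimize", call. = FALSE)
  structure(
    list(
      pop_size = as.integer(pop_size),
      generations = as.integer(generations),
      crossover_rate = crossover_rate,
      mutation_rate = mutation_rate,
      elitism = as.integer(elitism),
      stall = as.integer(stall),
      genes = free$factor,
      lower = free$lower,
      upper = free$upper,
      specs = specs
    ),
    class = "ga_params"
  )
}

#' Initialize a GA population uniformly within the bounds box
#'
#' @param params A [ga_params()] object.
#' @param seed Integer seed.
#' @return A `pop_size` x `n_genes` numeric matrix with gene names as
#'   columns.
#' @export
ga_init_population <- function(params, seed = 1) {
  ng <- length(params$genes)
  pop <- withr::with_seed(seed, {
    matrix(stats::runif(params$pop_size * ng), ncol = ng)
  })
  pop <- t(params$lower + t(pop) * (params$upper - params$lower))
  colnames(pop) <- params$genes
  pop
}

#' Decode chromosomes to full culture-condition records
#'
#' Fixed factors (pH) are filled with their baseline values, so a decoded
#' individual is a complete condition record.
#'
#' @param pop A matrix (or one row) of gene values named by factor.
#' @param specs Factor specifications.
#' @return A tibble with all factor columns in canonical order.
#' @export
ga_decode <- function(pop, specs = phellinus_factors()) {
  if (is.null(dim(pop))) pop <- matrix(pop, nrow = 1,
                                       dimnames = list(NULL, names(pop)))
  out <- tibble::as_tibble(pop)
  for (i in which(specs$fixed)) {
    out[[specs$factor[i]]] <- specs$baseline[i]
  }
  dplyr::select(out, dplyr::any_of(specs$factor))
}

#' GA fitness: predicted yield of the decoded conditions
#'
#' @param pop Matrix of individuals (genes in columns).
#' @param net A trained `yield_network`.
#' @return Numeric vector of predicted yields (μg/ml).
#' @export
ga_fitness <- function(pop, net) {
  if (is.null(dim(pop))) pop <- matrix(pop, nrow = 1,
                                       dimnames = list(NULL, names(pop)))
  f <- predict_yield(net, tibble::as_tibble(pop))
  if (any(!is.finite(f))) stop("non-finite fitness", call. = FALSE)
  f
}

# Roulette-wheel (fitness-proportional) parent index draw. Fitness is
# shifted so the worst individual gets (almost) zero weight; a flat
# landscape degenerates to uniform selection.
ga_select <- function(fitness, n_parents) {
  w <- fitness - min(fitness)
  if (sum(w) <= 0) w <- rep(1, length(fitness))
  w <- w + 1e-12 * max(w)
  sample.int(length(fitness), n_parents, replace = TRUE, prob = w)
}

# Blend (BLX-alpha) crossover: per gene the child is drawn uniformly from
# the interval spanned by its parents extended by alpha on each side, then
# clipped to the bounds box. alpha = 0 is the classic whole-arithmetic
# blend, which only ever contracts the population toward its mean; the
# 0.5 default restores enough outward exploration for fine convergence.
# With probability 1 - rate the child is a copy of p1.
ga_crossover <- function(p1, p2, rate, lower, upper, alpha = 0.5) {
  n <- nrow(p1)
  u <- matrix(stats::runif(length(p1), -alpha, 1 + alpha), nrow = n)
  blend <- u * p1 + (1 - u) * p2
  blend <- pmin(pmax(blend, matrix(lower, n, length(lower), byrow = TRUE)),
                matrix(upper, n, length(upper), byrow = TRUE))
  mask <- stats::runif(n) <= rate
  out <- p1
  out[mask, ] <- blend[mask, , drop = FALSE]
  out
}

# Uniform-resample mutation: each gene independently replaced by a uniform
# draw within its bounds with probability `rate`.
ga_mutate <- function(children, rate, lower, upper) {
  mask <- matrix(stats::runif(length(children)) < rate, nrow = nrow(children))
  if (any(mask)) {
    fresh <- t(lower + t(matrix(stats::runif(length(children)),
                                nrow = nrow(children))) * (upper - lower))
    children[mask] <- fresh[mask]
  }
  children
}

#' Search the condition box for the maximum predicted yield
#'
#' Real-coded elitist genetic algorithm with roulette-wheel selection,
#' blend (BLX-0.5) crossover and uniform-resample mutation, maximizing
#' the trained network's predicted yield over the factor bounds. Stops at
#' the generation cap or after `stall` generations without improvement.
#' With at least one elite the best-so-far fitness is non-decreasing and
#' the reported best always dominates the initial random population.
#'
#' @param net A trained `yield_network` whose input factors match the
#'   free factors of `params`.
#' @param params A [ga_params()] object.
#' @param seed Integer seed; fixes the whole run.
#' @return An object of class `ga_result`: `best` (named gene vector),
#'   `best_conditions` (decoded one-row tibble), `best_yield` (μg/ml),
#'   `converged_at` (generation of the last improvement),
#'   `generations_run`, and `history` (best-so-far fitness per
#'   generation, entry 1 = initial population).
#' @export
#' @examples
#' \donttest{
#' high <- dplyr::filter(assign_labels(phellinus_experiments(), 1273), label == 1)
#' net <- train_network(high, seed = 1)
#' res <- run_ga(net, ga_params(), seed = 1)
#' tidy(res)
#' }
run_ga <- function(net, params = ga_params(), seed = 1) {
  stopifnot(inherits(params, "ga_params"))
  if (!setequal(net$spec$factors, params$genes)) {
    stop("network inputs (", paste(net$spec$factors, collapse = ", "),
         ") do not match the GA genes", call. = FALSE)
  }
  withr::with_seed(seed, {
    ng <- length(params$genes)
    pop <- matrix(stats::runif(params$pop_size * ng), ncol = ng)
    pop <- t(params$lower + t(pop) * (params$upper - params$lower))
    colnames(pop) <- params$genes
    pop <- pop[, net$spec$factors, drop = FALSE]
    lower <- params$lower[match(net$spec$factors, params$genes)]
    upper <- params$upper[match(net$spec$factors, params$genes)]

    fitness <- ga_fitness(pop, net)
    best_i <- which.max(fitness)
    best <- pop[best_i, ]
    best_fit <- fitness[best_i]
    history <- best_fit
    converged_at <- 0L
    gen <- 0L
    while (gen < params$generations && gen - converged_at < params$stall) {
      gen <- gen + 1L
      n_children <- params$pop_size - params$elitism
      i1 <- ga_select(fitness, n_children)
      i2 <- ga_select(fitness, n_children)
      children <- ga_crossover(pop[i1, , drop = FALSE],
                               pop[i2, , drop = FALSE],
                               params$crossover_rate, lower, upper)
      children <- ga_mutate(children, params$mutation_rate, lower, upper)
      elite_idx <- order(fitness, decreasing = TRUE)[seq_len(params$elitism)]
      pop <- rbind(pop[elite_idx, , drop = FALSE], children)
      fitness <- ga_fitness(pop, net)
      gen_best <- which.max(fitness)
      if (fitness[gen_best] > best_fit) {
        best_fit <- fitness[gen_best]
        best <- pop[gen_best, ]
        converged_at <- gen
      }
      history <- c(history, best_fit)
    }
    structure(
      list(
        best = best,
        best_conditions = ga_decode(best, params$specs),
        best_yield = best_fit,
        converged_at = converged_at,
        generations_run = gen,
        history = history,
        seed = seed,
        params = params
      ),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA optimum after", x$generations_run, "generations",
      "(last improvement at", paste0(x$converged_at, "):\n"))
  print(x$best_conditions)
  cat("predicted yield:", round(x$best_yield, 1), "ug/ml\n")
  invisible(x)
}

#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) {
  dplyr::mutate(x$best_conditions,
                predicted_yield = x$best_yield,
                iterations = x$converged_at)
}

#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    best_yield = x$best_yield,
    converged_at = x$converged_at,
    generations_run = x$generations_run,
    seed = x$seed
  )
}
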