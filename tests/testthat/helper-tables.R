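# Minimal culture table at baseline conditions with chosen yields/groups.
mk_table <- function(yields, groups = rep("ph", length(yields)),
                     labels = NA_real_) {
  specs <- phellinus_factors()
  base <- stats::setNames(as.list(specs$baseline), specs$factor)
  tbl <- tibble::as_tibble(base)[rep(1, length(yields)), ]
  tbl$yield_ug_ml <- yields
  tbl$group <- groups
  tbl$label <- rep_len(labels, length(yields))
  tbl$synthetic <- FALSE
  tbl
}

# Random grouped table for boundary property tests: each group's yields are
# drawn so the groups overlap and a feasible boundary usually exists.
random_grouped_table <- function(seed) {
  withr::with_seed(seed, {
    n_groups <- sample(2:4, 1)
    rows <- purrr::map_dfr(seq_len(n_groups), function(g) {
      n <- sample(3:6, 1)
      mk_table(stats::runif(n, 0, 100), groups = paste0("g", g))
    })
    rows
  })
}

# Hand-built network computing a fixed linear function of its scaled
# inputs: output = sum(coef * x_scaled) (identity activations). Used as a
# transparent GA fitness with a known optimum at a corner of the box.
linear_network <- function(coefs, specs = phellinus_factors(),
                           y_center = 0, y_half = 1) {
  free <- specs$factor[!specs$fixed]
  spec <- network_spec(factors = free, specs = specs,
                       hidden = length(coefs), activations = "linear",
                       output = "linear")
  net <- build_network(spec, seed = 1)
  net$W[[1]] <- diag(length(coefs))
  net$b[[1]] <- rep(0, length(coefs))
  net$W[[2]] <- matrix(coefs, nrow = 1)
  net$b[[2]] <- 0
  net$trained <- TRUE
  net$y_center <- y_center
  net$y_half <- y_half
  net$y_gain <- 1
  net
}
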