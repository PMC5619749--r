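#' Unimodal multiplicative response model for synthetic experiments
#'
#' A generative stand-in for the fermentation response surface: each free
#' factor contributes a unimodal effect curve
#' `floor + (1 - floor) * exp(-((x - peak) / width)^2)` in (0, 1], the
#' factor effects multiply, and a global `scale` (μg/ml) sets the peak
#' yield. Noise is multiplicative log-normal. By construction the optimum
#' is the vector of per-factor peaks with noiseless yield exactly `scale`
#' — a closed-form oracle for optimizer-recovery tests. The family mimics
#' the qualitative shape of real single-factor series (a sharp pH peak, a
#' broad fermentation-time plateau) but not factor interactions or
#' heteroscedastic measurement error.
#'
#' @param specs Factor specifications; free factors get effect curves.
#' @param peaks Named vector of peak locations; defaults to each factor's
#'   baseline.
#' @param widths Named vector of curve widths (same units as the factor);
#'   defaults to 2 gradient steps.
#' @param floors Named vector of effect floors in (0, 1); default 0.15.
#' @param scale Peak yield in μg/ml (default 2000).
#' @param noise_sd Log-normal sdlog; the default 0.1 gives roughly a 10%
#'   coefficient of variation, the error scale seen in holdout forecasts.
#' @return An object of class `response_model`.
#' @export
response_model <- function(specs = phellinus_factors(), peaks = NULL,
                           widths = NULL, floors = NULL,
                           scale = 2000, noise_sd = 0.1) {
  validate_factor_specs(specs)
  free <- specs[!specs$fixed, ]
  fill <- function(x, default) {
    out <- stats::setNames(rep_len(default, nrow(free)), free$factor)
    if (!is.null(x)) {
      unknown <- setdiff(names(x), free$factor)
      if (length(unknown) > 0) {
        stop("unknown factor(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      out[names(x)] <- x
    }
    out
  }
  peaks <- fill(peaks, free$baseline)
  widths <- fill(widths, 2 * free$gradient_step)
  floors <- fill(floors, 0.15)
  stopifnot(all(peaks >= free$lower), all(peaks <= free$upper),
            all(widths > 0), all(floors > 0), all(floors < 1),
            scale > 0, noise_sd >= 0)
  structure(
    list(specs = specs, factors = free$factor, peaks = peaks,
         widths = widths, floors = floors, scale = scale,
         noise_sd = noise_sd),
    class = "response_model"
  )
}

# Noiseless mean response at the given condition rows.
response_mean <- function(model, data) {
  eff <- rep(1, nrow(data))
  for (f in model$factors) {
    x <- data[[f]]
    curve <- model$floors[[f]] + (1 - model$floors[[f]]) *
      exp(-((x - model$peaks[[f]]) / model$widths[[f]])^2)
    eff <- eff * curve
  }
  model$scale * eff
}

#' Build a single-factor experiment design
#'
#' One series per free factor: that factor sweeps an evenly spaced
#' gradient across its bounds while every other factor sits at its
#' baseline. This is the structure of the real experiment campaign, where
#' each series probes one culture factor at a time.
#'
#' @param specs Factor specifications.
#' @param steps_per_factor Number of gradient levels per series.
#' @return A culture table without yields; `group` names the varied
#'   factor and `synthetic` is `FALSE` (the design rows are conditions to
#'   run, not interpolated samples).
#' @export
#' @examples
#' make_design(steps_per_factor = 8)
make_design <- function(specs = phellinus_factors(), steps_per_factor = 8) {
  validate_factor_specs(specs)
  stopifnot(steps_per_factor >= 2)
  free <- specs[!specs$fixed, ]
  baseline <- stats::setNames(specs$baseline, specs$factor)
  purrr::map_dfr(seq_len(nrow(free)), function(i) {
    levels <- seq(free$lower[i], free$upper[i], length.out = steps_per_factor)
    row <- tibble::as_tibble(as.list(baseline))
    out <- row[rep(1, steps_per_factor), ]
    out[[free$factor[i]]] <- levels
    out$yield_ug_ml <- NA_real_
    out$group <- free$factor[i]
    out$label <- NA_real_
    out$synthetic <- FALSE
    out
  })
}

#' Simulate yields for a design under a response model
#'
#' @param design A culture table of conditions (e.g. from
#'   [make_design()]).
#' @param model A [response_model()].
#' @param seed Integer seed for the multiplicative noise.
#' @return The design with `yield_ug_ml` filled in; reproducible for a
#'   fixed seed.
#' @export
simulate_yields <- function(design, model, seed = 1) {
  stopifnot(inherits(model, "response_model"))
  validate_culture_table(design)
  mu <- response_mean(model, design)
  noise <- if (model$noise_sd > 0) {
    withr::with_seed(seed, stats::rlnorm(nrow(design), 0, model$noise_sd))
  } else {
    rep(1, nrow(design))
  }
  dplyr::mutate(design, yield_ug_ml = mu * noise)
}

#' Closed-form optimum of a response model
#'
#' @param model A [response_model()].
#' @return A one-row tibble of the optimal conditions (fixed factors at
#'   baseline) with the noiseless peak yield `yield_ug_ml = scale`.
#' @export
true_optimum <- function(model) {
  specs <- model$specs
  cond <- stats::setNames(as.list(specs$baseline), specs$factor)
  for (f in model$factors) cond[[f]] <- model$peaks[[f]]
  out <- tibble::as_tibble(cond)
  out$yield_ug_ml <- model$scale
  out
}
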