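#' Culture-condition experiment records
#'
#' The packaged single-factor fermentation experiment table for flavonoid
#' production by liquid-fermented *Phellinus*. Each record holds seven
#' culture-condition factors, the measured flavonoid yield (μg/ml), the
#' single-factor series (`group`) it belongs to, and the high/low-yield
#' class label under the 1273 μg/ml boundary. All 51 records are real
#' (`synthetic = FALSE`) wet-lab measurements; pipeline labels are normally
#' recomputed from a boundary via [assign_labels()] — the shipped `label`
#' column is a reference, not an input.
#'
#' @return A tibble with 51 rows and the columns
#'   `ph`, `temperature_C`, `initial_volume_ml`, `rotation_speed_rpm`,
#'   `inoculum_pct`, `seed_age_d`, `fermentation_time`, `yield_ug_ml`,
#'   `group`, `label`, `synthetic`.
#' @export
#' @examples
#' tbl <- phellinus_experiments()
#' dplyr::count(tbl, group)
phellinus_experiments <- function() {
  path <- system.file("extdata", "phellinus_experiments.csv",
                      package = "fermopt", mustWork = TRUE)
  read_culture_csv(path)
}

#' Reference held-out forecast table
#'
#' The 28 (actual, forecast) yield pairs from the original repeated-holdout
#' evaluation of the yield regressor (7 repeats of a 16-train / 4-test
#' split over the 20 high-yield records). Used to check the error-metric
#' arithmetic: `mean(|actual - forecast|)` is 133.53 μg/ml and the mean
#' percentage error is 8.7%.
#'
#' @return A tibble with columns `actual` and `forecast` (μg/ml).
#' @export
holdout_reference <- function() {
  path <- system.file("extdata", "holdout_reference.csv",
                      package = "fermopt", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
}

#' Factor specifications for the culture-condition space
#'
#' One row per culture factor: box bounds, the baseline value held fixed in
#' the other factors' single-factor series, the gradient step (the increment
#' between adjacent experiments in that factor's series, used as the
#' distance unit for SMOTE neighbour search), and whether the factor is
#' pinned during optimization. pH is `fixed` because every high-yield
#' record sits at pH 6 and the optimizer's chromosome has six genes.
#'
#' @return A tibble with columns `factor`, `lower`, `upper`, `baseline`,
#'   `gradient_step`, `fixed`.
#' @export
#' @examples
#' phellinus_factors()
phellinus_factors <- function() {
  specs <- tibble::tribble(
    ~factor,              ~lower, ~upper, ~baseline, ~gradient_step, ~fixed,
    "ph",                      1,     14,         6,              1,   TRUE,
    "temperature_C",          25,     40,        28,              5,  FALSE,
    "initial_volume_ml",      40,    140,       100,             20,  FALSE,
    "rotation_speed_rpm",    140,    150,       150,             10,  FALSE,
    "inoculum_pct",            2,     16,        10,              2,  FALSE,
    "seed_age_d",              4,     10,         8,              1,  FALSE,
    "fermentation_time",       1,     12,         8,              1,  FALSE
  )
  validate_factor_specs(specs)
  specs
}

# Canonical column orders for the CSV dialect.
factor_cols <- function() {
  c("ph", "temperature_C", "initial_volume_ml", "rotation_speed_rpm",
    "inoculum_pct", "seed_age_d", "fermentation_time")
}

culture_cols <- function() {
  c(factor_cols(), "yield_ug_ml", "group", "label", "synthetic")
}

validate_factor_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  needed <- c("factor", "lower", "upper", "baseline", "gradient_step", "fixed")
  missing <- setdiff(needed, names(specs))
  if (length(missing) > 0) {
    stop("factor specs missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(specs$lower >= specs$upper)) {
    stop("factor specs must have lower < upper", call. = FALSE)
  }
  if (any(specs$gradient_step <= 0)) {
    stop("gradient_step must be > 0", call. = FALSE)
  }
  if (any(specs$baseline < specs$lower | specs$baseline > specs$upper)) {
    stop("baseline must lie within [lower, upper]", call. = FALSE)
  }
  invisible(specs)
}

validate_culture_table <- function(data, require_yield = FALSE) {
  missing <- setdiff(factor_cols(), names(data))
  if (length(missing) > 0) {
    stop("culture table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ph <- data$ph
  if (any(!is.na(ph) & (ph < 1 | ph > 14))) {
    stop("ph must lie in [1, 14]", call. = FALSE)
  }
  for (col in setdiff(factor_cols(), "ph")) {
    v <- data[[col]]
    if (any(!is.na(v) & v <= 0)) {
      stop("factor '", col, "' must be strictly positive", call. = FALSE)
    }
  }
  if ("yield_ug_ml" %in% names(data)) {
    y <- data$yield_ug_ml
    if (any(!is.na(y) & y < 0)) stop("yield must be >= 0", call. = FALSE)
    if ("synthetic" %in% names(data) &&
        any(data$synthetic & !is.na(y))) {
      stop("synthetic records must not carry a yield", call. = FALSE)
    }
  }
  if (require_yield &&
      (!"yield_ug_ml" %in% names(data) || anyNA(data$yield_ug_ml))) {
    stop("every record must have a yield for this operation", call. = FALSE)
  }
  invisible(data)
}

#' Read a culture-condition experiment table from CSV
#'
#' The dialect is comma-separated UTF-8 with a required header; an empty
#' cell is an absent value. The seven factor columns are required; yield,
#' group, label and synthetic are optional and filled with `NA`/`FALSE`
#' when missing.
#'
#' @param path Path to a CSV file.
#' @return A tibble in the canonical column order (see
#'   [phellinus_experiments()]).
#' @export
read_culture_csv <- function(path) {
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      group = readr::col_character(),
      synthetic = readr::col_logical(),
      .default = readr::col_double()
    ),
    na = c("", "NA")
  ))
  missing <- setdiff(factor_cols(), names(raw))
  if (length(missing) > 0) {
    stop("CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(c(factor_cols(), "yield_ug_ml", "label"), names(raw))) {
    if (!is.numeric(raw[[col]])) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    # problems() rows count the header line; report the data row
    stop("parse error at row ", probs$row[1] - 1, ", column '",
         names(raw)[probs$col[1]], "': expected ", probs$expected[1],
         call. = FALSE)
  }
  if (!"yield_ug_ml" %in% names(raw)) raw$yield_ug_ml <- NA_real_
  if (!"group" %in% names(raw)) raw$group <- NA_character_
  if (!"label" %in% names(raw)) raw$label <- NA_real_
  if (!"synthetic" %in% names(raw)) raw$synthetic <- FALSE
  raw$synthetic[is.na(raw$synthetic)] <- FALSE
  out <- dplyr::select(raw, dplyr::all_of(culture_cols()))
  validate_culture_table(out)
  out
}

#' Write a culture-condition experiment table to CSV
#'
#' Inverse of [read_culture_csv()]: writing then re-reading reproduces the
#' table field for field. Absent yields and labels are written as empty
#' cells.
#'
#' @param data A culture table (tibble or data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_culture_csv <- function(data, path) {
  validate_culture_table(data)
  keep <- intersect(culture_cols(), names(data))
  readr::write_csv(dplyr::select(data, dplyr::all_of(keep)), path, na = "")
  invisible(path)
}

#' Convert condition records to gradient units
#'
#' Divides each factor column by its gradient step so that one experimental
#' increment in any factor counts as one unit of distance. This is the
#' metric space in which SMOTE nearest neighbours are found: a volume
#' change of 20 ml and a pH change of 1 are both distance 1.
#'
#' @param data A culture table.
#' @param specs Factor specifications, default [phellinus_factors()].
#' @param factors Which factors to convert; defaults to all seven.
#' @return A numeric matrix with one row per record and one column per
#'   factor, in gradient units.
#' @export
#' @examples
#' to_gradient_units(phellinus_experiments()[1:3, ])
to_gradient_units <- function(data, specs = phellinus_factors(),
                              factors = factor_cols()) {
  validate_factor_specs(specs)
  unknown <- setdiff(factors, specs$factor)
  if (length(unknown) > 0) {
    stop("unknown factor(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(factors, names(data))
  if (length(missing) > 0) {
    stop("culture table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  steps <- specs$gradient_step[match(factors, specs$factor)]
  m <- as.matrix(dplyr::select(as.data.frame(data), dplyr::all_of(factors)))
  sweep(m, 2, steps, "/")
}
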