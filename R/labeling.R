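#' Median yield boundary
#'
#' The simplest high/low-yield split: the sample median of the measured
#' yields. For an even record count the lower median is returned, so the
#' threshold is always an observed yield. A median boundary balances the
#' two classes exactly but can leave a whole single-factor series on one
#' side (every seed-age record is high-yield under it), which removes that
#' factor from the classifier's decision surface — the motivation for
#' [per_group_boundary()].
#'
#' @param data A culture table in which every record has a yield.
#' @return The threshold in μg/ml (a scalar).
#' @export
median_boundary <- function(data) {
  validate_culture_table(data, require_yield = TRUE)
  y <- data$yield_ug_ml
  if (length(y) == 0) stop("cannot take the median of an empty table", call. = FALSE)
  sort(y)[ceiling(length(y) / 2)]  # lower median for even n
}

#' Per-group balanced yield boundary
#'
#' Chooses a threshold that splits *every* single-factor series into both
#' classes, so each factor stays informative, while keeping the overall
#' high/low counts as close as possible. A threshold `t` is feasible when
#' every group has a record with yield >= t and one with yield < t, i.e.
#' `t` lies in the open-closed interval
#' (max over groups of the group minimum, min over groups of the group
#' maximum]. Among the observed yields in that interval the one minimizing
#' `|n_high - n_low|` is returned, ties broken by the smallest threshold.
#'
#' @param data A culture table with `group` set and all yields present.
#' @return A one-row tibble: `threshold`, `interval_lower`,
#'   `interval_upper` (the feasible interval endpoints), `n_high`, `n_low`.
#' @export
#' @examples
#' per_group_boundary(phellinus_experiments())
per_group_boundary <- function(data) {
  validate_culture_table(data, require_yield = TRUE)
  if (anyNA(data$group)) stop("every record needs a group", call. = FALSE)
  per_group <- dplyr::summarise(
    dplyr::group_by(data, .data$group),
    gmin = min(.data$yield_ug_ml),
    gmax = max(.data$yield_ug_ml),
    ndistinct = dplyr::n_distinct(.data$yield_ug_ml),
    .groups = "drop"
  )
  if (any(per_group$ndistinct < 2)) {
    stop("group(s) with fewer than 2 distinct yields: ",
         paste(per_group$group[per_group$ndistinct < 2], collapse = ", "),
         call. = FALSE)
  }
  lo <- max(per_group$gmin)
  hi <- min(per_group$gmax)
  if (hi <= lo) {
    blocking_hi <- per_group$group[which.min(per_group$gmax)]
    blocking_lo <- per_group$group[which.max(per_group$gmin)]
    stop("no feasible boundary: group '", blocking_hi,
         "' tops out at ", signif(hi, 7), " but group '", blocking_lo,
         "' starts at ", signif(lo, 7), call. = FALSE)
  }
  y <- data$yield_ug_ml
  candidates <- sort(unique(y[y > lo & y <= hi]))
  imbalance <- vapply(candidates, function(t) {
    n1 <- sum(y >= t)
    abs((length(y) - n1) - n1)
  }, numeric(1))
  t <- candidates[which.min(imbalance)]  # which.min takes the first = smallest t
  tibble::tibble(
    threshold = t,
    interval_lower = lo,
    interval_upper = hi,
    n_high = sum(y >= t),
    n_low = sum(y < t)
  )
}

#' Assign high/low-yield class labels
#'
#' Labels a record high-yield (1) when its yield is greater than or equal
#' to the threshold, low-yield (0) otherwise. The >= convention is fixed by
#' the packaged data: at the 1273 μg/ml boundary the 1273.594991 record is
#' high and the 1272.384 record is low.
#'
#' @param data A culture table with yields.
#' @param threshold Yield boundary in μg/ml.
#' @return The table with its `label` column set; row order preserved.
#' @export
assign_labels <- function(data, threshold) {
  validate_culture_table(data, require_yield = TRUE)
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  dplyr::mutate(data, label = as.numeric(.data$yield_ug_ml >= threshold))
}

#' Class counts and imbalance ratio
#'
#' @param data A labelled culture table.
#' @return A one-row tibble: `n_low` (class 0), `n_high` (class 1), and
#'   `imbalance` = n_low / n_high (`NA` when a class is empty).
#' @export
class_counts <- function(data) {
  lab <- if ("label" %in% names(data)) data$label else numeric(0)
  n0 <- sum(lab == 0, na.rm = TRUE)
  n1 <- sum(lab == 1, na.rm = TRUE)
  tibble::tibble(
    n_low = n0,
    n_high = n1,
    imbalance = ifelse(n1 > 0 && n0 > 0, n0 / n1, NA_real_)
  )
}
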