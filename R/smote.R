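#' Nearest minority-class neighbours in gradient units
#'
#' Euclidean distances are taken over the factor columns after conversion
#' to gradient units ([to_gradient_units()]), so one experimental step in
#' any factor counts equally. The query record is excluded from its own
#' neighbour set by row index; ties are broken by table order.
#'
#' @param minority A culture table of minority-class records.
#' @param i Row index of the query record within `minority`.
#' @param k Number of neighbours; must be smaller than the minority size.
#' @param specs Factor specifications.
#' @return Integer row indices of the `k` nearest neighbours, closest first.
#' @export
smote_neighbors <- function(minority, i, k, specs = phellinus_factors()) {
  n <- nrow(minority)
  if (k >= n) stop("k must be smaller than the minority class size", call. = FALSE)
  stopifnot(i >= 1, i <= n)
  g <- to_gradient_units(minority, specs)
  d <- sqrt(colSums((t(g) - g[i, ])^2))
  d[i] <- Inf
  order(d)[seq_len(k)]  # order() is stable: ties fall back to table order
}

#' Interpolate a synthetic minority record
#'
#' Places a new record on the segment between a minority record `x` and a
#' neighbour `xn`: each factor becomes `x + u * (xn - x)` with
#' `u` drawn from \[0, 1). The child is flagged synthetic, labelled
#' high-yield, and carries no yield — yields of interpolated conditions
#' were never measured, so synthetic records are excluded from regression
#' training by construction.
#'
#' @param x,xn One-row culture tables (a minority record and a neighbour).
#' @param u Interpolation coefficient in \[0, 1).
#' @return A one-row culture table.
#' @export
smote_interpolate <- function(x, xn, u) {
  if (!is.numeric(u) || length(u) != 1 || u < 0 || u >= 1) {
    stop("u must lie in [0, 1)", call. = FALSE)
  }
  out <- x
  for (col in factor_cols()) {
    out[[col]] <- x[[col]] + u * (xn[[col]] - x[[col]])
  }
  out$yield_ug_ml <- NA_real_
  out$label <- 1
  out$synthetic <- TRUE
  if ("group" %in% names(out)) out$group <- NA_character_
  out
}

#' Oversample the minority (high-yield) class by SMOTE
#'
#' Raises the minority class to `target` records by appending synthetic
#' interpolations: each selected minority record is paired with one of its
#' `k` nearest minority neighbours (gradient-unit Euclidean distance) and a
#' child is placed uniformly at random on the joining segment. When the
#' deficit is smaller than the minority size, the parents are sampled
#' uniformly without replacement; when it exceeds it, parents cycle.
#' Majority records pass through untouched and originals keep their order,
#' with synthetic records appended after them.
#'
#' @param data A labelled culture table with exactly two classes, minority
#'   class 1.
#' @param k Neighbour count (default 5, the canonical SMOTE choice).
#' @param target Desired minority count (default 30).
#' @param seed Integer seed for parent, neighbour and offset draws.
#' @param specs Factor specifications.
#' @return The augmented table.
#' @export
#' @examples
#' labelled <- assign_labels(phellinus_experiments(), 1273)
#' aug <- smote_oversample(labelled, k = 5, target = 30, seed = 1)
#' class_counts(aug)
smote_oversample <- function(data, k = 5, target = 30, seed = 1,
                             specs = phellinus_factors()) {
  if (!"label" %in% names(data) || anyNA(data$label)) {
    stop("table must be fully labelled", call. = FALSE)
  }
  classes <- sort(unique(data$label))
  if (!identical(classes, c(0, 1))) {
    stop("exactly two classes (0 and 1) are required", call. = FALSE)
  }
  minority <- dplyr::filter(data, .data$label == 1)
  n_min <- nrow(minority)
  if (target < n_min) {
    stop("target_minority_count must be >= current minority count", call. = FALSE)
  }
  deficit <- target - n_min
  if (deficit == 0) return(data)
  if (k >= n_min) stop("k must be smaller than the minority class size", call. = FALSE)

  synthetic <- withr::with_seed(seed, {
    parents <- if (deficit <= n_min) {
      sample.int(n_min, deficit)
    } else {
      rep_len(sample.int(n_min), deficit)
    }
    purrr::map(parents, function(i) {
      nb <- smote_neighbors(minority, i, k, specs)
      xn_idx <- nb[sample.int(k, 1)]
      smote_interpolate(minority[i, ], minority[xn_idx, ], stats::runif(1))
    })
  })
  dplyr::bind_rows(data, synthetic)
}
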