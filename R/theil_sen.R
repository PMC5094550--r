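# Robust Theil-Sen line fitting and the overlapping equal-count binning plan
# that underlies the segmented RT <-> iRT regression.

new_linear_fit <- function(slope, intercept) {
  structure(list(slope = slope, intercept = intercept), class = "linear_fit")
}

# internal workhorse on bare vectors; public surface takes an anchor table
ts_fit <- function(x, y) {
  n <- length(x)
  if (n < 2L) {
    irt_error("Theil-Sen fit needs at least 2 points", "irtnorm_degenerate_input")
  }
  if (length(unique(x)) < 2L) {
    irt_error("Theil-Sen fit needs at least one pair with distinct x (all x identical)",
              "irtnorm_degenerate_input")
  }
  if (n <= 2000L) {
    dx <- outer(x, x, "-")
    dy <- outer(y, y, "-")
    keep <- upper.tri(dx) & dx != 0
    slopes <- dy[keep] / dx[keep]
  } else {
    # avoid the n x n matrices; accumulate pairwise slopes row by row
    slopes <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
      js <- (i + 1L):n
      dxi <- x[js] - x[i]
      ok <- dxi != 0
      slopes[[i]] <- (y[js][ok] - y[i]) / dxi[ok]
    }
    slopes <- unlist(slopes, use.names = FALSE)
  }
  slope <- stats::median(slopes)
  intercept <- stats::median(y - slope * x)
  new_linear_fit(slope, intercept)
}

#' Robust Theil-Sen line fit
#'
#' Fits a straight line as the median of all pairwise slopes
#' \eqn{(y_j - y_i)/(x_j - x_i)} over point pairs with distinct x; the
#' intercept is the median of the per-point residual intercepts
#' \eqn{y_i - \hat{a} x_i}. The estimator tolerates up to roughly 29% gross
#' outliers, which is what makes it suitable for anchor sets containing
#' false-discovery identifications.
#'
#' @param anchors data.frame with numeric columns `x` and `y` (one anchor
#'   point per row).
#' @return An object of class `linear_fit` with elements `slope` and
#'   `intercept`.
#' @examples
#' fit <- fit_theil_sen(data.frame(x = c(0, 1, 2), y = c(0, 1, 10)))
#' fit$slope  # 5: median of pairwise slopes {1, 5, 9}
#' @export
fit_theil_sen <- function(anchors) {
  check_columns(anchors, c("x", "y"), "anchor table")
  check_finite_numeric(anchors$x, "anchor x")
  check_finite_numeric(anchors$y, "anchor y")
  ts_fit(anchors$x, anchors$y)
}

#' @export
predict.linear_fit <- function(object, x, ...) {
  check_finite_numeric(x, "x")
  object$slope * x + object$intercept
}

#' Plan overlapping equal-count bins over sorted anchor points
#'
#' Bin size is `max(round(n/40), 20)` points (round half up); bins start every
#' `floor(bin_size/2)` indices so that consecutive bins overlap by half, and
#' the final bin is right-aligned to end exactly at `n`, so every point falls
#' in at least one bin. For n = 400 this yields 39 bins of 20 points.
#'
#' @param n total number of anchor points (positive integer).
#' @param bin_size optional override of the `max(round(n/40), 20)` default
#'   (used by the extraction-window model, which bins its reference points
#'   with size `round(m/10)`).
#' @return An object of class `binning_plan`: list with `bin_size`, `stride`,
#'   and `bins`, a data.frame of 1-based inclusive `start`/`end` indices.
#' @export
plan_bins <- function(n, bin_size = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n)) {
    irt_error("n must be a single positive integer", "irtnorm_input_error")
  }
  n <- as.integer(n)
  if (is.null(bin_size)) {
    bin_size <- as.integer(max(round_half_up(n / 40), 20L))
  } else {
    bin_size <- as.integer(bin_size)
    if (bin_size < 2L) irt_error("bin_size must be >= 2", "irtnorm_input_error")
  }
  if (n < bin_size) {
    irt_error(sprintf(
      "n = %d is below the bin size %d; a global (fallback) fit is required",
      n, bin_size), "irtnorm_fallback_required")
  }
  stride <- max(1L, bin_size %/% 2L)
  starts <- seq.int(0L, n - bin_size, by = stride)
  if (starts[length(starts)] != n - bin_size) {
    starts <- c(starts, n - bin_size)
  }
  structure(list(
    bin_size = bin_size,
    stride = stride,
    bins = data.frame(start = starts + 1L, end = starts + bin_size)
  ), class = "binning_plan")
}
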