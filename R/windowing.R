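# Dynamic extraction-window width estimation: sliding-bin summaries of anchor
# residuals and chromatographic peak widths, fed into a segmented regression
# over the iRT axis.

new_window_model <- function(inner, scale, fixed_width, m) {
  structure(list(inner = inner, scale = scale, fixed_width = fixed_width, m = m),
            class = "window_model")
}

#' Summarize window observations in sliding bins along the iRT axis
#'
#' Observations are sorted by iRT and grouped in bins of
#' `s = max(2, round(n/log2(n)))` points sliding one index at a time (overlap
#' s - 1), yielding `n - s + 1` bins. Per bin: reference x is the mean iRT,
#' `w` the median peak width, `q` the 75th percentile of the absolute
#' difference between measured and predicted RT (linear interpolation between
#' order statistics), and the reference y is `(w + q) * 0.5`.
#'
#' @param obs data.frame with columns `irt`, `rt_measured`, `rt_predicted`
#'   (minutes) and `peak_width` (minutes, > 0).
#' @param min_obs minimum number of observations (default 30); below it a
#'   fixed window must be used instead.
#' @return data.frame of bin summaries with columns `x_ref`, `w`, `q`, `y_ref`.
#' @export
summarize_window_bins <- function(obs, min_obs = 30L) {
  check_columns(obs, c("irt", "rt_measured", "rt_predicted", "peak_width"),
                "window observations")
  for (col in c("irt", "rt_measured", "rt_predicted", "peak_width")) {
    check_finite_numeric(obs[[col]], col)
  }
  if (any(obs$peak_width <= 0)) {
    irt_error("peak_width must be > 0", "irtnorm_input_error")
  }
  n <- nrow(obs)
  if (n < min_obs) {
    irt_error(sprintf("only %d window observations (< %d); apply a fixed window",
                      n, min_obs), "irtnorm_fixed_window_required")
  }
  ord <- order(obs$irt)
  irt <- obs$irt[ord]
  res <- abs(obs$rt_measured - obs$rt_predicted)[ord]
  pw <- obs$peak_width[ord]
  s <- max(2L, as.integer(round_half_up(n / log2(n))))
  n_bins <- n - s + 1L
  x_ref <- w <- q <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    idx <- i:(i + s - 1L)
    x_ref[i] <- mean(irt[idx])
    w[i] <- stats::median(pw[idx])
    q[i] <- stats::quantile(res[idx], 0.75, names = FALSE, type = 7)
  }
  data.frame(x_ref = x_ref, w = w, q = q, y_ref = (w + q) * 0.5)
}

#' Fit the extraction-window model from bin summaries
#'
#' The (x_ref, y_ref) reference points are fed into the segmented regression
#' with bin size `max(2, round(m/10))`, where m is the number of reference
#' points. The emitted window width is `scale` (default 2) times the inner
#' regression's prediction.
#'
#' @param summaries data.frame from [summarize_window_bins()].
#' @param scale multiplier on the inner prediction (default 2).
#' @param fixed_width optional fixed full window width (minutes) recorded for
#'   fallback use.
#' @return A `window_model`.
#' @export
fit_window_model <- function(summaries, scale = 2, fixed_width = NULL) {
  check_columns(summaries, c("x_ref", "y_ref"), "window bin summaries")
  if (scale <= 0) irt_error("scale must be > 0", "irtnorm_input_error")
  m <- nrow(summaries)
  if (m < 2L) {
    irt_error("need >= 2 window bin summaries", "irtnorm_degenerate_input")
  }
  bin_size <- max(2L, as.integer(round_half_up(m / 10)))
  inner <- build_segmented_model(
    data.frame(x = summaries$x_ref, y = summaries$y_ref),
    mode = "window_width", min_anchors = 2L, bin_size = bin_size)
  new_window_model(inner, scale = scale, fixed_width = fixed_width, m = m)
}

#' Build an extraction-window model from raw observations
#'
#' Convenience wrapper: with at least `min_obs` observations, summarizes
#' sliding bins and fits the window regression; with fewer, returns a
#' fixed-width model (default width: 5% of the observed RT span).
#'
#' @inheritParams summarize_window_bins
#' @inheritParams fit_window_model
#' @return A `window_model`.
#' @export
build_window_model <- function(obs, scale = 2, min_obs = 30L, fixed_width = NULL) {
  check_columns(obs, c("irt", "rt_measured", "rt_predicted", "peak_width"),
                "window observations")
  if (nrow(obs) < min_obs) {
    fw <- fixed_width %||% (0.05 * diff(range(obs$rt_measured)))
    if (!is.finite(fw) || fw <= 0) {
      irt_error("fixed window width must be a positive number", "irtnorm_input_error")
    }
    return(new_window_model(inner = NULL, scale = scale, fixed_width = fw,
                            m = 0L))
  }
  fit_window_model(summarize_window_bins(obs, min_obs = min_obs),
                   scale = scale, fixed_width = fixed_width)
}

#' Extraction-window width at an iRT position
#'
#' Full window width (minutes), centered on the predicted RT: `scale` times
#' the inner regression's prediction, or the fixed width for fallback models.
#'
#' @param model a `window_model`.
#' @param irt numeric vector of iRT positions.
#' @return Numeric vector of full window widths in minutes.
#' @export
window_at <- function(model, irt) {
  if (!inherits(model, "window_model")) {
    irt_error("window_at expects a window_model", "irtnorm_input_error")
  }
  check_finite_numeric(irt, "irt")
  if (is.null(model$inner)) {
    return(rep(model$fixed_width, length(irt)))
  }
  model$scale * predict(model$inner, irt)
}

#' @export
print.window_model <- function(x, ...) {
  if (is.null(x$inner)) {
    cat(sprintf("Window model: fixed width %.3f min\n", x$fixed_width))
  } else {
    cat(sprintf("Window model: scale %.1f x segmented fit on %d reference points\n",
                x$scale, x$m))
  }
  invisible(x)
}

window_model_to_list <- function(model) {
  list(type = "window_model",
       scale = model$scale,
       fixed_width = model$fixed_width,
       m = model$m,
       inner = if (is.null(model$inner)) NULL else model_to_list(model$inner))
}

window_model_from_list <- function(lst) {
  new_window_model(
    inner = if (is.null(lst$inner)) NULL else model_from_list(lst$inner),
    scale = as.numeric(lst$scale),
    fixed_width = if (is.null(lst$fixed_width)) NULL else as.numeric(lst$fixed_width),
    m = as.integer(lst$m))
}
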