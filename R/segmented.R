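# Segmented (piecewise-linear) regression: per-bin Theil-Sen fits connected
# at reference knots, with linear extrapolation beyond the outermost knots.

MODEL_MODES <- c("rt_to_irt", "irt_to_rt", "window_width")

new_segmented_model <- function(mode, knots, fallback = NULL, meta = list()) {
  structure(list(mode = mode, knots = knots, fallback = fallback, meta = meta),
            class = "segmented_model")
}

#' Build a segmented RT/iRT regression model
#'
#' Anchors are sorted by the independent coordinate and split into overlapping
#' equal-count bins ([plan_bins()]). A Theil-Sen line is fitted per bin; the
#' bin's knot is placed at the median x of the bin, with the y value taken
#' from the bin's fitted line at that x. Knots are connected by straight
#' segments and the edge segments are extrapolated. When fewer than
#' `min_anchors` anchors are available the model degrades to a single global
#' Theil-Sen line (the `fallback`).
#'
#' @param anchors data.frame with numeric columns `x`, `y`.
#' @param mode one of `"rt_to_irt"` (spectral library generation),
#'   `"irt_to_rt"` (targeted DIA analysis) or `"window_width"` (internal to
#'   the extraction-window model).
#' @param min_anchors minimum anchor count for the segmented fit; below it the
#'   global linear fallback is used. Defaults: 200 for library generation,
#'   50 for DIA analysis.
#' @param bin_size optional bin-size override passed to [plan_bins()].
#' @return An object of class `segmented_model`.
#' @seealso [predict.segmented_model()], [invert_model()], [write_model()]
#' @export
build_segmented_model <- function(anchors,
                                  mode = c("rt_to_irt", "irt_to_rt", "window_width"),
                                  min_anchors = 200L,
                                  bin_size = NULL) {
  mode <- match.arg(mode)
  check_columns(anchors, c("x", "y"), "anchor table")
  check_finite_numeric(anchors$x, "anchor x")
  check_finite_numeric(anchors$y, "anchor y")
  n <- nrow(anchors)
  meta <- list(n_anchors = n, created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  global_fallback <- function() {
    new_segmented_model(mode, knots = data.frame(x = numeric(0), y = numeric(0)),
                        fallback = ts_fit(anchors$x, anchors$y), meta = meta)
  }

  if (n < min_anchors) return(global_fallback())
  plan <- tryCatch(plan_bins(n, bin_size = bin_size),
                   irtnorm_fallback_required = function(e) NULL)
  if (is.null(plan)) return(global_fallback())

  ord <- order(anchors$x, anchors$y)
  xs <- anchors$x[ord]
  ys <- anchors$y[ord]

  kx <- numeric(0)
  ky <- numeric(0)
  for (b in seq_len(nrow(plan$bins))) {
    idx <- plan$bins$start[b]:plan$bins$end[b]
    fit <- tryCatch(ts_fit(xs[idx], ys[idx]),
                    irtnorm_degenerate_input = function(e) NULL)
    if (is.null(fit)) next  # bin of tied x values; contributes no knot
    x_ref <- stats::median(xs[idx])
    kx <- c(kx, x_ref)
    ky <- c(ky, fit$slope * x_ref + fit$intercept)
  }
  # bins with identical reference x collapse to one knot with the mean y
  if (length(kx)) {
    ky <- as.numeric(tapply(ky, kx, mean))
    kx <- sort(unique(kx))
  }
  if (length(kx) < 2L) return(global_fallback())
  meta$bin_size <- plan$bin_size
  meta$stride <- plan$stride
  new_segmented_model(mode, knots = data.frame(x = kx, y = ky), meta = meta)
}

#' Predict from a segmented model
#'
#' Linear interpolation between the bracketing knots; beyond the first or
#' last knot the corresponding edge segment's slope is extrapolated. Models
#' holding only a global fallback evaluate `slope * x + intercept`.
#'
#' @param object a `segmented_model`.
#' @param x numeric vector of query coordinates (RT in minutes for
#'   `rt_to_irt` models, iRT otherwise).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.segmented_model <- function(object, x, ...) {
  check_finite_numeric(x, "x")
  k <- nrow(object$knots)
  if (k < 2L) {
    if (is.null(object$fallback)) {
      irt_error("segmented model has neither knots nor fallback", "irtnorm_input_error")
    }
    return(object$fallback$slope * x + object$fallback$intercept)
  }
  kx <- object$knots$x
  ky <- object$knots$y
  i <- findInterval(x, kx, all.inside = TRUE)  # edge segments extend outward
  slope <- (ky[i + 1L] - ky[i]) / (kx[i + 1L] - kx[i])
  ky[i] + slope * (x - kx[i])
}

#' Invert a segmented model
#'
#' For a piecewise-linear map that is strictly monotone in y, the inverse is
#' the same model with knot coordinates swapped; a fallback line inverts
#' analytically. `rt_to_irt` and `irt_to_rt` modes are exchanged.
#'
#' @param model a `segmented_model` whose knot y values are strictly monotone
#'   (or whose fallback slope is nonzero).
#' @return The inverse `segmented_model`.
#' @export
invert_model <- function(model) {
  if (!inherits(model, "segmented_model")) {
    irt_error("invert_model expects a segmented_model", "irtnorm_input_error")
  }
  inv_mode <- switch(model$mode,
                     rt_to_irt = "irt_to_rt",
                     irt_to_rt = "rt_to_irt",
                     irt_error("window-width models map iRT to a width and have no inverse",
                               "irtnorm_input_error"))
  k <- nrow(model$knots)
  if (k < 2L) {
    fb <- model$fallback
    if (is.null(fb) || fb$slope == 0) {
      irt_error("fallback line with zero slope is not invertible",
                "irtnorm_degenerate_input")
    }
    return(new_segmented_model(inv_mode, data.frame(x = numeric(0), y = numeric(0)),
                               fallback = new_linear_fit(1 / fb$slope,
                                                         -fb$intercept / fb$slope),
                               meta = model$meta))
  }
  ky <- model$knots$y
  dy <- diff(ky)
  if (all(dy > 0)) {
    knots <- data.frame(x = ky, y = model$knots$x)
  } else if (all(dy < 0)) {
    knots <- data.frame(x = rev(ky), y = rev(model$knots$x))
  } else {
    irt_error("knot y values are not strictly monotone; model is not invertible",
              "irtnorm_degenerate_input")
  }
  new_segmented_model(inv_mode, knots, meta = model$meta)
}

#' @export
print.segmented_model <- function(x, ...) {
  cat(sprintf("Segmented model (%s): %d knots%s, fitted on %s anchors\n",
              x$mode, nrow(x$knots),
              if (is.null(x$fallback)) "" else " [global linear fallback]",
              x$meta$n_anchors %||% "?"))
  invisible(x)
}

model_to_list <- function(model) {
  list(
    type = "segmented_model",
    mode = model$mode,
    knots = if (nrow(model$knots)) unname(as.matrix(model$knots)) else list(),
    fallback = if (is.null(model$fallback)) NULL else
      list(slope = model$fallback$slope, intercept = model$fallback$intercept),
    meta = model$meta
  )
}

model_from_list <- function(lst) {
  knots <- if (length(lst$knots)) {
    m <- matrix(unlist(lst$knots), ncol = 2, byrow = !is.matrix(lst$knots))
    if (is.matrix(lst$knots)) m <- lst$knots
    data.frame(x = m[, 1], y = m[, 2])
  } else {
    data.frame(x = numeric(0), y = numeric(0))
  }
  fallback <- if (is.null(lst$fallback)) NULL else
    new_linear_fit(lst$fallback$slope, lst$fallback$intercept)
  new_segmented_model(lst$mode, knots, fallback, as.list(lst$meta))
}

#' Serialize a model to JSON
#'
#' Writes a `segmented_model` or `window_model` to a JSON file at full double
#' precision, so that read/write round-trips are bit-exact for finite values.
#'
#' @param model a `segmented_model` or `window_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  lst <- if (inherits(model, "window_model")) {
    window_model_to_list(model)
  } else if (inherits(model, "segmented_model")) {
    model_to_list(model)
  } else {
    irt_error("write_model expects a segmented_model or window_model",
              "irtnorm_input_error")
  }
  # 17 significant digits round-trip IEEE doubles bit-exactly
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a serialized model from JSON
#'
#' @param path JSON file written by [write_model()].
#' @return The deserialized `segmented_model` or `window_model`.
#' @export
read_model <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(lst$type, "window_model")) return(window_model_from_list(lst))
  if (identical(lst$type, "segmented_model")) return(model_from_list(lst))
  irt_error(sprintf("unrecognized model type in %s", path), "irtnorm_schema_error")
}
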