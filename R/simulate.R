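# Synthetic chromatographic runs with known ground truth: gradient warps,
# apex-RT jitter, outliers, peak widths, iRT noise injection, and precision
# scoring. This is the harness for the precision experiments.

#' Construct a gradient warp (ground-truth iRT-to-RT mapping)
#'
#' A warp is a piecewise-linear, strictly increasing mapping from the iRT
#' scale to run retention time (minutes), defined by ordered control points.
#'
#' @param breakpoints data.frame with numeric columns `irt` and `rt`, both
#'   strictly increasing.
#' @param name label for the warp.
#' @return An object of class `gradient_warp`.
#' @export
gradient_warp <- function(breakpoints, name = "custom") {
  check_columns(breakpoints, c("irt", "rt"), "warp breakpoints")
  check_finite_numeric(breakpoints$irt, "warp irt")
  check_finite_numeric(breakpoints$rt, "warp rt")
  if (nrow(breakpoints) < 2L || any(diff(breakpoints$irt) <= 0) ||
      any(diff(breakpoints$rt) <= 0)) {
    irt_error("warp breakpoints must be >= 2 points, strictly increasing in both coordinates",
              "irtnorm_input_error")
  }
  structure(list(name = name, breakpoints = breakpoints), class = "gradient_warp")
}

#' Preset gradient warps
#'
#' `"segmented_2h"` mimics a two-hour segmented acetonitrile gradient
#' (5-8% in 2 min, to 12% in 9 min, to 29% in 94 min, to 34% in 12 min), with
#' percent organic mapped linearly onto the iRT domain \[-25, 125\]; retention
#' is approximately linear in percent organic, so the iRT-to-RT map inherits
#' the gradient program's elbows. `"linear_2h"` is a straight two-hour
#' mapping of the same iRT domain onto \[0, 120\] minutes.
#'
#' @param name `"segmented_2h"` or `"linear_2h"`.
#' @return A `gradient_warp`.
#' @export
warp_preset <- function(name = c("segmented_2h", "linear_2h")) {
  name <- match.arg(name)
  if (name == "linear_2h") {
    return(gradient_warp(data.frame(irt = c(-25, 125), rt = c(0, 120)),
                         name = name))
  }
  acn <- c(5, 8, 12, 29, 34)
  minutes <- c(0, 2, 11, 105, 117)
  irt <- -25 + 150 * (acn - min(acn)) / diff(range(acn))
  gradient_warp(data.frame(irt = irt, rt = minutes), name = name)
}

#' Evaluate a gradient warp
#'
#' @param warp a `gradient_warp`.
#' @param irt numeric vector of iRT values (edge segments extrapolate).
#' @return Retention times in minutes.
#' @export
warp_at <- function(warp, irt) {
  if (!inherits(warp, "gradient_warp")) {
    irt_error("warp_at expects a gradient_warp", "irtnorm_input_error")
  }
  check_finite_numeric(irt, "irt")
  bx <- warp$breakpoints$irt
  by <- warp$breakpoints$rt
  i <- findInterval(irt, bx, all.inside = TRUE)
  slope <- (by[i + 1L] - by[i]) / (bx[i + 1L] - bx[i])
  by[i] + slope * (irt - bx[i])
}

#' Generate a synthetic chromatographic run
#'
#' Draws `n` precursors with true iRT uniform over the warp's iRT domain.
#' Non-outlier apex RTs are the warp's value plus Gaussian jitter of SD
#' `rt_noise_sd`; a fraction `outlier_fraction` of apexes is replaced by
#' draws uniform over the run's RT span (emulating ~1% false discoveries).
#' Peak widths are lognormal. Bit-identical under a fixed seed.
#'
#' @param n number of precursors.
#' @param warp a `gradient_warp` (default: the segmented two-hour preset).
#' @param rt_noise_sd SD of apex-RT jitter in minutes (default 0.1).
#' @param width_meanlog,width_sdlog lognormal peak-width parameters
#'   (defaults give a median full width of 0.5 min).
#' @param outlier_fraction fraction of apexes replaced by uniform outliers
#'   (default 0.01).
#' @param seed integer RNG seed.
#' @return A `synthetic_run`: list with `warp`, `observations` (data.frame
#'   `precursor_id`, `true_irt`, `rt_apex`, `peak_width`, `is_outlier`) and
#'   `config` (all generator parameters including the seed).
#' @export
generate_run <- function(n, warp = warp_preset("segmented_2h"),
                         rt_noise_sd = 0.1,
                         width_meanlog = log(0.5), width_sdlog = 0.3,
                         outlier_fraction = 0.01, seed = 1L) {
  if (n < 1) irt_error("n must be >= 1", "irtnorm_input_error")
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    irt_error("outlier_fraction must be in [0, 1)", "irtnorm_input_error")
  }
  if (rt_noise_sd < 0) irt_error("rt_noise_sd must be >= 0", "irtnorm_input_error")
  if (!inherits(warp, "gradient_warp")) {
    irt_error("warp must be a gradient_warp", "irtnorm_input_error")
  }
  set.seed(seed)
  irt_range <- range(warp$breakpoints$irt)
  rt_range <- range(warp$breakpoints$rt)
  true_irt <- stats::runif(n, irt_range[1], irt_range[2])
  rt_apex <- warp_at(warp, true_irt) + stats::rnorm(n, 0, rt_noise_sd)
  is_outlier <- stats::runif(n) < outlier_fraction
  n_out <- sum(is_outlier)
  if (n_out > 0L) {
    rt_apex[is_outlier] <- stats::runif(n_out, rt_range[1], rt_range[2])
  }
  peak_width <- stats::rlnorm(n, width_meanlog, width_sdlog)
  obs <- data.frame(
    precursor_id = sprintf("PEP%06d/2", seq_len(n)),
    true_irt = true_irt,
    rt_apex = rt_apex,
    peak_width = peak_width,
    is_outlier = is_outlier,
    stringsAsFactors = FALSE)
  structure(list(
    warp = warp,
    observations = obs,
    config = list(n = n, warp = warp$name, rt_noise_sd = rt_noise_sd,
                  width_meanlog = width_meanlog, width_sdlog = width_sdlog,
                  outlier_fraction = outlier_fraction, seed = seed)
  ), class = "synthetic_run")
}

#' Inject Gaussian noise into library iRT values
#'
#' Adds independent Gaussian noise of the given SD to each precursor's iRT,
#' leaving every other field untouched; emulates degrading the retention-time
#' precision of a spectral library. `sd = 0` returns an identical copy.
#'
#' @param x a `calibration_set`, `spectral_library`, or any data.frame with an
#'   `irt` column.
#' @param sd noise standard deviation on the iRT scale (>= 0).
#' @param seed integer RNG seed.
#' @return Object of the same type with perturbed `irt`.
#' @export
inject_irt_noise <- function(x, sd, seed = 1L) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0) {
    irt_error("sd must be a single number >= 0", "irtnorm_input_error")
  }
  set.seed(seed)
  if (inherits(x, "spectral_library")) {
    x$entries$irt <- x$entries$irt + stats::rnorm(nrow(x$entries), 0, sd)
    return(x)
  }
  if (is.data.frame(x)) {
    check_columns(x, "irt", "iRT table")
    x$irt <- x$irt + stats::rnorm(nrow(x), 0, sd)
    return(x)
  }
  irt_error("inject_irt_noise expects a spectral_library, calibration_set, or data.frame with an irt column",
            "irtnorm_input_error")
}

#' Score retention-time precision on a synthetic run
#'
#' Computes, over the run's non-outlier observations: the median absolute
#' difference between the true iRT and the model-converted apex RT; the
#' median extraction-window width; and the coverage, i.e. the fraction of
#' true apexes falling inside their extraction window (centered on the
#' predicted RT at the library iRT).
#'
#' @param run a `synthetic_run`.
#' @param model a `segmented_model`; either direction is accepted, and the
#'   other direction is obtained with [invert_model()] unless `rt_model` is
#'   given.
#' @param windows a `window_model`.
#' @param library_irt optional per-observation library iRT used for extraction
#'   (defaults to the run's true iRT; pass noise-injected values to emulate an
#'   imprecise library).
#' @param rt_model optional independently fitted iRT-to-RT `segmented_model`.
#' @return A `precision_report`: list with `median_abs_delta_irt`,
#'   `median_window_width`, `coverage`, `n_evaluated`.
#' @export
evaluate_precision <- function(run, model, windows, library_irt = NULL,
                               rt_model = NULL) {
  if (!inherits(run, "synthetic_run") || nrow(run$observations) == 0L) {
    irt_error("evaluate_precision needs a non-empty synthetic_run",
              "irtnorm_input_error")
  }
  obs <- run$observations
  library_irt <- library_irt %||% obs$true_irt
  if (length(library_irt) != nrow(obs)) {
    irt_error("library_irt must have one value per observation", "irtnorm_input_error")
  }
  if (model$mode == "rt_to_irt") {
    m_rt2irt <- model
    m_irt2rt <- rt_model %||% invert_model(model)
  } else if (model$mode == "irt_to_rt") {
    m_irt2rt <- model
    m_rt2irt <- rt_model %||% invert_model(model)
  } else {
    irt_error("model must map rt_to_irt or irt_to_rt", "irtnorm_input_error")
  }
  ok <- !obs$is_outlier
  delta_irt <- abs(predict(m_rt2irt, obs$rt_apex[ok]) - obs$true_irt[ok])
  rt_pred <- predict(m_irt2rt, library_irt)
  win <- window_at(windows, library_irt)
  covered <- abs(obs$rt_apex - rt_pred) <= win / 2
  structure(list(
    median_abs_delta_irt = stats::median(delta_irt),
    median_window_width = stats::median(win[ok]),
    coverage = mean(covered[ok]),
    n_evaluated = sum(ok)
  ), class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf(paste0("Precision report (n = %d non-outlier precursors)\n",
                     "  median |delta iRT|   : %.4g\n",
                     "  median window width  : %.4g min\n",
                     "  coverage             : %.3f\n"),
              x$n_evaluated, x$median_abs_delta_irt,
              x$median_window_width, x$coverage))
  invisible(x)
}

#' Run a full synthetic precision experiment
#'
#' End-to-end harness mirroring the library iRT-noise design: generate a run,
#' perturb the library iRTs with Gaussian noise of SD `irt_noise_sd`, fit
#' iRT-to-RT and RT-to-iRT models on the (noisy iRT, measured RT) anchors
#' (global linear when `regression = "linear"`), fit the dynamic window model
#' from the anchors' residuals and peak widths, and score precision.
#'
#' @param n number of precursors (default 2000).
#' @param warp a `gradient_warp`.
#' @param irt_noise_sd SD of Gaussian noise added to the library iRTs
#'   (default 0; the design grid is typically 0, 1, 2, 4, 8, 16).
#' @param rt_noise_sd apex-RT jitter SD in minutes.
#' @param outlier_fraction fraction of outlier apexes.
#' @param min_anchors segmented-regression threshold (default 50, the
#'   targeted-DIA setting).
#' @param regression `"segmented"` (default) or `"linear"` (force the global
#'   Theil-Sen fallback, the classic whole-gradient calibration).
#' @param seed integer seed driving both the run and the noise injection.
#' @return List with `run`, `report` (a `precision_report`), the two
#'   `segmented_model`s (`model_irt_to_rt`, `model_rt_to_irt`), the
#'   `window_model`, and `library_irt`.
#' @export
run_precision_experiment <- function(n = 2000L, warp = warp_preset("segmented_2h"),
                                     irt_noise_sd = 0, rt_noise_sd = 0.1,
                                     outlier_fraction = 0.01,
                                     min_anchors = 50L,
                                     regression = c("segmented", "linear"),
                                     seed = 1L) {
  regression <- match.arg(regression)
  run <- generate_run(n, warp, rt_noise_sd = rt_noise_sd,
                      outlier_fraction = outlier_fraction, seed = seed)
  obs <- run$observations
  library_irt <- inject_irt_noise(data.frame(irt = obs$true_irt),
                                  sd = irt_noise_sd, seed = seed + 1L)$irt
  eff_min <- if (regression == "linear") n + 1L else min_anchors
  m_irt2rt <- build_segmented_model(data.frame(x = library_irt, y = obs$rt_apex),
                                    mode = "irt_to_rt", min_anchors = eff_min)
  m_rt2irt <- build_segmented_model(data.frame(x = obs$rt_apex, y = library_irt),
                                    mode = "rt_to_irt", min_anchors = eff_min)
  wobs <- data.frame(irt = library_irt,
                     rt_measured = obs$rt_apex,
                     rt_predicted = predict(m_irt2rt, library_irt),
                     peak_width = obs$peak_width)
  windows <- build_window_model(wobs)
  report <- evaluate_precision(run, m_rt2irt, windows,
                               library_irt = library_irt, rt_model = m_irt2rt)
  list(run = run, report = report, model_irt_to_rt = m_irt2rt,
       model_rt_to_irt = m_rt2irt, window_model = windows,
       library_irt = library_irt)
}
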