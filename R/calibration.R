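# iRT scale definition and construction of the extended calibration set from
# replicate runs.

#' Two-anchor iRT calibration
#'
#' The iRT scale is defined by two reference peptides: the early-eluting scale
#' anchor at iRT = 0 and the late anchor at iRT = 100. Given their retention
#' times in a run, the calibration is the unique line mapping `rt_b` to 0 and
#' `rt_l` to 100 exactly: slope `100/(rt_l - rt_b)`, intercept `-slope * rt_b`.
#'
#' @param rt_b retention time (minutes) of the iRT = 0 anchor peptide.
#' @param rt_l retention time (minutes) of the iRT = 100 anchor peptide.
#' @return A `linear_fit` mapping RT (minutes) to iRT.
#' @examples
#' fit <- two_anchor_calibration(10, 70)
#' predict(fit, 40)  # 50
#' @export
two_anchor_calibration <- function(rt_b, rt_l) {
  check_finite_numeric(rt_b, "rt_b")
  check_finite_numeric(rt_l, "rt_l")
  if (rt_b == rt_l) {
    irt_error("the two anchor peptides have identical retention times; scale is undefined",
              "irtnorm_degenerate_anchors")
  }
  slope <- 100 / (rt_l - rt_b)
  new_linear_fit(slope, -slope * rt_b)
}

#' Build an extended iRT calibration set from replicate runs
#'
#' Implements the extended-anchor-set construction: (1) keep only precursors
#' identified in every replicate run; (2) compute the mean and sample SD
#' (denominator n-1) of the apex RTs per precursor; (3) bin the RT means into
#' `n_bins` equal-width bins spanning first to last eluter; (4) per bin keep
#' the `keep_fraction` of precursors with the lowest RT SD (kit peptides are
#' exempt from the filter and always retained); (5) assign iRT to every
#' retained precursor with the exact two-anchor calibration fitted on the kit
#' anchors' mean RTs.
#'
#' @param observations data.frame with columns `run_id`, `precursor_id`,
#'   `rt_apex` (minutes), and optionally `modified_sequence` (used to match
#'   kit peptides).
#' @param kit data.frame of calibration-kit peptides with columns `sequence`
#'   and `irt`; must contain the scale-defining pair at iRT 0 and 100.
#' @param n_bins number of equal-width RT bins (default 20).
#' @param keep_fraction fraction of precursors kept per bin, lowest SD first
#'   (default 0.8; floor, at least one per non-empty bin).
#' @return A `calibration_set`: data.frame with columns `precursor_id`, `irt`,
#'   `rt_mean`, `rt_sd`, `is_kit`, plus a `provenance` attribute recording the
#'   construction parameters.
#' @export
extend_calibration_set <- function(observations, kit, n_bins = 20L,
                                   keep_fraction = 0.8) {
  check_columns(observations, c("run_id", "precursor_id", "rt_apex"),
                "replicate observations")
  check_columns(kit, c("sequence", "irt"), "kit table")
  check_finite_numeric(observations$rt_apex, "rt_apex")
  if (any(observations$rt_apex < 0)) {
    irt_error("rt_apex must be >= 0", "irtnorm_input_error")
  }
  if (keep_fraction <= 0 || keep_fraction > 1) {
    irt_error("keep_fraction must be in (0, 1]", "irtnorm_input_error")
  }
  runs <- unique(observations$run_id)
  if (length(runs) < 3L) {
    irt_error("calibration-set construction needs >= 3 replicate runs",
              "irtnorm_input_error")
  }

  # (1) precursors present in every run
  seen <- unique(observations[, c("run_id", "precursor_id")])
  n_runs_seen <- table(seen$precursor_id)
  complete <- names(n_runs_seen)[n_runs_seen == length(runs)]
  obs <- observations[observations$precursor_id %in% complete, , drop = FALSE]

  # (2) per-precursor mean and sample SD of apex RT
  rt_mean <- tapply(obs$rt_apex, obs$precursor_id, mean)
  rt_sd <- tapply(obs$rt_apex, obs$precursor_id, stats::sd)
  entries <- data.frame(precursor_id = names(rt_mean),
                        rt_mean = as.numeric(rt_mean),
                        rt_sd = as.numeric(rt_sd),
                        stringsAsFactors = FALSE)

  # kit membership: match kit sequences against the modified sequence when
  # the report carries one, else against the precursor id itself
  if ("modified_sequence" %in% names(observations)) {
    seq_of <- observations$modified_sequence[
      match(entries$precursor_id, observations$precursor_id)]
  } else {
    seq_of <- entries$precursor_id
  }
  kit_idx <- match(seq_of, kit$sequence)
  entries$is_kit <- !is.na(kit_idx)
  kit_irt <- kit$irt[kit_idx]

  rt_b <- entries$rt_mean[entries$is_kit & kit_irt == 0]
  rt_l <- entries$rt_mean[entries$is_kit & kit_irt == 100]
  if (length(rt_b) != 1L || length(rt_l) != 1L) {
    irt_error(paste("cannot calibrate: the scale-defining kit peptides (iRT 0 and 100)",
                    "must each be identified in every run"),
              "irtnorm_cannot_calibrate")
  }

  # (3) equal-width bins over [first, last] eluter, last bin closed on the right
  lo <- min(entries$rt_mean)
  hi <- max(entries$rt_mean)
  width <- (hi - lo) / n_bins
  bin <- if (width > 0) {
    pmin(n_bins, floor((entries$rt_mean - lo) / width) + 1L)
  } else {
    rep(1L, nrow(entries))
  }

  # (4) lowest-SD keep_fraction per bin; kit peptides exempt
  keep <- logical(nrow(entries))
  for (b in unique(bin)) {
    in_bin <- which(bin == b)
    k <- length(in_bin)
    n_keep <- max(1L, floor(keep_fraction * k))
    ord <- in_bin[order(entries$rt_sd[in_bin], entries$precursor_id[in_bin])]
    keep[ord[seq_len(n_keep)]] <- TRUE
  }
  keep[entries$is_kit] <- TRUE
  out <- entries[keep, , drop = FALSE]

  # (5) iRT assignment by the exact two-anchor map
  fit <- two_anchor_calibration(rt_b, rt_l)
  out$irt <- fit$slope * out$rt_mean + fit$intercept
  out <- out[order(out$rt_mean, out$precursor_id),
             c("precursor_id", "irt", "rt_mean", "rt_sd", "is_kit")]
  rownames(out) <- NULL
  attr(out, "provenance") <- list(n_runs = length(runs), n_bins = n_bins,
                                  keep_fraction = keep_fraction,
                                  rt_b = rt_b, rt_l = rt_l,
                                  n_input_precursors = length(n_runs_seen),
                                  n_complete = length(complete))
  class(out) <- c("calibration_set", "data.frame")
  out
}

#' Match a run's identifications to a calibration database
#'
#' Inner join on `precursor_id` between the peptides identified in a run and
#' the calibration set, yielding the anchor points (x = measured RT,
#' y = database iRT) for the RT-to-iRT regression. Duplicate precursor ids in
#' the run produce one anchor per occurrence; output order follows the run.
#'
#' @param run_peptides data.frame with columns `precursor_id` and `rt`
#'   (apex RT, minutes).
#' @param db a `calibration_set` (or any data.frame with `precursor_id`, `irt`).
#' @return data.frame of anchor points with columns `precursor_id`, `x`, `y`;
#'   zero rows when the overlap is empty.
#' @export
match_to_calibration_db <- function(run_peptides, db) {
  check_columns(run_peptides, c("precursor_id", "rt"), "run peptide table")
  check_columns(db, c("precursor_id", "irt"), "calibration set")
  idx <- match(run_peptides$precursor_id, db$precursor_id)
  hit <- !is.na(idx)
  data.frame(precursor_id = run_peptides$precursor_id[hit],
             x = run_peptides$rt[hit],
             y = db$irt[idx[hit]],
             stringsAsFactors = FALSE)
}
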