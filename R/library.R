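# Spectral library assembly: fragment filtering, consensus iRT across runs,
# and the OpenSWATH-style transition-list dialect.

#' Filter and rank fragment ions
#'
#' Keeps fragments with 300 <= m/z <= 1800 (boundaries inclusive) and at least
#' three amino acid residues; neutral-loss fragments are eligible. Survivors
#' are sorted by intensity descending (ties: lower m/z first) and truncated to
#' the `max_keep` most intense.
#'
#' @param candidates data.frame with columns `series`, `ordinal`,
#'   `fragment_charge`, `mz`, `intensity` and optionally `neutral_loss`.
#' @param mz_min,mz_max inclusive m/z bounds (defaults 300 and 1800 Th).
#' @param min_ordinal minimum residue count (default 3).
#' @param max_keep maximum fragments kept (default 6).
#' @return The filtered, intensity-sorted data.frame (possibly zero rows).
#' @export
filter_fragments <- function(candidates, mz_min = 300, mz_max = 1800,
                             min_ordinal = 3L, max_keep = 6L) {
  if (nrow(candidates) == 0L) return(candidates)
  check_columns(candidates, c("series", "ordinal", "mz", "intensity"),
                "fragment table")
  keep <- candidates$mz >= mz_min & candidates$mz <= mz_max &
    candidates$ordinal >= min_ordinal
  out <- candidates[keep, , drop = FALSE]
  out <- out[order(-out$intensity, out$mz), , drop = FALSE]
  out <- utils::head(out, max_keep)
  rownames(out) <- NULL
  out
}

#' Consensus iRT across runs
#'
#' The library iRT of a precursor is the median of its per-run iRT values
#' (mean of the central pair for even counts), making the consensus invariant
#' to run order.
#'
#' @param per_run_irts numeric vector of per-run iRT values (length >= 1).
#' @return The median iRT.
#' @export
consensus_irt <- function(per_run_irts) {
  if (length(per_run_irts) == 0L) {
    irt_error("consensus iRT needs at least one value", "irtnorm_input_error")
  }
  check_finite_numeric(per_run_irts, "per-run iRTs")
  stats::median(per_run_irts)
}

#' Assemble a spectral library from annotated PSM tables
#'
#' Per run, the overlap of the run's identifications with the calibration
#' database provides the anchor points for an RT-to-iRT segmented regression
#' (global linear fallback below `min_anchors`), which converts every PSM's
#' apex RT to iRT. Per precursor, the library iRT is the median across runs;
#' fragment ions are taken from the single best run's spectrum (lowest PSM
#' score if a `score` column is present, else the run whose RT is the
#' per-precursor median), filtered with [filter_fragments()]. Precursors with
#' fewer than `min_fragments` surviving fragments are dropped.
#'
#' @param psms data.frame of peptide-spectrum matches with columns `run_id`,
#'   `precursor_id`, `modified_sequence`, `sequence`, `charge`, `rt_apex`
#'   (minutes) and optionally `score` (lower is better) and `protein_id`.
#' @param fragments data.frame with columns `precursor_id`, `series`,
#'   `ordinal`, `fragment_charge`, `mz`, `intensity`, optionally
#'   `neutral_loss` and `run_id` (per-run spectra; without `run_id` the rows
#'   are treated as shared across runs).
#' @param calibration_db a `calibration_set` used for RT-to-iRT conversion.
#' @param min_anchors minimum calibration overlap for the segmented regression
#'   (default 200, the library-generation setting).
#' @param min_fragments,max_fragments entry retention bounds (defaults 3, 6).
#' @param mz_min,mz_max,min_ordinal fragment filter settings.
#' @return A `spectral_library`: list with `entries` (one row per precursor:
#'   `precursor_id`, `modified_sequence`, `sequence`, `charge`,
#'   `precursor_mz`, `irt`, `protein_id`, `n_fragments`) and `fragments`
#'   (the retained, intensity-ranked fragment rows keyed by `precursor_id`).
#' @export
assemble_library <- function(psms, fragments, calibration_db,
                             min_anchors = 200L,
                             min_fragments = 3L, max_fragments = 6L,
                             mz_min = 300, mz_max = 1800, min_ordinal = 3L) {
  check_columns(psms, c("run_id", "precursor_id", "modified_sequence",
                        "sequence", "charge", "rt_apex"), "PSM table")
  check_columns(fragments, c("precursor_id", "series", "ordinal", "mz",
                             "intensity"), "fragment table")
  runs <- unique(psms$run_id)

  # per-run RT -> iRT conversion via the calibration-db overlap
  psms$irt <- NA_real_
  any_overlap <- FALSE
  for (r in runs) {
    in_run <- psms$run_id == r
    anchors <- match_to_calibration_db(
      data.frame(precursor_id = psms$precursor_id[in_run],
                 rt = psms$rt_apex[in_run], stringsAsFactors = FALSE),
      calibration_db)
    if (nrow(anchors) < 2L) next
    any_overlap <- TRUE
    model <- build_segmented_model(anchors, mode = "rt_to_irt",
                                   min_anchors = min_anchors)
    psms$irt[in_run] <- predict(model, psms$rt_apex[in_run])
  }
  if (!any_overlap) {
    irt_error("no run has a usable overlap (>= 2 anchors) with the calibration database",
              "irtnorm_cannot_build")
  }
  psms <- psms[!is.na(psms$irt), , drop = FALSE]

  has_score <- "score" %in% names(psms)
  frag_by_run <- "run_id" %in% names(fragments)

  ids <- unique(psms$precursor_id)
  entry_rows <- vector("list", length(ids))
  frag_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    pid <- ids[i]
    sub <- psms[psms$precursor_id == pid, , drop = FALSE]
    lib_irt <- consensus_irt(sub$irt)
    # source spectrum: best-scoring run, else the run at the median RT
    best <- if (has_score) {
      which.min(sub$score)
    } else {
      order(sub$rt_apex)[(nrow(sub) + 1L) %/% 2L]
    }
    best_run <- sub$run_id[best]
    cand <- fragments[fragments$precursor_id == pid, , drop = FALSE]
    if (frag_by_run) cand <- cand[cand$run_id == best_run, , drop = FALSE]
    kept <- filter_fragments(cand, mz_min = mz_min, mz_max = mz_max,
                             min_ordinal = min_ordinal, max_keep = max_fragments)
    if (nrow(kept) < min_fragments) next
    entry_rows[[i]] <- data.frame(
      precursor_id = pid,
      modified_sequence = sub$modified_sequence[1L],
      sequence = sub$sequence[1L],
      charge = sub$charge[1L],
      precursor_mz = precursor_mz(sub$sequence[1L], sub$charge[1L]),
      irt = lib_irt,
      protein_id = if ("protein_id" %in% names(sub)) sub$protein_id[1L] else NA_character_,
      n_fragments = nrow(kept),
      stringsAsFactors = FALSE)
    frag_rows[[i]] <- kept
  }
  entries <- do.call(rbind, entry_rows[!vapply(entry_rows, is.null, logical(1))])
  frags <- do.call(rbind, frag_rows[!vapply(frag_rows, is.null, logical(1))])
  if (is.null(entries)) {
    entries <- data.frame(precursor_id = character(0))
    frags <- fragments[0, , drop = FALSE]
  }
  rownames(entries) <- NULL
  rownames(frags) <- NULL
  structure(list(entries = entries, fragments = frags,
                 meta = list(n_runs = length(runs), min_anchors = min_anchors)),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("Spectral library: %d precursors, %d fragment ions\n",
              nrow(x$entries), nrow(x$fragments)))
  invisible(x)
}

#' Write a spectral library as an OpenSWATH-style transition list
#'
#' One row per fragment ion, tab-separated with '.' decimal radix, columns
#' PrecursorMz, ProductMz, LibraryIntensity, NormalizedRetentionTime,
#' PeptideSequence, ModifiedPeptideSequence, PrecursorCharge, FragmentType,
#' FragmentSeriesNumber, FragmentCharge, ProteinId.
#'
#' @param library a `spectral_library`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  e <- library$entries
  f <- library$fragments
  i <- match(f$precursor_id, e$precursor_id)
  out <- data.frame(
    PrecursorMz = e$precursor_mz[i],
    ProductMz = f$mz,
    LibraryIntensity = f$intensity,
    NormalizedRetentionTime = e$irt[i],
    PeptideSequence = e$sequence[i],
    ModifiedPeptideSequence = e$modified_sequence[i],
    PrecursorCharge = e$charge[i],
    FragmentType = f$series,
    FragmentSeriesNumber = f$ordinal,
    FragmentCharge = if ("fragment_charge" %in% names(f)) f$fragment_charge else 1L,
    ProteinId = e$protein_id[i],
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OpenSWATH-style transition list into a spectral library
#'
#' @param path TSV written by [write_library()] (or any transition list with
#'   the same column dialect).
#' @return A `spectral_library`.
#' @export
read_library <- function(path) {
  tab <- read_table(path, c(
    PrecursorMz = "numeric", ProductMz = "numeric", LibraryIntensity = "numeric",
    NormalizedRetentionTime = "numeric", PeptideSequence = "character",
    ModifiedPeptideSequence = "character", PrecursorCharge = "integer",
    FragmentType = "character", FragmentSeriesNumber = "integer",
    FragmentCharge = "integer", ProteinId = "character"))
  pid <- paste0(tab$ModifiedPeptideSequence, "/", tab$PrecursorCharge)
  first <- !duplicated(pid)
  entries <- data.frame(
    precursor_id = pid[first],
    modified_sequence = tab$ModifiedPeptideSequence[first],
    sequence = tab$PeptideSequence[first],
    charge = tab$PrecursorCharge[first],
    precursor_mz = tab$PrecursorMz[first],
    irt = tab$NormalizedRetentionTime[first],
    protein_id = tab$ProteinId[first],
    n_fragments = as.integer(table(pid)[pid[first]]),
    stringsAsFactors = FALSE)
  frags <- data.frame(
    precursor_id = pid,
    series = tab$FragmentType,
    ordinal = tab$FragmentSeriesNumber,
    fragment_charge = tab$FragmentCharge,
    mz = tab$ProductMz,
    intensity = tab$LibraryIntensity,
    stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  structure(list(entries = entries, fragments = frags, meta = list(source = path)),
            class = "spectral_library")
}
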