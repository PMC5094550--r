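# Tab-separated table IO with named-column schemas. The dialect is strict:
# header required, '.' decimal radix only, extra columns preserved.

#' Read a tab-separated table against a schema
#'
#' @param path TSV file with a header row.
#' @param columns named character vector mapping required column names to
#'   types (`"character"`, `"numeric"`, `"integer"`, `"logical"`). Extra
#'   columns are kept as character.
#' @return data.frame with the schema columns converted; column order puts
#'   schema columns first.
#' @export
read_table <- function(path, columns) {
  if (!file.exists(path)) {
    irt_error(sprintf("file not found: %s", path), "irtnorm_io_error")
  }
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(names(columns), names(raw))
  if (length(missing)) {
    irt_error(sprintf("%s is missing required column(s): %s",
                      path, paste(missing, collapse = ", ")),
              "irtnorm_schema_error")
  }
  for (col in names(columns)) {
    type <- columns[[col]]
    v <- raw[[col]]
    if (type %in% c("numeric", "integer")) {
      if (any(grepl(",", v, fixed = TRUE))) {
        row <- which(grepl(",", v, fixed = TRUE))[1]
        irt_error(sprintf(
          "column '%s' row %d contains a comma ('%s'); decimal commas are not supported, use '.' as the radix",
          col, row, v[row]), "irtnorm_parse_error")
      }
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !(v %in% c("NA", "")))
      if (length(bad)) {
        irt_error(sprintf("column '%s' row %d is not numeric: '%s'",
                          col, bad[1], v[bad[1]]), "irtnorm_parse_error")
      }
      raw[[col]] <- if (type == "integer") as.integer(parsed) else parsed
    } else if (type == "logical") {
      raw[[col]] <- as.logical(v)
    }
  }
  raw[, c(names(columns), setdiff(names(raw), names(columns))), drop = FALSE]
}

#' Write a table as TSV
#'
#' Deterministic column order (schema columns first when given), tab
#' separator, no quoting, '.' radix, full double precision.
#'
#' @param rows data.frame to write.
#' @param path output path.
#' @param columns optional character vector fixing the leading column order.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, columns = NULL) {
  if (!is.null(columns)) {
    check_columns(rows, columns, "output table")
    rows <- rows[, c(columns, setdiff(names(rows), columns)), drop = FALSE]
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- schema wrappers for the formats the workflows exchange ----

#' Read an anchor-point table (columns precursor_id, x, y)
#' @param path TSV path.
#' @return data.frame of anchor points.
#' @export
read_anchor_table <- function(path) {
  read_table(path, c(precursor_id = "character", x = "numeric", y = "numeric"))
}

#' Read a replicate-run report (run_id, precursor_id, modified_sequence,
#' charge, rt_apex_min)
#' @param path TSV path.
#' @return data.frame with `rt_apex` in minutes.
#' @export
read_replicate_report <- function(path) {
  tab <- read_table(path, c(run_id = "character", precursor_id = "character",
                            modified_sequence = "character", charge = "integer",
                            rt_apex_min = "numeric"))
  names(tab)[names(tab) == "rt_apex_min"] <- "rt_apex"
  tab
}

#' Write a calibration set (precursor_id, irt, rt_mean_min, rt_sd_min)
#' @param cal a `calibration_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_set <- function(cal, path) {
  out <- data.frame(precursor_id = cal$precursor_id, irt = cal$irt,
                    rt_mean_min = cal$rt_mean, rt_sd_min = cal$rt_sd,
                    stringsAsFactors = FALSE)
  write_table(out, path)
}

#' Read a calibration set written by [write_calibration_set()]
#' @param path TSV path.
#' @return A `calibration_set` data.frame.
#' @export
read_calibration_set <- function(path) {
  tab <- read_table(path, c(precursor_id = "character", irt = "numeric",
                            rt_mean_min = "numeric", rt_sd_min = "numeric"))
  names(tab)[names(tab) == "rt_mean_min"] <- "rt_mean"
  names(tab)[names(tab) == "rt_sd_min"] <- "rt_sd"
  class(tab) <- c("calibration_set", "data.frame")
  tab
}

#' Read window observations (precursor_id, irt, rt_measured_min,
#' rt_predicted_min, peak_width_min)
#' @param path TSV path.
#' @return data.frame for [build_window_model()].
#' @export
read_window_observations <- function(path) {
  tab <- read_table(path, c(precursor_id = "character", irt = "numeric",
                            rt_measured_min = "numeric",
                            rt_predicted_min = "numeric",
                            peak_width_min = "numeric"))
  names(tab) <- sub("_min$", "", names(tab))
  tab
}

#' Export a synthetic run (TSV observations plus JSON config sidecar)
#' @param run a `synthetic_run`.
#' @param path output TSV path; the generator config (parameters and seed) is
#'   written next to it as `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  obs <- run$observations
  out <- data.frame(precursor_id = obs$precursor_id, true_irt = obs$true_irt,
                    rt_apex_min = obs$rt_apex, peak_width_min = obs$peak_width,
                    is_outlier = obs$is_outlier, stringsAsFactors = FALSE)
  write_table(out, path)
  cfg <- run$config
  cfg$warp_breakpoints <- unname(as.matrix(run$warp$breakpoints))
  jsonlite::write_json(cfg, paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a synthetic run written by [write_run()]
#' @param path TSV path (expects the `.config.json` sidecar next to it).
#' @return A `synthetic_run`.
#' @export
read_run <- function(path) {
  tab <- read_table(path, c(precursor_id = "character", true_irt = "numeric",
                            rt_apex_min = "numeric", peak_width_min = "numeric",
                            is_outlier = "logical"))
  cfg_path <- paste0(path, ".config.json")
  if (!file.exists(cfg_path)) {
    irt_error(sprintf("missing run config sidecar: %s", cfg_path), "irtnorm_io_error")
  }
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  bp <- matrix(unlist(cfg$warp_breakpoints), ncol = 2,
               byrow = !is.matrix(cfg$warp_breakpoints))
  if (is.matrix(cfg$warp_breakpoints)) bp <- cfg$warp_breakpoints
  warp <- gradient_warp(data.frame(irt = bp[, 1], rt = bp[, 2]),
                        name = cfg$warp %||% "custom")
  obs <- data.frame(precursor_id = tab$precursor_id, true_irt = tab$true_irt,
                    rt_apex = tab$rt_apex_min, peak_width = tab$peak_width_min,
                    is_outlier = tab$is_outlier, stringsAsFactors = FALSE)
  cfg$warp_breakpoints <- NULL
  structure(list(warp = warp, observations = obs, config = as.list(cfg)),
            class = "synthetic_run")
}
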