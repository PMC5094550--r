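#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up; base round() rounds half to even, which would make bin sizes
# depend on the parity of n/40
round_half_up <- function(x) floor(x + 0.5)

irt_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "irtnorm_error", "error")))
}

check_finite_numeric <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    irt_error(sprintf("%s must be finite numeric values", what),
              "irtnorm_input_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    irt_error(sprintf("%s is missing required column(s): %s",
                      what, paste(missing, collapse = ", ")),
              "irtnorm_schema_error")
  }
  invisible(df)
}
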