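# Classed conditions so callers (and the CLI) can distinguish bad parameters
# from bad data from bad files.

abort_invalid <- function(msg) {
  rlang::abort(msg, class = c("neonicr_invalid_parameter", "neonicr_error"))
}

abort_config <- function(msg) {
  rlang::abort(msg, class = c("neonicr_configuration_error", "neonicr_error"))
}

abort_incompatible <- function(msg) {
  rlang::abort(msg, class = c("neonicr_incompatible_raster", "neonicr_error"))
}

abort_range <- function(msg) {
  rlang::abort(msg, class = c("neonicr_out_of_range", "neonicr_error"))
}

abort_measurement <- function(msg) {
  rlang::abort(msg, class = c("neonicr_invalid_measurement", "neonicr_error"))
}

abort_sample <- function(msg) {
  rlang::abort(msg, class = c("neonicr_invalid_sample", "neonicr_error"))
}

abort_category <- function(msg) {
  rlang::abort(msg, class = c("neonicr_invalid_category", "neonicr_error"))
}

abort_group <- function(msg) {
  rlang::abort(msg, class = c("neonicr_empty_group", "neonicr_error"))
}

abort_format <- function(msg) {
  rlang::abort(msg, class = c("neonicr_format_error", "neonicr_error"))
}

abort_io <- function(msg) {
  rlang::abort(msg, class = c("neonicr_io_error", "neonicr_error"))
}

abort_usage <- function(msg) {
  rlang::abort(msg, class = c("neonicr_usage_error", "neonicr_error"))
}

abort_estimability <- function(msg) {
  rlang::abort(msg, class = c("neonicr_estimability_error", "neonicr_error"))
}

abort_degenerate <- function(msg) {
  rlang::abort(msg, class = c("neonicr_degenerate_structure", "neonicr_error"))
}

abort_selection <- function(msg) {
  rlang::abort(msg, class = c("neonicr_selection_error", "neonicr_error"))
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used when percentages are reported as
#' integers: 75.5 rounds to 76, unlike [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_number <- function(x, name, min = NULL, max = NULL,
                         min_open = FALSE, max_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (!is.null(min) && (if (min_open) x <= min else x < min)) {
    abort_invalid(sprintf("`%s` must be %s %s (got %g).",
                          name, if (min_open) ">" else ">=", min, x))
  }
  if (!is.null(max) && (if (max_open) x >= max else x > max)) {
    abort_invalid(sprintf("`%s` must be %s %s (got %g).",
                          name, if (max_open) "<" else "<=", max, x))
  }
  invisible(x)
}

check_numeric_vec <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    abort_invalid(sprintf("`%s` must be a non-empty finite numeric vector.", name))
  }
  if (!is.null(min) && any(x < min)) {
    abort_invalid(sprintf("`%s` must be >= %s.", name, min))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_format(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Run `expr` under a fixed seed when one is given, restoring RNG state after.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
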