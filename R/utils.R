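# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Stop with a formatted message (no call in output)
#' @keywords internal
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Check that columns are present in a data frame
#' @keywords internal
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    fail("%s is missing required column(s): %s", what,
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Draw a derived RNG stream seed; keeps values in 32-bit integer range
#' @keywords internal
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
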