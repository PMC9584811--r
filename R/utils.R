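#' @importFrom rlang .data abort warn `%||%`
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols across n
#' @keywords internal
"_PACKAGE"

# Round half away from zero to the nearest currency denomination.
# base::round() rounds half to even, which is the wrong convention for money.
round_currency <- function(x, denomination = 1) {
  stopifnot(denomination > 0)
  sign(x) * floor(abs(x) / denomination + 0.5) * denomination
}

months_to_years <- function(m) m / 12

assert_choice_values <- function(x, arg = "choice") {
  bad <- !is.na(x) & !x %in% c("immediate", "delayed")
  if (any(bad)) {
    abort(sprintf("`%s` must be 'immediate' or 'delayed' (got %s).",
                  arg, paste(unique(x[bad]), collapse = ", ")))
  }
  invisible(x)
}

# Raw median absolute deviation (no 1.4826 normal-consistency constant).
raw_mad <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  stats::median(abs(x - stats::median(x)))
}
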