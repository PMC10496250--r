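#' Round half away from zero
#'
#' Rounds to the given number of digits with ties going away from zero
#' (`0.5 -> 1`), matching how clinical tables are conventionally rounded,
#' rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal digits.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 94.44, 52.94))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with a consistent prefix and no call
abort_efminer <- function(...) stop(..., call. = FALSE)

# Parse ISO-8601 dates strictly; returns Date with NA for unparseable input.
parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subtype label sets used throughout
hf_labels <- function() c("HFrEF", "HFmrEF", "HFpEF", "NoHF")
subtype_labels <- function() c(hf_labels(), "Indeterminate")
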