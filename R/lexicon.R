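#' Mining lexicon: trigger terms, worded-EF map and past-reading qualifiers
#'
#' A lexicon bundles everything locale-specific that the EF miner needs:
#' the trigger terms that mark a sentence as EF-relevant, the words accepted
#' as a percent marker, the map from worded EF descriptions to percent
#' values, and the phrases/patterns that disqualify a reading as historical.
#'
#' The three anchored worded descriptions follow the 2016 ESC heart-failure
#' bands: "preserved" is 50%, "mildly reduced" is 45% and "reduced" is 39%.
#' The additional defaults ("severely reduced" 25%, "normal" 60%) are
#' artifact-defined conveniences, not guideline anchors, and can be removed
#' or replaced by supplying a custom lexicon.
#'
#' @param locale locale identifier stored with the lexicon (default "en").
#' @return An object of class `ef_lexicon`: a list with elements
#'   `triggers`, `percent_words`, `worded_map` (named numeric),
#'   `past_qualifiers`, `past_patterns` (regular expressions),
#'   `numeric_left_context` (logical; also scan the two tokens immediately
#'   left of a trigger for constructions like "35% EF"), and `locale`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' lex$worded_map[["mildly reduced"]]
default_lexicon <- function(locale = "en") {
  new_lexicon(list(
    triggers = c("EF", "ejection fraction"),
    percent_words = "percent",
    worded_map = c(
      "mildly reduced"   = 45,
      "severely reduced" = 25,
      "preserved"        = 50,
      "reduced"          = 39,
      "normal"           = 60
    ),
    past_qualifiers = c("a year ago", "years ago", "previously"),
    past_patterns = "\\bin (19|20)[0-9]{2}\\b",
    numeric_left_context = TRUE,
    locale = locale
  ))
}

new_lexicon <- function(x) {
  x <- validate_lexicon(x)
  structure(x, class = "ef_lexicon")
}

validate_lexicon <- function(x) {
  if (!is.list(x)) abort_efminer("lexicon must be a list")
  if (length(x$triggers) == 0 || any(!nzchar(x$triggers))) {
    abort_efminer("lexicon: 'triggers' must be a non-empty character vector")
  }
  wm <- x$worded_map
  if (length(wm) > 0) {
    if (is.null(names(wm)) || any(!nzchar(names(wm)))) {
      abort_efminer("lexicon: 'worded_map' must be a named numeric vector")
    }
    wm <- vapply(wm, as.numeric, numeric(1))
    if (any(is.na(wm)) || any(wm < 0 | wm > 100)) {
      abort_efminer("lexicon: worded_map values must lie in [0, 100]")
    }
    # longest phrase first so e.g. "mildly reduced" shadows "reduced"
    wm <- wm[order(-nchar(names(wm)), names(wm))]
    x$worded_map <- wm
  }
  x$percent_words <- as.character(x$percent_words %||% character())
  x$past_qualifiers <- as.character(x$past_qualifiers %||% character())
  x$past_patterns <- as.character(x$past_patterns %||% character())
  x$numeric_left_context <- isTRUE(x$numeric_left_context %||% TRUE)
  x$locale <- as.character(x$locale %||% "en")
  x
}

#' Read a lexicon from a YAML file
#'
#' The file may define any subset of the keys `triggers`, `percent_words`,
#' `worded_map`, `past_qualifiers`, `past_patterns`,
#' `numeric_left_context`, `locale`; missing keys fall back to
#' [default_lexicon()] values, so a file can override just the vocabulary.
#'
#' @param path path to a YAML lexicon file. The default English lexicon
#'   shipped with the package is at
#'   `system.file("extdata", "lexicon_en.yaml", package = "efminer")`.
#' @return an `ef_lexicon` object.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) abort_efminer("lexicon file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- unclass(default_lexicon())
  for (key in names(raw)) {
    if (!key %in% names(base)) {
      abort_efminer("lexicon file has unknown key: ", key)
    }
    val <- raw[[key]]
    if (key == "worded_map") val <- unlist(val)
    base[[key]] <- val
  }
  new_lexicon(base)
}

#' @export
print.ef_lexicon <- function(x, ...) {
  cat("<ef_lexicon> locale:", x$locale, "\n")
  cat("  triggers:      ", paste(x$triggers, collapse = ", "), "\n")
  cat("  percent words: ", paste(x$percent_words, collapse = ", "), "\n")
  cat("  worded map:    ",
      paste(sprintf("%s=%g", names(x$worded_map), x$worded_map),
            collapse = ", "), "\n")
  cat("  past qualifiers:", length(x$past_qualifiers), "phrase(s),",
      length(x$past_patterns), "pattern(s)\n")
  invisible(x)
}
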