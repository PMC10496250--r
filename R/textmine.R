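#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr bind_rows arrange distinct filter mutate group_by
#'   summarise ungroup n across all_of left_join anti_join select rename
#'   slice_min slice_max row_number desc
#' @importFrom stringr str_locate_all str_extract str_extract_all str_sub
#'   str_detect fixed regex str_escape
NULL

# ---------------------------------------------------------------------------
# Sentence segmentation
# ---------------------------------------------------------------------------

#' Split clinical text into sentences with character offsets
#'
#' Terminators are `.`, `!`, `?` and newline, with one exception: a period
#' flanked by digits on both sides (as in `"35.5"` or the Finnish-style date
#' `"12.5.2019"`) is part of a numeric token and does not terminate.
#' Offsets are 0-based, half-open, into the original `text`; surrounding
#' whitespace is trimmed from each sentence.
#'
#' @param text a single character string (may be empty).
#' @return a tibble with columns `start`, `end` (0-based half-open offsets)
#'   and `text` (the trimmed sentence).
#' @export
#' @examples
#' split_sentences("Seen 12.5.2019. EF 55%.")
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble(start = integer(), end = integer(), text = character())
  if (is.na(text) || nchar(text) == 0L) return(empty)

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  digit <- chars %in% as.character(0:9)
  prev_digit <- c(FALSE, digit[-n])
  next_digit <- c(digit[-1], FALSE)
  term <- chars %in% c("!", "?", "\n") |
    (chars == "." & !(prev_digit & next_digit))

  bounds <- c(0L, which(term), n)
  out <- vector("list", length(bounds) - 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k] + 1L        # 1-based first char after previous terminator
    hi <- bounds[k + 1L]
    if (hi >= lo && term[hi]) hi <- hi - 1L  # drop the terminator itself
    if (hi < lo) next
    # trim whitespace, keeping offsets honest
    while (lo <= hi && grepl("^\\s$", chars[lo])) lo <- lo + 1L
    while (hi >= lo && grepl("^\\s$", chars[hi])) hi <- hi - 1L
    if (hi < lo) next
    out[[k]] <- list(start = lo - 1L, end = hi,
                     text = substr(text, lo, hi))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  tibble(
    start = vapply(out, `[[`, integer(1), "start"),
    end = vapply(out, `[[`, integer(1), "end"),
    text = vapply(out, `[[`, character(1), "text")
  )
}

# ---------------------------------------------------------------------------
# Trigger search
# ---------------------------------------------------------------------------

#' Locate EF trigger terms in a sentence
#'
#' Single-token triggers (e.g. `"EF"`) match case-sensitively at word
#' boundaries, so that words merely containing the letters (e.g. "LEFT")
#' never fire; multi-word triggers (e.g. `"ejection fraction"`) match
#' case-insensitively. Overlapping hits are deduplicated to the longest
#' match.
#'
#' @param sentence a single string.
#' @param lexicon an [ef_lexicon][default_lexicon].
#' @return tibble with columns `start`, `end` (0-based half-open, within the
#'   sentence) and `term`.
#' @export
find_triggers <- function(sentence, lexicon = default_lexicon()) {
  hits <- list()
  for (term in lexicon$triggers) {
    multiword <- grepl("\\s", term)
    pat <- paste0(if (multiword) "(?i)" else "",
                  "\\b", str_escape(term), "\\b")
    loc <- str_locate_all(sentence, regex(pat))[[1]]
    if (nrow(loc) > 0) {
      hits[[length(hits) + 1L]] <- tibble(
        start = loc[, 1] - 1L, end = loc[, 2], term = term
      )
    }
  }
  if (length(hits) == 0L) {
    return(tibble(start = integer(), end = integer(), term = character()))
  }
  out <- bind_rows(hits)
  out <- out[order(out$start, -(out$end - out$start)), , drop = FALSE]
  # deduplicate overlaps, keeping the longest match
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    len <- out$end - out$start
    ord <- order(-len, out$start)
    taken <- matrix(numeric(0), ncol = 2)
    keep <- rep(FALSE, nrow(out))
    for (i in ord) {
      overlaps <- nrow(taken) > 0 &&
        any(out$start[i] < taken[, 2] & out$end[i] > taken[, 1])
      if (!overlaps) {
        keep[i] <- TRUE
        taken <- rbind(taken, c(out$start[i], out$end[i]))
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Candidate value parsers
# ---------------------------------------------------------------------------

# A two-digit integer part (never a fragment of a longer digit run) with an
# optional decimal part using '.' or ',' (Finnish decimal comma).
.num_core <- "(?<![0-9])[0-9]{2}(?:[.,][0-9]+)?(?![0-9])"

num_pattern <- function(lexicon) {
  words <- lexicon$percent_words
  if (length(words) > 0) {
    word_alt <- paste0(
      "|\\s+(?i:", paste(str_escape(words), collapse = "|"), ")\\b")
  } else {
    word_alt <- ""
  }
  paste0(.num_core, "(?:\\s*%", word_alt, ")")
}

range_pattern <- function() {
  paste0(.num_core, "\\s*%\\s*-\\s*", .num_core, "(?:\\s*%)?",
         "|",
         .num_core, "\\s*-\\s*", .num_core, "\\s*%")
}

as_ef_number <- function(x) as.numeric(sub(",", ".", x, fixed = TRUE))

# Search regions for value parsing: rightward of the trigger, plus (when
# enabled) the two whitespace-delimited tokens immediately left of it.
search_regions <- function(sentence, trigger_start0, trigger_end0, lexicon) {
  regions <- list(c(trigger_end0, nchar(sentence)))
  if (isTRUE(lexicon$numeric_left_context) && trigger_start0 > 0) {
    left <- substr(sentence, 1L, trigger_start0)
    toks <- str_locate_all(left, "\\S+")[[1]]
    if (nrow(toks) > 0) {
      first <- toks[max(1L, nrow(toks) - 1L), 1] - 1L
      regions <- c(list(c(first, trigger_start0)), regions)
    }
  }
  regions
}

locate_in_regions <- function(sentence, pattern, regions) {
  out <- list()
  for (rg in regions) {
    seg <- substr(sentence, rg[1] + 1L, rg[2])
    loc <- str_locate_all(seg, regex(pattern))[[1]]
    if (nrow(loc) > 0) {
      out[[length(out) + 1L]] <- tibble(
        span_start = loc[, 1] - 1L + rg[1],
        span_end = loc[, 2] + rg[1]
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(span_start = integer(), span_end = integer()))
  }
  distinct(arrange(bind_rows(out), .data$span_start), .keep_all = TRUE)
}

#' Parse plain numeric EF candidates near a trigger
#'
#' Matches a two-digit value (optional decimal part, `.` or `,` separator)
#' whose next non-space token is `%` or a percent word, searching rightward
#' from the trigger and, when `lexicon$numeric_left_context` is on, the two
#' tokens immediately left of the trigger.
#'
#' @param sentence a single string.
#' @param trigger_span integer length-2 vector: 0-based half-open offsets of
#'   the trigger within `sentence` (a row of [find_triggers()] output).
#' @param lexicon an [ef_lexicon][default_lexicon].
#' @return tibble with `span_start`, `span_end`, `value`, ordered by
#'   position.
#' @export
parse_numeric <- function(sentence, trigger_span, lexicon = default_lexicon()) {
  regions <- search_regions(sentence, trigger_span[1], trigger_span[2], lexicon)
  loc <- locate_in_regions(sentence, num_pattern(lexicon), regions)
  if (nrow(loc) == 0) return(tibble(loc, value = numeric()))
  matched <- str_sub(sentence, loc$span_start + 1L, loc$span_end)
  loc$value <- as_ef_number(str_extract(matched, "^[0-9]{2}(?:[.,][0-9]+)?"))
  loc
}

#' Parse EF range candidates near a trigger
#'
#' Matches hyphen-separated two-digit pairs with a percent marker on either
#' or both numbers (e.g. `"35-40%"`, `"40%-45%"`). The candidate carries the
#' two endpoints; the resolved value is their midpoint.
#'
#' @inheritParams parse_numeric
#' @return tibble with `span_start`, `span_end`, `low`, `high`.
#' @export
parse_range <- function(sentence, trigger_span, lexicon = default_lexicon()) {
  regions <- search_regions(sentence, trigger_span[1], trigger_span[2], lexicon)
  loc <- locate_in_regions(sentence, range_pattern(), regions)
  if (nrow(loc) == 0) {
    return(tibble(loc, low = numeric(), high = numeric()))
  }
  matched <- str_sub(sentence, loc$span_start + 1L, loc$span_end)
  nums <- str_extract_all(matched, "[0-9]{2}(?:[.,][0-9]+)?")
  loc$low <- vapply(nums, function(v) as_ef_number(v[1]), numeric(1))
  loc$high <- vapply(nums, function(v) as_ef_number(v[2]), numeric(1))
  loc
}

#' Parse worded EF descriptions
#'
#' Longest-phrase-first, case-insensitive search of the lexicon's
#' `worded_map` over the whole sentence, so that "mildly reduced" never also
#' fires "reduced". Intended to run only when no accepted numeric or range
#' candidate exists in the sentence.
#'
#' @inheritParams parse_numeric
#' @return tibble with `span_start`, `span_end`, `phrase`, `value`.
#' @export
parse_worded <- function(sentence, trigger_span = NULL,
                         lexicon = default_lexicon()) {
  wm <- lexicon$worded_map   # already ordered longest-first
  taken <- matrix(numeric(0), ncol = 2)
  rows <- list()
  for (phrase in names(wm)) {
    pat <- paste0("(?i)\\b", str_escape(phrase), "\\b")
    loc <- str_locate_all(sentence, regex(pat))[[1]]
    for (i in seq_len(nrow(loc))) {
      s <- loc[i, 1] - 1L; e <- loc[i, 2]
      overlaps <- nrow(taken) > 0 && any(s < taken[, 2] & e > taken[, 1])
      if (!overlaps) {
        taken <- rbind(taken, c(s, e))
        rows[[length(rows) + 1L]] <- tibble(
          span_start = s, span_end = e,
          phrase = phrase, value = unname(wm[[phrase]])
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(span_start = integer(), span_end = integer(),
                  phrase = character(), value = numeric()))
  }
  arrange(bind_rows(rows), .data$span_start)
}

# ---------------------------------------------------------------------------
# Quality checks
# ---------------------------------------------------------------------------

# Spans of date-shaped tokens within a sentence (0-based half-open):
# d.m.yyyy, d/m/yyyy, d.m. (trailing dot), d.m.yy, and a two-digit number
# immediately followed by a four-digit year.
date_token_spans <- function(sentence) {
  pats <- c(
    "\\b[0-9]{1,2}\\.[0-9]{1,2}\\.(?:19|20)[0-9]{2}\\b",
    "\\b[0-9]{1,2}/[0-9]{1,2}/(?:19|20)[0-9]{2}\\b",
    "\\b[0-9]{1,2}\\.[0-9]{1,2}\\.[0-9]{2}(?![0-9])",
    "\\b[0-9]{1,2}\\.[0-9]{1,2}\\.(?![0-9])",
    "\\b[0-9]{2}\\s+(?:19|20)[0-9]{2}\\b"
  )
  out <- list()
  for (p in pats) {
    loc <- str_locate_all(sentence, regex(p))[[1]]
    if (nrow(loc) > 0) {
      out[[length(out) + 1L]] <- cbind(loc[, 1] - 1L, loc[, 2])
    }
  }
  if (length(out) == 0L) matrix(numeric(0), ncol = 2) else do.call(rbind, out)
}

has_past_qualifier <- function(sentence, lexicon) {
  for (q in lexicon$past_qualifiers) {
    if (str_detect(sentence, regex(paste0("\\b", str_escape(q), "\\b"),
                                   ignore_case = TRUE))) {
      return(TRUE)
    }
  }
  for (p in lexicon$past_patterns) {
    if (str_detect(sentence, regex(p, ignore_case = TRUE))) return(TRUE)
  }
  FALSE
}

#' Apply date-masquerade and past-reading quality checks
#'
#' Two disqualification rules: (a) a numeric/range candidate whose span
#' overlaps a date-shaped token (`d.m.yyyy`, `d/m/yyyy`, `d.m.`, `d.m.yy`,
#' or a two-digit number followed by a four-digit year) is rejected as
#' `date_masquerade`; (b) if the sentence contains any past-reading
#' qualifier ("a year ago", "previously", "in 2015", ...), every candidate
#' in the sentence is rejected as `past_reading`. Out-of-range values are
#' deliberately not filtered here: outlier removal happens after daily
#' averaging (see [filter_outliers()]).
#'
#' @param candidates tibble of candidates with columns `span_start`,
#'   `span_end`, `source_kind` (and value columns, passed through).
#' @param sentence the sentence the candidates came from.
#' @param lexicon an [ef_lexicon][default_lexicon].
#' @return `candidates` with columns `status` ("accepted"/"rejected") and
#'   `reject_reason` ("none", "date_masquerade", "past_reading").
#' @export
apply_quality_checks <- function(candidates, sentence,
                                 lexicon = default_lexicon()) {
  candidates$status <- rep("accepted", nrow(candidates))
  candidates$reject_reason <- rep("none", nrow(candidates))
  if (nrow(candidates) == 0) return(candidates)

  dspans <- date_token_spans(sentence)
  if (nrow(dspans) > 0) {
    for (i in seq_len(nrow(candidates))) {
      if (candidates$source_kind[i] == "worded") next
      hit <- any(candidates$span_start[i] < dspans[, 2] &
                   candidates$span_end[i] > dspans[, 1])
      if (hit) {
        candidates$status[i] <- "rejected"
        candidates$reject_reason[i] <- "date_masquerade"
      }
    }
  }
  if (has_past_qualifier(sentence, lexicon)) {
    fresh <- candidates$reject_reason == "none"
    candidates$status[fresh] <- "rejected"
    candidates$reject_reason[fresh] <- "past_reading"
  }
  candidates
}

# ---------------------------------------------------------------------------
# Full extraction
# ---------------------------------------------------------------------------

empty_mentions <- function() {
  tibble(
    patient_id = character(), note_id = character(),
    note_date = as.Date(character()), sentence = character(),
    span_start = integer(), span_end = integer(),
    source_kind = character(),
    raw_value_low = numeric(), raw_value_high = numeric(),
    resolved_value = numeric(),
    status = character(), reject_reason = character()
  )
}

#' Extract all EF mentions from one clinical note
#'
#' Composition of the mining stages: sentence split, per-sentence trigger
#' search, numeric then range parsing (a range suppresses numeric
#' sub-matches of its own digits), then — only if neither produced an
#' accepted candidate in the sentence — the worded-description search;
#' quality checks run on every candidate. All candidates, accepted and
#' rejected, are emitted for auditability.
#'
#' @param note a list or one-row data frame with `patient_id`, `note_id`,
#'   `note_date` and `text`.
#' @param lexicon an [ef_lexicon][default_lexicon].
#' @return a tibble of EF mentions: one row per candidate with provenance
#'   (`sentence`, `span_start`/`span_end` relative to the sentence),
#'   `source_kind` ("numeric"/"range"/"worded"), raw and resolved values,
#'   `status` and `reject_reason`.
#' @export
#' @examples
#' note <- list(patient_id = "p1", note_id = "n1",
#'              note_date = as.Date("2019-03-02"),
#'              text = "EF 35%. EF 40% a year ago.")
#' extract_mentions(note)
extract_mentions <- function(note, lexicon = default_lexicon()) {
  text <- note$text
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty_mentions())
  sentences <- split_sentences(text)
  rows <- list()

  for (si in seq_len(nrow(sentences))) {
    sent <- sentences$text[si]
    trig <- find_triggers(sent, lexicon)
    if (nrow(trig) == 0) next

    nums <- list(); rngs <- list()
    for (ti in seq_len(nrow(trig))) {
      tspan <- c(trig$start[ti], trig$end[ti])
      nums[[ti]] <- parse_numeric(sent, tspan, lexicon)
      rngs[[ti]] <- parse_range(sent, tspan, lexicon)
    }
    nums <- distinct(bind_rows(nums))
    rngs <- distinct(bind_rows(rngs))

    # a matched range suppresses numeric sub-matches of its own digits
    if (nrow(nums) > 0 && nrow(rngs) > 0) {
      keep <- vapply(seq_len(nrow(nums)), function(i) {
        !any(nums$span_start[i] < rngs$span_end &
               nums$span_end[i] > rngs$span_start)
      }, logical(1))
      nums <- nums[keep, , drop = FALSE]
    }

    cand <- bind_rows(
      if (nrow(nums) > 0) tibble(
        span_start = nums$span_start, span_end = nums$span_end,
        source_kind = "numeric",
        raw_value_low = nums$value, raw_value_high = nums$value
      ),
      if (nrow(rngs) > 0) tibble(
        span_start = rngs$span_start, span_end = rngs$span_end,
        source_kind = "range",
        raw_value_low = rngs$low, raw_value_high = rngs$high
      )
    )
    if (!is.null(cand) && nrow(cand) > 0) {
      cand <- arrange(cand, .data$span_start)
      cand <- apply_quality_checks(cand, sent, lexicon)
    }

    no_accepted <- is.null(cand) || nrow(cand) == 0 ||
      !any(cand$status == "accepted")
    if (no_accepted) {
      w <- parse_worded(sent, lexicon = lexicon)
      if (nrow(w) > 0) {
        wc <- tibble(
          span_start = w$span_start, span_end = w$span_end,
          source_kind = "worded",
          raw_value_low = w$value, raw_value_high = w$value
        )
        wc <- apply_quality_checks(wc, sent, lexicon)
        cand <- bind_rows(cand, wc)
      }
    }
    if (is.null(cand) || nrow(cand) == 0) next

    cand$resolved_value <- (cand$raw_value_low + cand$raw_value_high) / 2
    cand$sentence <- sent
    rows[[length(rows) + 1L]] <- cand
  }

  if (length(rows) == 0L) return(empty_mentions())
  out <- bind_rows(rows)
  tibble(
    patient_id = as.character(note$patient_id),
    note_id = as.character(note$note_id),
    note_date = as.Date(note$note_date),
    sentence = out$sentence,
    span_start = as.integer(out$span_start),
    span_end = as.integer(out$span_end),
    source_kind = out$source_kind,
    raw_value_low = out$raw_value_low,
    raw_value_high = out$raw_value_high,
    resolved_value = out$resolved_value,
    status = out$status,
    reject_reason = out$reject_reason
  )
}

#' Extract EF mentions from a whole notes table
#'
#' @param notes tibble of clinical notes as returned by [read_notes()].
#' @param lexicon an [ef_lexicon][default_lexicon].
#' @return tibble of EF mentions across all notes, in note order.
#' @export
mine_notes <- function(notes, lexicon = default_lexicon()) {
  if (nrow(notes) == 0) return(empty_mentions())
  res <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    res[[i]] <- extract_mentions(notes[i, ], lexicon)
  }
  bind_rows(res)
}
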