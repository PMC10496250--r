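# The rule-based EF miner: sentence segmentation, trigger search, value
# parsing and quality checks.

test_that("sentence splitting respects numeric-internal periods", {
  s <- split_sentences("EF 35%. Patient stable.")
  expect_equal(nrow(s), 2)
  expect_equal(s$text, c("EF 35%", "Patient stable"))

  expect_equal(nrow(split_sentences("")), 0)

  s <- split_sentences("Seen 12.5.2019. EF 55%.")
  expect_equal(nrow(s), 2)
  expect_true(grepl("12.5.2019", s$text[1], fixed = TRUE))

  # decimal values survive, '!' and '?' and newline terminate
  s <- split_sentences("EF 35.5% today!\nStable? Yes")
  expect_equal(s$text, c("EF 35.5% today", "Stable", "Yes"))

  # offsets are 0-based half-open into the original text
  txt <- "A b. EF 40%."
  s <- split_sentences(txt)
  for (i in seq_len(nrow(s))) {
    expect_equal(substr(txt, s$start[i] + 1, s$end[i]), s$text[i])
  }
})

test_that("trigger search is case-sensitive for EF, insensitive for phrases", {
  lex <- default_lexicon()
  t1 <- find_triggers("EF 35%", lex)
  expect_equal(nrow(t1), 1)
  expect_equal(unname(c(t1$start, t1$end)), c(0, 2))

  expect_equal(nrow(find_triggers("Ejection fraction was 55 percent", lex)), 1)
  expect_equal(nrow(find_triggers("LEFT atrium dilated", lex)), 0)
  expect_equal(nrow(find_triggers("ef measured", lex)), 0)  # lower-case
  expect_equal(nrow(find_triggers("the chef said", lex)), 0)
})

test_that("numeric parsing: two digits, decimals, percent word, left context", {
  lex <- default_lexicon()
  tsp <- c(0, 2)
  expect_equal(parse_numeric("EF 35%", tsp, lex)$value, 35)
  expect_equal(parse_numeric("EF was 55 percent", tsp, lex)$value, 55)
  expect_equal(parse_numeric("EF 35,5%", tsp, lex)$value, 35.5)
  expect_equal(parse_numeric("EF 35.5%", tsp, lex)$value, 35.5)
  # single- and three-digit numbers are never candidates
  expect_equal(nrow(parse_numeric("EF 5%", tsp, lex)), 0)
  expect_equal(nrow(parse_numeric("EF 105%", tsp, lex)), 0)
  # percent marker required
  expect_equal(nrow(parse_numeric("EF 55 today", tsp, lex)), 0)
  # left-of-trigger constructions
  m <- parse_numeric("45% EF today", c(4, 6), lex)
  expect_equal(m$value, 45)
  lex_off <- default_lexicon()
  lex_off$numeric_left_context <- FALSE
  expect_equal(nrow(parse_numeric("45% EF today", c(4, 6), lex_off)), 0)
})

test_that("range parsing takes the midpoint and suppresses sub-matches", {
  lex <- default_lexicon()
  tsp <- c(0, 2)
  r <- parse_range("EF 35-40%", tsp, lex)
  expect_equal(c(r$low, r$high), c(35, 40))
  r <- parse_range("EF 40%-45%", tsp, lex)
  expect_equal((r$low + r$high) / 2, 42.5)
  r <- parse_range("EF 40 - 40%", tsp, lex)
  expect_equal((r$low + r$high) / 2, 40)
  # a percent marker somewhere is required
  expect_equal(nrow(parse_range("EF 35-40 today", tsp, lex)), 0)

  m <- extract_mentions(make_note("EF 35-40%."))
  expect_equal(nrow(m), 1)           # no spurious numeric from "40%"
  expect_equal(m$source_kind, "range")
  expect_equal(m$raw_value_low, 35)
  expect_equal(m$raw_value_high, 40)
  expect_equal(m$resolved_value, 37.5)
})

test_that("worded parsing maps ESC phrases, longest first", {
  lex <- default_lexicon()
  expect_equal(parse_worded("Ejection fraction is preserved.",
                            lexicon = lex)$value, 50)
  w <- parse_worded("EF mildly reduced", lexicon = lex)
  expect_equal(nrow(w), 1)             # "reduced" must not also fire
  expect_equal(w$value, 45)
  expect_equal(w$phrase, "mildly reduced")
  expect_equal(parse_worded("EF reduced", lexicon = lex)$value, 39)
  # worded never fires when an accepted numeric exists in the sentence
  m <- extract_mentions(make_note("EF 35%, preserved systolic function."))
  expect_false(any(m$source_kind == "worded"))
  # ... but it may fire when every numeric was disqualified
  m <- extract_mentions(make_note("EF 40% a year ago, now preserved."))
  expect_setequal(m$status, "rejected")
})

test_that("quality checks reject past readings and date lookalikes", {
  m <- extract_mentions(make_note("EF 40% a year ago"))
  expect_equal(m$status, "rejected")
  expect_equal(m$reject_reason, "past_reading")

  m <- extract_mentions(make_note("Echo 12.5.2019, EF 55%"))
  expect_equal(m$resolved_value, 55)
  expect_equal(m$status, "accepted")

  m <- extract_mentions(make_note("EF 55%"))
  expect_equal(m$status, "accepted")
  expect_equal(m$reject_reason, "none")

  # "in <year>" qualifier disqualifies the whole sentence
  m <- extract_mentions(make_note("EF 45% in 2015"))
  expect_equal(m$reject_reason, "past_reading")

  # a two-digit year fragment of a d.m.yy date followed by '%' is caught
  m <- extract_mentions(make_note("EF control 13.5.45 %"))
  expect_equal(m$status, "rejected")
  expect_equal(m$reject_reason, "date_masquerade")
})

test_that("extraction composes the stages and keeps rejected mentions", {
  m <- extract_mentions(make_note("EF 35%. EF 40% a year ago."))
  expect_equal(nrow(m), 2)
  expect_equal(m$resolved_value, c(35, 40))
  expect_equal(m$status, c("accepted", "rejected"))
  expect_equal(m$reject_reason, c("none", "past_reading"))

  expect_equal(nrow(extract_mentions(make_note("No relevant cardiac terms."))), 0)
  expect_equal(nrow(extract_mentions(make_note(""))), 0)

  m <- extract_mentions(
    make_note("Ejection fraction preserved, EF not measured numerically."))
  expect_equal(nrow(m), 1)
  expect_equal(m$source_kind, "worded")
  expect_equal(m$resolved_value, 50)

  # spans always lie within the sentence; resolved = midpoint of raws
  m <- extract_mentions(make_note(
    "EF 35%. EF 40-50%. Ejection fraction preserved."))
  expect_true(all(m$span_start >= 0 & m$span_end <= nchar(m$sentence)))
  expect_equal(m$resolved_value, (m$raw_value_low + m$raw_value_high) / 2)
})

test_that("no generated date 1900-2099 ever yields an accepted mention", {
  set.seed(17)
  for (k in 1:150) {
    d <- sample(1:28, 1); mo <- sample(1:12, 1); y <- sample(1900:2099, 1)
    forms <- c(
      sprintf("EF noted %d.%d.%d %%.", d, mo, y),
      sprintf("EF noted %d/%d/%d %%.", d, mo, y),
      sprintf("EF noted %d.%d.%02d %%.", d, mo, y %% 100),
      sprintf("EF noted %d.%d. %d %%.", d, mo, y),
      sprintf("EF noted %02d %d %%.", sample(10:99, 1), y))
    for (txt in forms) {
      m <- extract_mentions(make_note(txt))
      expect_true(all(m$status != "accepted"), label = txt)
    }
  }
})

test_that("extraction is deterministic", {
  note <- make_note("EF 35%. EF 40-50%. EF reduced previously. Sat 96%.")
  expect_identical(extract_mentions(note), extract_mentions(note))
})

test_that("custom lexicons round-trip through YAML and drive the miner", {
  lex_file <- system.file("extdata", "lexicon_en.yaml", package = "efminer")
  lex <- read_lexicon(lex_file)
  expect_s3_class(lex, "ef_lexicon")
  expect_equal(unname(lex$worded_map[["mildly reduced"]]), 45)

  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(worded_map = list("hyperdynamic" = 70)), tmp)
  lex2 <- read_lexicon(tmp)
  m <- extract_mentions(make_note("EF hyperdynamic."), lex2)
  expect_equal(m$resolved_value, 70)

  expect_error(read_lexicon(tempfile()), "not found")
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(worded_map = list(reduced = 150)), bad)
  expect_error(read_lexicon(bad), "\\[0, 100\\]")
})
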