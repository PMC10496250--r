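# The synthetic-EHR generator: determinism, forced mixes, scoring and the
# end-to-end pipeline agreement on a clean corpus.

test_that("generation is deterministic under a fixed seed", {
  cfg <- gen_config(n_patients = 60, seed = 123)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$notes, b$notes)
  expect_identical(a$labs, b$labs)
  expect_identical(a$registry, b$registry)
  expect_identical(a$truth$planted, b$truth$planted)
  # a different seed changes the corpus
  c2 <- generate_corpus(gen_config(n_patients = 60, seed = 124))
  expect_false(identical(a$notes$text, c2$notes$text))
})

test_that("subtype mix constraints propagate to truth and labs", {
  cfg <- gen_config(n_patients = 150, seed = 9,
                    subtype_mix = c(HFrEF = 0, HFmrEF = 0, HFpEF = 0,
                                    NoHF = 1),
                    probnp_missing = 0)
  corpus <- generate_corpus(cfg)
  expect_true(all(corpus$truth$patients$true_subtype == "NoHF"))
  pro <- corpus$labs[corpus$labs$analyte == "probnp", ]
  expect_equal(nrow(pro), 150)
  expect_true(all(pro$value <= 125))

  cfg <- gen_config(n_patients = 80, seed = 9,
                    subtype_mix = c(HFrEF = 0, HFmrEF = 0, HFpEF = 1,
                                    NoHF = 0),
                    probnp_missing = 0)
  pro <- generate_corpus(cfg)$labs
  pro <- pro[pro$analyte == "probnp", ]
  expect_true(all(pro$value > 125))

  expect_error(gen_config(subtype_mix = c(HFrEF = 0.5, HFmrEF = 0.5,
                                          HFpEF = 0.5, NoHF = 0.5)),
               "sum to 1")
})

test_that("n_patients = 0 produces empty outputs with schemas intact", {
  corpus <- generate_corpus(gen_config(n_patients = 0, seed = 1))
  expect_equal(nrow(corpus$notes), 0)
  expect_equal(nrow(corpus$labs), 0)
  expect_equal(nrow(corpus$registry), 0)
  expect_named(corpus$notes, c("patient_id", "note_id", "note_date", "text"))
})

test_that("planted EF values sit in their subtype band", {
  corpus <- generate_corpus(gen_config(n_patients = 400, seed = 77))
  tp <- corpus$truth$patients
  expect_true(all(tp$true_ef[tp$true_subtype == "HFrEF"] < 40))
  mr <- tp$true_ef[tp$true_subtype == "HFmrEF"]
  expect_true(all(mr >= 40 & mr < 50))
  expect_true(all(tp$true_ef[tp$true_subtype %in% c("HFpEF", "NoHF")] >= 50))
})

test_that("score_extraction accounts recall, precision and templates", {
  corpus <- generate_corpus(gen_config(n_patients = 200, seed = 55))
  mentions <- mine_notes(corpus$notes)
  sc <- score_extraction(mentions, corpus$truth)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_equal(sc$n_false_positives, 0)
  # per-template counts sum to the totals
  pt <- sc$per_template
  expect_equal(sum(pt$n_planted), sc$n_planted)
  expect_equal(sum(pt$n_recovered), sc$n_planted * sc$recall)

  # corpus mismatch is an error
  rogue <- mentions[1, ]
  rogue$note_id <- "not_a_note"
  expect_error(score_extraction(rbind(mentions, rogue), corpus$truth),
               "outside")
})

test_that("a distractor-only corpus yields zero accepted mentions", {
  cfg <- gen_config(
    n_patients = 300, seed = 19,
    template_mix = c(numeric = 0, range = 0, worded = 0, multi_same_day = 0,
                     past_distractor = 0, date_distractor = 1,
                     nonEF_percent_distractor = 0))
  corpus <- generate_corpus(cfg)
  mentions <- mine_notes(corpus$notes)
  expect_equal(sum(mentions$status == "accepted"), 0)

  cfg$template_mix <- c(numeric = 0, range = 0, worded = 0,
                        multi_same_day = 0, past_distractor = 1,
                        date_distractor = 0, nonEF_percent_distractor = 0)
  corpus <- generate_corpus(cfg)
  mentions <- mine_notes(corpus$notes)
  expect_equal(sum(mentions$status == "accepted"), 0)
  expect_true(all(mentions$reject_reason == "past_reading"))
})

test_that("pipeline subtypes equal generative truth when labs allow", {
  corpus <- generate_corpus(gen_config(n_patients = 350, seed = 101))
  mentions <- mine_notes(corpus$notes)
  ef <- filter_outliers(daily_mean(
    mentions[mentions$status == "accepted", ]))
  cohort <- build_cohort(ef, corpus$labs, corpus$registry)
  cmp <- merge(cohort[, c("patient_id", "subtype")],
               corpus$truth$patients[, c("patient_id", "true_subtype")])
  cmp <- cmp[cmp$subtype != "Indeterminate", ]
  expect_gt(nrow(cmp), 250)
  expect_equal(mean(cmp$subtype == cmp$true_subtype), 1)
})
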