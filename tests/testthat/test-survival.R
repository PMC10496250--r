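# Age-scale Cox modelling and the Schoenfeld proportionality check.

# survival-record table straight from generator truth (fast path: no text
# mining involved; this tests the model, not the miner)
records_from_truth <- function(corpus) {
  tp <- corpus$truth$patients
  reg <- corpus$registry
  rec <- tibble::tibble(
    patient_id = tp$patient_id,
    entry_age = reg$entry_age, exit_age = reg$exit_age,
    event = as.integer(reg$died),
    subtype = factor(tp$true_subtype,
                     levels = c("NoHF", "HFrEF", "HFmrEF", "HFpEF")),
    sex = factor(tp$sex, levels = c("female", "male")),
    egfr = tp$egfr,
    hypertension = tp$hypertension, ihd = tp$ihd, t2d = tp$t2d,
    copd = tp$copd, renal_failure = tp$renal_failure)
  rec[!is.na(rec$egfr) & rec$exit_age > rec$entry_age, ]
}

test_that("prepare_survival merges, drops Indeterminate, rejects bad follow-up", {
  cohort <- tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"),
    subtype = c("NoHF", "HFrEF", "Indeterminate", "HFpEF"),
    ef_percent = c(60, 30, 55, 55), ef_date = as.Date("2019-01-01"),
    probnp = c(50, NA, NA, 400), probnp_date = as.Date(NA),
    creatinine = 80, egfr = 90, age_at_index = 70, sex = "female")
  registry <- tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"), sex = "female",
    birth_date = as.Date("1949-01-01"),
    hypertension = c(TRUE, FALSE, FALSE, TRUE),
    entry_age = c(70, 70, 70, 70),
    exit_age = c(72, 75, 71, 69),       # p4 invalid: exit < entry
    died = c(FALSE, TRUE, FALSE, TRUE))

  expect_warning(rec <- prepare_survival(cohort, registry), "p4")
  log <- attr(rec, "log")
  expect_equal(log$n_indeterminate, 1)
  expect_equal(log$n_rejected_followup, 1)
  expect_setequal(rec$patient_id, c("p1", "p2"))
  expect_equal(levels(rec$subtype), c("NoHF", "HFrEF", "HFmrEF", "HFpEF"))
  # reference coding: NoHF patient contributes no subtype indicator
  expect_equal(as.integer(rec$subtype[rec$patient_id == "p1"]), 1L)
  expect_equal(rec$event[rec$patient_id == "p2"], 1L)
})

test_that("a null covariate's HR confidence interval covers 1", {
  corpus <- generate_corpus(gen_config(n_patients = 2000, seed = 31),
                            render_notes = FALSE)
  rec <- records_from_truth(corpus)
  set.seed(31)
  rec$noise <- rnorm(nrow(rec))        # independent of the hazard
  fit <- fit_cox(rec, covariates = c("sex", "egfr", "noise"))
  est <- fit$estimates[fit$estimates$term == "noise", ]
  expect_lt(est$ci_low, 1)
  expect_gt(est$ci_high, 1)
  expect_true(all(fit$estimates$ci_low <= fit$estimates$hazard_ratio))
  expect_true(all(fit$estimates$hazard_ratio <= fit$estimates$ci_high))
})

test_that("fit recovers a known HFrEF log-hazard within 3 SE", {
  corpus <- generate_corpus(gen_config(n_patients = 4000, seed = 7),
                            render_notes = FALSE)
  rec <- records_from_truth(corpus)
  fit <- fit_cox(rec)
  est <- fit$estimates[fit$estimates$term == "subtypeHFrEF", ]
  expect_lt(abs(est$log_hr - log(2.63)) / est$se, 3)
})

test_that("duplicating the data leaves estimates identical, CIs narrower", {
  corpus <- generate_corpus(gen_config(n_patients = 1500, seed = 13),
                            render_notes = FALSE)
  rec <- records_from_truth(corpus)
  doubled <- dplyr::bind_rows(rec, rec)
  # Breslow ties make the doubled partial likelihood an exact rescaling
  f1 <- fit_cox(rec, ties = "breslow")
  f2 <- fit_cox(doubled, ties = "breslow")
  expect_equal(f2$estimates$log_hr, f1$estimates$log_hr, tolerance = 1e-8)
  expect_true(all(f2$estimates$se < f1$estimates$se))
})

test_that("schoenfeld check returns one residual row per event and term", {
  corpus <- generate_corpus(gen_config(n_patients = 1200, seed = 5),
                            render_notes = FALSE)
  rec <- records_from_truth(corpus)
  fit <- fit_cox(rec, covariates = c("sex", "egfr"))
  chk <- schoenfeld_check(fit)
  n_events <- sum(rec$event)
  n_terms <- nrow(fit$estimates)
  expect_equal(nrow(chk$residuals), n_events * n_terms)
  expect_setequal(unique(chk$residuals$term), fit$estimates$term)
  expect_equal(nrow(chk$tests), n_terms)
  expect_true(all(chk$tests$p >= 0 & chk$tests$p <= 1))
  # residuals are reported against event age (the analysis time scale)
  expect_true(all(chk$residuals$event_age >= min(rec$entry_age)))
})

test_that("proportional-hazards data rarely fails the trend test", {
  # generator hazards are proportional by construction; at alpha = 0.05 the
  # subtype terms should pass in most replicates
  p_vals <- c()
  for (s in 41:45) {
    corpus <- generate_corpus(gen_config(n_patients = 1500, seed = s),
                              render_notes = FALSE)
    rec <- records_from_truth(corpus)
    fit <- fit_cox(rec, covariates = "sex")
    chk <- schoenfeld_check(fit)
    p_vals <- c(p_vals,
                chk$tests$p[startsWith(chk$tests$term, "subtype")])
  }
  expect_gt(mean(p_vals > 0.05), 0.6)
})

test_that("degenerate inputs raise diagnostic errors", {
  corpus <- generate_corpus(gen_config(n_patients = 300, seed = 2),
                            render_notes = FALSE)
  rec <- records_from_truth(corpus)
  rec$event <- 0L
  expect_error(fit_cox(rec), "no events")
})
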