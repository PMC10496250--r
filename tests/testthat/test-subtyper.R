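# Subtype rules, proBNP pairing, eGFR and cohort assembly.

test_that("subtype assignment follows the ESC-band rule table", {
  expect_equal(assign_subtype(35, NA), "HFrEF")
  expect_equal(assign_subtype(45, 3000), "HFmrEF")
  expect_equal(assign_subtype(55, 300), "HFpEF")
  expect_equal(assign_subtype(55, 100), "NoHF")
  expect_equal(assign_subtype(55, NA), "Indeterminate")

  # boundaries
  expect_equal(assign_subtype(39.999, NA), "HFrEF")
  expect_equal(assign_subtype(40, NA), "HFmrEF")
  expect_equal(assign_subtype(49.999, NA), "HFmrEF")
  expect_equal(assign_subtype(c(50, 50), c(300, 100)), c("HFpEF", "NoHF"))
  expect_equal(assign_subtype(55, 125), "NoHF")      # threshold itself: normal
  expect_equal(assign_subtype(55, 125.01), "HFpEF")

  expect_error(assign_subtype(9, NA), "\\[10, 90\\]")
  expect_error(assign_subtype(95, NA), "\\[10, 90\\]")
})

test_that("rule partition matches a brute-force oracle over the grid", {
  efs <- c(10:90, 39.5, 40.5, 49.5, 50.5)
  probnps <- c(0, 1, 50, 124, 125, 125.01, 126, 500, 5000, NA)
  for (p in probnps) {
    got <- assign_subtype(efs, p)
    want <- vapply(efs, function(e) oracle_subtype(e, p), character(1))
    expect_equal(got, want, label = paste("probnp =", p))
    # exactly one label each, from the closed label set
    expect_true(all(got %in% c("HFrEF", "HFmrEF", "HFpEF", "NoHF",
                               "Indeterminate")))
  }
  # below EF 50 the rule is constant in proBNP
  for (e in c(10, 25, 39, 40, 45, 49.9)) {
    expect_equal(length(unique(assign_subtype(rep(e, length(probnps)),
                                              probnps))), 1)
  }
})

test_that("proBNP pairing picks the nearest sample within the window", {
  labs <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p3", "p3"),
    sample_date = as.Date(c("2019-02-20", "2019-04-01", "2020-02-04",
                            "2018-12-02", "2019-01-31")),
    analyte = "probnp", value = c(100, 200, 300, 400, 500), unit = "ng/l")
  index <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    index_date = as.Date(c("2019-03-02", "2019-01-01", "2019-01-01")))
  out <- pair_probnp(labs, index)
  expect_equal(out$value[out$patient_id == "p1"], 100)  # -10d beats +30d
  expect_true(is.na(out$value[out$patient_id == "p2"])) # +400d outside 365
  expect_equal(out$value[out$patient_id == "p3"], 400)  # +/-30d tie: earlier

  # no probnp at all
  out <- pair_probnp(labs[0, ], index)
  expect_true(all(is.na(out$value)))
})

test_that("eGFR matches the published CKD-EPI 2009 closed form", {
  # frozen from an independent evaluation of the equation
  expect_equal(compute_egfr(70, 60, "female"), 81.15239990405253)
  expect_equal(compute_egfr(80, 60, "male"), 91.91724295996661)
  expect_equal(compute_egfr(50, 40, "female"), 116.2593986346128)
  expect_equal(compute_egfr(120, 75, "male"), 50.668889322606674)

  # doubling creatinine strictly decreases eGFR
  set.seed(3)
  cr <- runif(50, 40, 200)
  expect_true(all(compute_egfr(2 * cr, 60, "male") <
                    compute_egfr(cr, 60, "male")))
  expect_error(compute_egfr(-1, 60, "male"), "positive")
  expect_error(compute_egfr(70, 60, "other"), "sex")
})

test_that("build_cohort applies exclusions and logs them", {
  meas <- tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"),
    measure_date = as.Date("2019-03-02"),
    ef_percent = c(38, 60, 60, 55), n_mentions = 1L)
  labs <- tibble::tibble(
    patient_id = c("p1", "p2", "p2", "p4"),
    sample_date = as.Date("2019-03-01"),
    analyte = c("creatinine", "creatinine", "probnp", "creatinine"),
    value = c(80, 90, 100, 70), unit = c("umol/l", "umol/l", "ng/l", "umol/l"))
  registry <- tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"), sex = "female",
    birth_date = as.Date("1950-01-01"))

  cohort <- build_cohort(meas, labs, registry)
  log <- attr(cohort, "log")
  # p3 has no creatinine -> excluded; p1 HFrEF needs no proBNP;
  # p2 NoHF (probnp 100); p4 EF 55 without proBNP -> Indeterminate
  expect_equal(log$n_with_ef, 4)
  expect_equal(log$n_missing_creatinine, 1)
  expect_equal(log$n_cohort, 3)
  expect_setequal(cohort$patient_id, c("p1", "p2", "p4"))
  expect_equal(cohort$subtype[cohort$patient_id == "p1"], "HFrEF")
  expect_equal(cohort$subtype[cohort$patient_id == "p2"], "NoHF")
  expect_equal(cohort$subtype[cohort$patient_id == "p4"], "Indeterminate")
  expect_false(any(is.na(cohort$egfr)))

  # keeping patients without creatinine is configurable
  cohort2 <- build_cohort(meas, labs, registry, require_creatinine = FALSE)
  expect_equal(nrow(cohort2), 4)
  expect_true(is.na(cohort2$egfr[cohort2$patient_id == "p3"]))
})
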