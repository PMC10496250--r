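# Heart-failure subtyping from index EF and NT-proBNP, plus the CKD-EPI
# eGFR covariate and cohort assembly.

#' Assign the heart-failure subtype from EF and NT-proBNP
#'
#' ESC-band rules: EF < 40 is HFrEF; 40 <= EF < 50 is HFmrEF (the band is
#' half-open so non-integer daily means like 49.5 stay HFmrEF); EF >= 50
#' with proBNP > 125 ng/l is HFpEF; EF >= 50 with proBNP <= 125 ng/l is
#' NoHF. proBNP is ignored below EF 50. A patient with EF >= 50 but no
#' proBNP value cannot be adjudicated and is labelled `Indeterminate`.
#'
#' A proBNP of exactly 125 ng/l counts as normal (NoHF): elevation is
#' defined strictly above the threshold.
#'
#' @param ef numeric EF percent, each in `[10, 90]` (the post-filter range).
#' @param probnp numeric NT-proBNP in ng/l; `NA` for missing. Recycled to
#'   the length of `ef` if scalar.
#' @param threshold proBNP threshold in ng/l (default 125).
#' @return character vector of labels in
#'   `c("HFrEF","HFmrEF","HFpEF","NoHF","Indeterminate")`.
#' @export
#' @examples
#' assign_subtype(c(35, 45, 55, 55, 55), c(NA, 3000, 300, 100, NA))
assign_subtype <- function(ef, probnp = NA_real_, threshold = 125) {
  if (any(is.na(ef))) abort_efminer("assign_subtype: ef must not be missing")
  if (any(ef < 10 | ef > 90)) {
    abort_efminer("assign_subtype: ef outside [10, 90] — run outlier ",
                  "filtering before subtyping")
  }
  probnp <- rep_len(probnp, length(ef))
  out <- character(length(ef))
  out[ef < 40] <- "HFrEF"
  out[ef >= 40 & ef < 50] <- "HFmrEF"
  hi <- ef >= 50
  out[hi & !is.na(probnp) & probnp > threshold] <- "HFpEF"
  out[hi & !is.na(probnp) & probnp <= threshold] <- "NoHF"
  out[hi & is.na(probnp)] <- "Indeterminate"
  out
}

#' Pair the nearest laboratory sample to each patient's index date
#'
#' For each patient, chooses the sample of the requested analyte with the
#' smallest absolute day difference from the index date, within
#' `± window_days`; equidistant ties go to the earlier sample. Patients
#' with no qualifying sample get `NA`.
#'
#' @param labs labs tibble from [read_labs()].
#' @param index tibble with `patient_id` and `index_date` (Date).
#' @param analyte `"probnp"` or `"creatinine"`.
#' @param window_days non-negative pairing window in days (default 365);
#'   `Inf` accepts any sample.
#' @return tibble `patient_id`, `value`, `sample_date` (one row per row of
#'   `index`, `NA` where unmatched).
#' @export
pair_lab <- function(labs, index, analyte = "probnp", window_days = 365) {
  if (window_days < 0) abort_efminer("window_days must be >= 0")
  sub <- labs[labs$analyte == analyte, , drop = FALSE]
  joined <- left_join(index[, c("patient_id", "index_date")], sub,
                      by = "patient_id", relationship = "many-to-many")
  joined$.dist <- abs(as.numeric(joined$sample_date - joined$index_date))
  joined <- joined[is.na(joined$.dist) | joined$.dist <= window_days, ,
                   drop = FALSE]
  best <- joined |>
    arrange(.data$patient_id, .data$.dist, .data$sample_date) |>
    group_by(.data$patient_id) |>
    dplyr::slice(1) |> ungroup() |>
    select("patient_id", value = "value", sample_date = "sample_date")
  out <- left_join(index[, "patient_id", drop = FALSE], best,
                   by = "patient_id")
  out
}

#' @rdname pair_lab
#' @export
pair_probnp <- function(labs, index, window_days = 365) {
  pair_lab(labs, index, analyte = "probnp", window_days = window_days)
}

#' Estimated glomerular filtration rate (CKD-EPI 2009, creatinine)
#'
#' The 2009 CKD-EPI creatinine equation without the race coefficient:
#' `eGFR = 141 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209 * 0.993^age *
#' 1.018[female]`, with creatinine in mg/dl (`Scr = umol/l / 88.42`),
#' `k = 0.7`, `a = -0.329` for women and `k = 0.9`, `a = -0.411` for men.
#'
#' @param creatinine serum creatinine in µmol/l (> 0).
#' @param age age in years (> 0).
#' @param sex `"female"` or `"male"` (vectorised).
#' @return eGFR in ml/min/1.73 m².
#' @export
compute_egfr <- function(creatinine, age, sex) {
  if (any(creatinine <= 0, na.rm = TRUE) || any(age <= 0, na.rm = TRUE)) {
    abort_efminer("compute_egfr: creatinine and age must be positive")
  }
  if (any(!sex %in% c("female", "male"))) {
    abort_efminer("compute_egfr: sex must be 'female' or 'male'")
  }
  scr <- creatinine / 88.42
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1)
}

#' Assemble the subtyped analysis cohort
#'
#' Runs index-EF selection, proBNP and creatinine pairing, eGFR computation
#' and subtype assignment for every patient with at least one EF
#' measurement. Patients with no creatinine sample are excluded by default
#' (eGFR is a required model covariate); proBNP is only required where the
#' rules need it (EF >= 50), and those missing it become `Indeterminate`.
#'
#' @param measurements EF measurements from [filter_outliers()].
#' @param labs labs tibble from [read_labs()].
#' @param registry registry tibble from [read_registry()] (needs `sex`,
#'   `birth_date`).
#' @param index_policy passed to [select_index_ef()].
#' @param ref_date reference date for `index_policy = "nearest"`.
#' @param probnp_window_days pairing window for proBNP (default 365).
#' @param probnp_threshold ng/l threshold for elevation (default 125).
#' @param creatinine_window_days pairing window for creatinine (default
#'   `Inf`: any sample).
#' @param require_creatinine exclude patients without creatinine (default
#'   TRUE).
#' @return tibble `patient_id`, `subtype`, `ef_percent`, `ef_date`,
#'   `probnp`, `probnp_date`, `creatinine`, `egfr`, `age_at_index`, `sex`,
#'   with attribute `log` summarising exclusions
#'   (`n_with_ef`, `n_missing_registry`, `n_missing_creatinine`,
#'   `n_indeterminate`, `n_cohort`).
#' @export
build_cohort <- function(measurements, labs, registry,
                         index_policy = "latest", ref_date = NULL,
                         probnp_window_days = 365, probnp_threshold = 125,
                         creatinine_window_days = Inf,
                         require_creatinine = TRUE) {
  index <- select_index_ef(measurements, policy = index_policy,
                           ref_date = ref_date)
  log <- list(n_with_ef = nrow(index))
  index <- rename(index, index_date = "measure_date")

  reg <- registry[, intersect(c("patient_id", "sex", "birth_date"),
                              names(registry)), drop = FALSE]
  merged <- left_join(index, reg, by = "patient_id")
  miss_reg <- is.na(merged$sex) | is.na(merged$birth_date)
  log$n_missing_registry <- sum(miss_reg)
  merged <- merged[!miss_reg, , drop = FALSE]
  merged$age_at_index <-
    as.numeric(merged$index_date - merged$birth_date) / 365.25

  crea <- pair_lab(labs, merged, analyte = "creatinine",
                   window_days = creatinine_window_days)
  merged$creatinine <- crea$value
  if (require_creatinine) {
    miss_crea <- is.na(merged$creatinine)
    log$n_missing_creatinine <- sum(miss_crea)
    merged <- merged[!miss_crea, , drop = FALSE]
  } else {
    log$n_missing_creatinine <- 0L
  }
  merged$egfr <- ifelse(
    is.na(merged$creatinine), NA_real_,
    compute_egfr(pmax(merged$creatinine, 1e-9), merged$age_at_index,
                 merged$sex))

  pro <- pair_probnp(labs, merged, window_days = probnp_window_days)
  merged$probnp <- pro$value
  merged$probnp_date <- pro$sample_date

  merged$subtype <- assign_subtype(merged$ef_percent, merged$probnp,
                                   threshold = probnp_threshold)
  log$n_indeterminate <- sum(merged$subtype == "Indeterminate")
  log$n_cohort <- nrow(merged)

  out <- tibble(
    patient_id = merged$patient_id,
    subtype = merged$subtype,
    ef_percent = merged$ef_percent,
    ef_date = merged$index_date,
    probnp = merged$probnp,
    probnp_date = merged$probnp_date,
    creatinine = merged$creatinine,
    egfr = merged$egfr,
    age_at_index = merged$age_at_index,
    sex = merged$sex
  )
  attr(out, "log") <- log
  out
}
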