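# Seeded synthetic-EHR generator: clinical notes with planted EF mentions
# and distractors, laboratory series, registry flags and survival times,
# together with a machine-readable ground truth, so that every pipeline
# stage is testable without access-restricted patient data.

clean_kinds <- function() c("numeric", "range", "worded", "multi_same_day")
distractor_kinds <- function() {
  c("past_distractor", "date_distractor", "nonEF_percent_distractor")
}

#' Configuration for the synthetic-EHR generator
#'
#' Defaults describe a cohort shaped like a Finnish hospital-biobank
#' sample: the subtype mix, per-subtype age distributions, sex ratios and
#' comorbidity prevalences follow the real cohort's published descriptives;
#' survival uses a Gompertz baseline with the published subtype hazard
#' ratios (HFrEF 2.63, HFmrEF 1.91, HFpEF 2.28) as generative truth.
#' EF values are drawn per subtype band (HFrEF 15-39, HFmrEF 40-49,
#' HFpEF/NoHF 50-75); proBNP is log-normal per subtype, capped at 125 ng/l
#' for NoHF and floored above 125 ng/l for HFpEF so generated labels are
#' internally consistent.
#'
#' @param n_patients number of patients.
#' @param seed integer seed fixing all randomness end-to-end.
#' @param subtype_mix named probabilities over HFrEF/HFmrEF/HFpEF/NoHF
#'   (must sum to 1).
#' @param template_mix named probabilities over the seven note-template
#'   kinds (must sum to 1). The clean kinds (numeric, range, worded,
#'   multi_same_day) are renormalised to choose each patient's index-note
#'   template; each distractor kind's entry is the per-patient probability
#'   of an additional distractor note of that kind.
#' @param probnp_missing,creatinine_missing per-patient probabilities that
#'   the lab series lacks the analyte.
#' @param survival list: `rate` and `shape` of the Gompertz baseline hazard
#'   (per year of age), `log_hr` named by subtype, `sex_male`,
#'   `egfr_per_unit` (centred at 90 ml/min), `flag` (per comorbidity),
#'   `followup_years` (administrative censoring after entry) and `max_age`.
#' @param locale lexicon locale for the note templates (only "en" ships).
#' @return a validated `ef_gen_config` list.
#' @export
gen_config <- function(
    n_patients = 500,
    seed = 1,
    subtype_mix = c(HFrEF = 1162, HFmrEF = 474, HFpEF = 2110,
                    NoHF = 30237) / 33983,
    template_mix = c(numeric = 0.40, range = 0.10, worded = 0.10,
                     multi_same_day = 0.10, past_distractor = 0.10,
                     date_distractor = 0.10,
                     nonEF_percent_distractor = 0.10),
    probnp_missing = 0.10,
    creatinine_missing = 0.05,
    survival = list(rate = 4.5e-5, shape = 0.09,
                    log_hr = c(NoHF = 0, HFrEF = log(2.63),
                               HFmrEF = log(1.91), HFpEF = log(2.28)),
                    sex_male = log(1.5), egfr_per_unit = -0.01,
                    flag = log(1.2), followup_years = 5, max_age = 100),
    locale = "en") {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    subtype_mix = subtype_mix, template_mix = template_mix,
    probnp_missing = probnp_missing,
    creatinine_missing = creatinine_missing,
    survival = survival, locale = locale,
    # per-subtype cohort shape (age mean/sd, share of women, comorbidity
    # prevalences) in HFrEF/HFmrEF/HFpEF/NoHF order
    age_mean = c(HFrEF = 67.9, HFmrEF = 68.8, HFpEF = 70.8, NoHF = 57.3),
    age_sd = c(HFrEF = 14.6, HFmrEF = 13.1, HFpEF = 14.6, NoHF = 18.1),
    female_prob = c(HFrEF = 0.400, HFmrEF = 0.289, HFpEF = 0.500,
                    NoHF = 0.598),
    comorbidity_prev = list(
      hypertension = c(HFrEF = 0.589, HFmrEF = 0.618, HFpEF = 0.714,
                       NoHF = 0.251),
      ihd = c(HFrEF = 0.439, HFmrEF = 0.549, HFpEF = 0.420, NoHF = 0.121),
      t2d = c(HFrEF = 0.379, HFmrEF = 0.348, HFpEF = 0.357, NoHF = 0.148),
      copd = c(HFrEF = 0.120, HFmrEF = 0.135, HFpEF = 0.124, NoHF = 0.030),
      renal_failure = c(HFrEF = 0.151, HFmrEF = 0.143, HFpEF = 0.201,
                        NoHF = 0.014)),
    probnp_lnorm = list(
      HFrEF = c(meanlog = log(1500), sdlog = 1.0),
      HFmrEF = c(meanlog = log(1500), sdlog = 1.0),
      HFpEF = c(meanlog = log(900), sdlog = 1.0),
      NoHF = c(meanlog = log(70), sdlog = 0.35)),
    creatinine_lnorm = c(meanlog = log(80), sdlog = 0.25)
  )
  validate_gen_config(cfg)
}

validate_gen_config <- function(cfg) {
  if (cfg$n_patients < 0) abort_efminer("gen_config: n_patients must be >= 0")
  for (nm in c("subtype_mix", "template_mix")) {
    mix <- cfg[[nm]]
    want <- if (nm == "subtype_mix") hf_labels() else
      c(clean_kinds(), distractor_kinds())
    if (!setequal(names(mix), want)) {
      abort_efminer("gen_config: ", nm, " must be named over {",
                    paste(want, collapse = ", "), "}")
    }
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
      abort_efminer("gen_config: ", nm, " must be non-negative and sum to 1")
    }
  }
  structure(cfg, class = "ef_gen_config")
}

ef_band_limits <- function(subtype) {
  switch(subtype,
         HFrEF = c(15, 39), HFmrEF = c(40, 49),
         HFpEF = c(50, 75), NoHF = c(50, 75))
}

# Render one index note; returns list(text, planted_values)
render_clean_note <- function(kind, subtype) {
  lim <- ef_band_limits(subtype)
  if (kind == "numeric") {
    v <- sample(lim[1]:lim[2], 1)
    list(text = paste0("Routine follow-up visit. Echocardiography ",
                       "performed today. EF ", v,
                       "%. Medication continued."),
         values = v, true_ef = v)
  } else if (kind == "range") {
    v <- sample((lim[1] + 2):(lim[2] - 2), 1)
    list(text = paste0("Follow-up visit. Echo today shows EF ", v - 2, "-",
                       v + 2, "%. Plan unchanged."),
         values = v, true_ef = v)
  } else if (kind == "worded") {
    word <- switch(subtype, HFrEF = "reduced", HFmrEF = "mildly reduced",
                   "preserved")
    v <- switch(subtype, HFrEF = 39, HFmrEF = 45, 50)
    list(text = paste0("Echocardiography reviewed. Ejection fraction is ",
                       word, ". No acute distress."),
         values = v, true_ef = v)
  } else {  # multi_same_day
    delta <- sample(1:2, 1)
    v <- sample((lim[1] + delta):(lim[2] - delta), 1)
    list(text = paste0("Morning echo: EF ", v - delta,
                       "%. Repeat measurement in the afternoon: EF ",
                       v + delta, "%. Findings discussed."),
         values = c(v - delta, v + delta), true_ef = v)
  }
}

render_distractor_note <- function(kind) {
  if (kind == "past_distractor") {
    x <- sample(20:70, 1)
    paste0("Control visit. EF ", x, "% a year ago. Now feeling well.")
  } else if (kind == "date_distractor") {
    d <- sample(1:28, 1); m <- sample(1:12, 1)
    if (stats::runif(1) < 0.5) {
      yy <- sample(10:99, 1)
      paste0("EF control visit ", d, ".", m, ".", yy,
             " %. Otherwise stable.")
    } else {
      yyyy <- sample(1900:2099, 1)
      paste0("Echo performed on ", d, ".", m, ".", yyyy,
             ". EF not quantified today.")
    }
  } else {  # nonEF_percent_distractor
    s <- sample(90:99, 1)
    paste0("Vital signs stable. Oxygen saturation ", s,
           "%. Continue monitoring.")
  }
}

#' Generate a synthetic EHR corpus with ground truth
#'
#' Draws a subtype for each patient, plants a band-consistent EF value in
#' one index note rendered from a clean template, optionally adds
#' distractor notes (past readings, date lookalikes, non-EF percentages),
#' draws subtype-conditional proBNP and creatinine series, registry flags
#' and survival follow-up, and returns everything together with the ground
#' truth needed to score extraction and classification.
#'
#' @param config an [gen_config()] object.
#' @param render_notes set to `FALSE` to skip note/lab text generation and
#'   return only registry + truth (fast path for survival simulations).
#' @return list with tibbles `notes`, `labs`, `registry` and `truth`, a
#'   list of `patients` (true subtype, EF, index date), `planted`
#'   (mention-level ground truth), `notes` (per-note template inventory)
#'   and `distractors`.
#' @export
generate_corpus <- function(config = gen_config(), render_notes = TRUE) {
  config <- validate_gen_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  labels <- hf_labels()

  if (n == 0) {
    empty_truth <- list(
      patients = tibble(patient_id = character(), true_subtype = character(),
                        true_ef = numeric(), index_date = as.Date(character()),
                        age_at_index = numeric(), sex = character()),
      planted = tibble(patient_id = character(), note_id = character(),
                       note_date = as.Date(character()), value = numeric(),
                       template = character()),
      notes = tibble(note_id = character(), patient_id = character(),
                     note_date = as.Date(character()), template = character()),
      distractors = tibble(patient_id = character(), note_id = character(),
                           note_date = as.Date(character()),
                           kind = character()))
    return(list(
      notes = tibble(patient_id = character(), note_id = character(),
                     note_date = as.Date(character()), text = character()),
      labs = tibble(patient_id = character(),
                    sample_date = as.Date(character()), analyte = character(),
                    value = numeric(), unit = character()),
      registry = tibble(patient_id = character(), sex = character(),
                        birth_date = as.Date(character())),
      truth = empty_truth))
  }

  pid <- sprintf("p%05d", seq_len(n))
  subtype <- sample(labels, n, replace = TRUE,
                    prob = config$subtype_mix[labels])
  index_date <- as.Date("2015-01-01") + sample(0:2190, n, replace = TRUE)
  age <- pmin(pmax(stats::rnorm(n, config$age_mean[subtype],
                                config$age_sd[subtype]), 18), 95)
  sex <- ifelse(stats::runif(n) < config$female_prob[subtype],
                "female", "male")

  clean_mass <- sum(config$template_mix[clean_kinds()])
  if (clean_mass > 0) {
    kind <- sample(clean_kinds(), n, replace = TRUE,
                   prob = config$template_mix[clean_kinds()] / clean_mass)
  } else {
    kind <- rep(NA_character_, n)
  }

  notes_rows <- list(); planted_rows <- list(); note_inv <- list()
  distractor_rows <- list()
  true_ef <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    nseq <- 0L
    if (!is.na(kind[i])) {
      rend <- render_clean_note(kind[i], subtype[i])
      true_ef[i] <- rend$true_ef
      nseq <- nseq + 1L
      nid <- paste0(pid[i], "_n", nseq)
      if (render_notes) {
        notes_rows[[length(notes_rows) + 1L]] <- list(
          patient_id = pid[i], note_id = nid, note_date = index_date[i],
          text = rend$text)
      }
      note_inv[[length(note_inv) + 1L]] <- list(
        note_id = nid, patient_id = pid[i], note_date = index_date[i],
        template = kind[i])
      for (v in rend$values) {
        planted_rows[[length(planted_rows) + 1L]] <- list(
          patient_id = pid[i], note_id = nid, note_date = index_date[i],
          value = as.numeric(v), template = kind[i])
      }
      # additional distractor notes, one Bernoulli draw per kind
      for (dk in distractor_kinds()) {
        if (stats::runif(1) < config$template_mix[[dk]]) {
          nseq <- nseq + 1L
          nid <- paste0(pid[i], "_n", nseq)
          ddate <- index_date[i] + 30 * (nseq - 1L)
          if (render_notes) {
            notes_rows[[length(notes_rows) + 1L]] <- list(
              patient_id = pid[i], note_id = nid, note_date = ddate,
              text = render_distractor_note(dk))
          }
          note_inv[[length(note_inv) + 1L]] <- list(
            note_id = nid, patient_id = pid[i], note_date = ddate,
            template = dk)
          distractor_rows[[length(distractor_rows) + 1L]] <- list(
            patient_id = pid[i], note_id = nid, note_date = ddate, kind = dk)
        }
      }
    } else {
      # no clean mass: one distractor note from the renormalised mix
      dmass <- sum(config$template_mix[distractor_kinds()])
      dk <- sample(distractor_kinds(), 1,
                   prob = config$template_mix[distractor_kinds()] / dmass)
      nid <- paste0(pid[i], "_n1")
      if (render_notes) {
        notes_rows[[length(notes_rows) + 1L]] <- list(
          patient_id = pid[i], note_id = nid, note_date = index_date[i],
          text = render_distractor_note(dk))
      }
      note_inv[[length(note_inv) + 1L]] <- list(
        note_id = nid, patient_id = pid[i], note_date = index_date[i],
        template = dk)
      distractor_rows[[length(distractor_rows) + 1L]] <- list(
        patient_id = pid[i], note_id = nid, note_date = index_date[i],
        kind = dk)
    }
  }

  # labs: subtype-conditional proBNP (NoHF capped at 125, HFpEF floored
  # above 125) and creatinine
  labs_rows <- list()
  creatinine <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (stats::runif(1) >= config$probnp_missing) {
      par <- config$probnp_lnorm[[subtype[i]]]
      v <- stats::rlnorm(1, par[["meanlog"]], par[["sdlog"]])
      if (subtype[i] == "NoHF") v <- min(v, 125)
      if (subtype[i] == "HFpEF") v <- max(v, 126)
      labs_rows[[length(labs_rows) + 1L]] <- list(
        patient_id = pid[i], sample_date = index_date[i] - sample(0:60, 1),
        analyte = "probnp", value = round(v, 1), unit = "ng/l")
    }
    if (stats::runif(1) >= config$creatinine_missing) {
      creatinine[i] <- round(stats::rlnorm(
        1, config$creatinine_lnorm[["meanlog"]],
        config$creatinine_lnorm[["sdlog"]]), 1)
      labs_rows[[length(labs_rows) + 1L]] <- list(
        patient_id = pid[i], sample_date = index_date[i] - sample(0:30, 1),
        analyte = "creatinine", value = creatinine[i], unit = "umol/l")
    }
  }

  flags <- lapply(config$comorbidity_prev, function(prev) {
    stats::runif(n) < prev[subtype]
  })

  patients <- tibble(
    patient_id = pid, true_subtype = subtype, true_ef = true_ef,
    index_date = index_date, age_at_index = age, sex = sex,
    creatinine = creatinine,
    egfr = ifelse(is.na(creatinine), NA_real_,
                  compute_egfr(pmax(creatinine, 1e-9), age, sex)))
  for (fl in names(flags)) patients[[fl]] <- flags[[fl]]

  followup <- generate_survival(patients, config)
  registry <- tibble(
    patient_id = pid, sex = sex,
    birth_date = index_date - round(age * 365.25))
  for (fl in names(flags)) registry[[fl]] <- flags[[fl]]
  registry$entry_age <- followup$entry_age
  registry$exit_age <- followup$exit_age
  registry$died <- followup$died

  to_tbl <- function(rows, proto) {
    if (length(rows) == 0) return(proto)
    bind_rows(lapply(rows, as_tibble))
  }
  list(
    notes = to_tbl(notes_rows,
                   tibble(patient_id = character(), note_id = character(),
                          note_date = as.Date(character()),
                          text = character())),
    labs = to_tbl(labs_rows,
                  tibble(patient_id = character(),
                         sample_date = as.Date(character()),
                         analyte = character(), value = numeric(),
                         unit = character())),
    registry = registry,
    truth = list(
      patients = patients,
      planted = to_tbl(planted_rows,
                       tibble(patient_id = character(), note_id = character(),
                              note_date = as.Date(character()),
                              value = numeric(), template = character())),
      notes = to_tbl(note_inv,
                     tibble(note_id = character(), patient_id = character(),
                            note_date = as.Date(character()),
                            template = character())),
      distractors = to_tbl(distractor_rows,
                           tibble(patient_id = character(),
                                  note_id = character(),
                                  note_date = as.Date(character()),
                                  kind = character()))))
}

#' Draw survival follow-up under the generative hazard model
#'
#' Age is the time scale: each patient enters at their index age and is
#' followed until death or administrative censoring
#' (`entry + followup_years`, capped at `max_age`). Event ages are drawn
#' from a Gompertz baseline `h0(a) = rate * exp(shape * a)` multiplied by
#' `exp(lp)`, where the linear predictor holds the subtype log-hazard
#' (defaults: the published point estimates HR 2.63 / 1.91 / 2.28), a sex
#' effect, an eGFR effect and the comorbidity-flag effects, by inverse
#' transform of the conditional survival function.
#'
#' @param patients tibble with `true_subtype`, `age_at_index`, `sex`,
#'   `egfr` (NA tolerated) and the comorbidity flags (as from
#'   `generate_corpus()$truth$patients`).
#' @param config an [gen_config()] object.
#' @return tibble `patient_id`, `entry_age`, `exit_age`, `died`.
#' @export
generate_survival <- function(patients, config = gen_config()) {
  sv <- config$survival
  n <- nrow(patients)
  lp <- unname(sv$log_hr[patients$true_subtype]) +
    sv$sex_male * (patients$sex == "male") +
    sv$egfr_per_unit * (ifelse(is.na(patients$egfr), 90, patients$egfr) - 90)
  for (fl in names(config$comorbidity_prev)) {
    if (fl %in% names(patients)) lp <- lp + sv$flag * patients[[fl]]
  }
  a0 <- patients$age_at_index
  u <- stats::runif(n)
  # inverse of S(a | a0) = exp(-(H0(a) - H0(a0)) * exp(lp)),
  # H0(a) = rate/shape * exp(shape * a)
  event_age <- (1 / sv$shape) *
    log(exp(sv$shape * a0) - sv$shape * log(u) / (sv$rate * exp(lp)))
  censor_age <- pmin(a0 + sv$followup_years, sv$max_age)
  died <- event_age <= censor_age
  exit_age <- pmin(event_age, censor_age)
  exit_age <- ifelse(died & exit_age <= a0, a0 + 1 / 365.25, exit_age)
  tibble(patient_id = patients$patient_id, entry_age = a0,
         exit_age = exit_age, died = died)
}

#' Score extraction output against the planted ground truth
#'
#' A planted value counts as recovered when an accepted mention matches its
#' patient, date and value to within 1e-9; an accepted mention that matches
#' no planted value (e.g. a distractor that slipped through) is a false
#' positive.
#'
#' @param mentions mention tibble from [mine_notes()] (accepted and
#'   rejected rows both fine; only accepted ones are scored).
#' @param truth the `truth` element of [generate_corpus()] output.
#' @return list: `recall`, `precision` (NA when undefined), `n_planted`,
#'   `n_accepted`, `n_false_positives`, and `per_template` (tibble with
#'   per-template planted/recovered and per-distractor-kind false-accept
#'   counts).
#' @export
score_extraction <- function(mentions, truth) {
  known_notes <- truth$notes$note_id
  if (nrow(mentions) > 0 && !all(mentions$note_id %in% known_notes)) {
    abort_efminer("score_extraction: mentions reference notes outside the ",
                  "generated corpus")
  }
  acc <- mentions[mentions$status == "accepted", , drop = FALSE]

  planted <- truth$planted
  match_key <- function(p, d, v) paste(p, d, format(v, digits = 12))
  acc_keys <- match_key(acc$patient_id, acc$note_date, acc$resolved_value)
  planted_keys <- match_key(planted$patient_id, planted$note_date,
                            planted$value)
  recovered <- planted_keys %in% acc_keys
  true_accept <- acc_keys %in% planted_keys

  per_template <- planted |>
    mutate(recovered = recovered) |>
    group_by(template = .data$template) |>
    summarise(n_planted = dplyr::n(),
              n_recovered = sum(.data$recovered), .groups = "drop")
  if (nrow(truth$distractors) > 0) {
    fa <- truth$distractors |>
      mutate(n_false = vapply(.data$note_id, function(nid) {
        sum(acc$note_id == nid)
      }, numeric(1))) |>
      group_by(template = .data$kind) |>
      summarise(n_planted = 0L, n_recovered = 0L,
                n_false_accepted = as.integer(sum(.data$n_false)),
                .groups = "drop")
    per_template$n_false_accepted <- 0L
    per_template <- bind_rows(per_template, fa)
  }

  list(
    recall = if (nrow(planted) == 0) NA_real_ else mean(recovered),
    precision = if (nrow(acc) == 0) NA_real_ else mean(true_accept),
    n_planted = nrow(planted),
    n_accepted = nrow(acc),
    n_false_positives = sum(!true_accept),
    per_template = per_template)
}
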