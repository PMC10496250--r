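# Pipeline orchestration: mine -> aggregate -> subtype -> validate /
# survive, driven by a single config, with per-stage counts and exclusion
# tallies in a JSON run summary.

pipeline_config_keys <- function() {
  c("notes", "labs", "registry", "gold", "outdir", "lexicon",
    "index_policy", "ref_date", "probnp_window_days", "probnp_threshold",
    "creatinine_window_days", "require_creatinine", "seed", "simulate")
}

#' Validate a pipeline configuration
#'
#' @param config named list (or path to a YAML file) with keys among:
#'   `notes`, `labs`, `registry`, `gold` (optional gold-standard subtype
#'   CSV), `outdir`, `lexicon` (YAML path; default lexicon when omitted),
#'   `index_policy`, `ref_date`, `probnp_window_days`, `probnp_threshold`,
#'   `creatinine_window_days`, `require_creatinine`, `seed`, `simulate`
#'   (optional list of [gen_config()] overrides — when present the corpus
#'   is generated rather than read). Unknown keys are rejected.
#' @return the validated config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), pipeline_config_keys())
  if (length(unknown) > 0) {
    abort_efminer("pipeline config has unknown key(s): ",
                  paste(unknown, collapse = ", "))
  }
  config$index_policy <- config$index_policy %||% "latest"
  config$probnp_window_days <- config$probnp_window_days %||% 365
  config$probnp_threshold <- config$probnp_threshold %||% 125
  config$creatinine_window_days <- config$creatinine_window_days %||% Inf
  config$require_creatinine <- config$require_creatinine %||% TRUE
  config$seed <- config$seed %||% 1
  if (is.null(config$outdir)) abort_efminer("pipeline config needs 'outdir'")
  if (is.null(config$simulate)) {
    for (key in c("notes", "labs", "registry")) {
      if (is.null(config[[key]])) {
        abort_efminer("pipeline config needs '", key,
                      "' (or a 'simulate' block)")
      }
      if (!file.exists(config[[key]])) {
        abort_efminer("pipeline input file not found: ", config[[key]])
      }
    }
  }
  config
}

#' Write a generated corpus to disk
#'
#' Emits `notes.jsonl`, `labs.csv`, `registry.csv`, `truth_patients.csv`,
#' `truth_planted.csv`, `truth_notes.csv` and `truth_distractors.csv` into
#' `outdir`.
#'
#' @param corpus output of [generate_corpus()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_corpus <- function(corpus, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  notes <- corpus$notes
  con <- file(file.path(outdir, "notes.jsonl"), "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    writeLines(jsonlite::toJSON(list(
      patient_id = notes$patient_id[i], note_id = notes$note_id[i],
      note_date = format(notes$note_date[i]), text = notes$text[i]),
      auto_unbox = TRUE), con)
  }
  readr::write_csv(corpus$labs, file.path(outdir, "labs.csv"),
                   progress = FALSE)
  reg <- corpus$registry
  reg$died <- as.integer(reg$died)
  readr::write_csv(reg, file.path(outdir, "registry.csv"), progress = FALSE)
  readr::write_csv(corpus$truth$patients,
                   file.path(outdir, "truth_patients.csv"), progress = FALSE)
  readr::write_csv(corpus$truth$planted,
                   file.path(outdir, "truth_planted.csv"), progress = FALSE)
  readr::write_csv(corpus$truth$notes,
                   file.path(outdir, "truth_notes.csv"), progress = FALSE)
  readr::write_csv(corpus$truth$distractors,
                   file.path(outdir, "truth_distractors.csv"),
                   progress = FALSE)
  invisible(outdir)
}

#' Run the full mining pipeline
#'
#' Stages, in order: (optionally) simulate, mine, aggregate, subtype, and —
#' when the inputs allow — validate against a gold standard and fit the
#' age-scale Cox model. Every stage reports counts in and out, and every
#' excluded patient or rejected mention is tallied by reason. The summary
#' is written to `summary.json` in the output directory.
#'
#' @param config a config list or YAML path; see [pipeline_config()].
#' @return the run summary list, invisibly; artifacts (mentions audit, EF
#'   table, subtype table, metrics, summary) are written under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = config$seed)

  # --- inputs: simulate or read -------------------------------------------
  gold <- NULL
  if (!is.null(config$simulate)) {
    gcfg <- do.call(gen_config, c(config$simulate,
                                  if (is.null(config$simulate$seed))
                                    list(seed = config$seed)))
    corpus <- generate_corpus(gcfg)
    write_corpus(corpus, file.path(outdir, "sim"))
    notes <- corpus$notes; labs <- corpus$labs; registry <- corpus$registry
    gold <- corpus$truth$patients[
      !is.na(corpus$truth$patients$true_ef),
      c("patient_id", "true_subtype")]
    names(gold) <- c("patient_id", "subtype")
    summary$simulate <- list(n_patients = gcfg$n_patients,
                             n_notes = nrow(notes))
  } else {
    notes <- read_notes(config$notes)
    labs <- read_labs(config$labs)
    registry <- read_registry(config$registry)
    if (!is.null(config$gold)) {
      gold <- readr::read_csv(config$gold,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
    }
  }
  lexicon <- if (is.null(config$lexicon)) default_lexicon() else
    read_lexicon(config$lexicon)

  # --- mine ----------------------------------------------------------------
  mentions <- mine_notes(notes, lexicon)
  write_audit(mentions, file.path(outdir, "audit.csv"))
  reject_tally <- as.list(table(
    mentions$reject_reason[mentions$status == "rejected"]))
  summary$mine <- list(
    n_notes = nrow(notes),
    n_mentions = nrow(mentions),
    n_accepted = sum(mentions$status == "accepted"),
    n_rejected = sum(mentions$status == "rejected"),
    rejected_by_reason = reject_tally)

  # --- aggregate -----------------------------------------------------------
  accepted <- mentions[mentions$status == "accepted", , drop = FALSE]
  measurements <- daily_mean(accepted)
  filtered <- filter_outliers(measurements)
  readr::write_csv(filtered, file.path(outdir, "ef.csv"), progress = FALSE)
  summary$aggregate <- list(
    n_measurements = nrow(measurements),
    n_outliers_removed = nrow(attr(filtered, "removed")),
    n_patients_with_ef = length(unique(filtered$patient_id)))

  # --- subtype -------------------------------------------------------------
  cohort <- build_cohort(
    filtered, labs, registry,
    index_policy = config$index_policy,
    ref_date = if (!is.null(config$ref_date)) as.Date(config$ref_date),
    probnp_window_days = config$probnp_window_days,
    probnp_threshold = config$probnp_threshold,
    creatinine_window_days = config$creatinine_window_days,
    require_creatinine = config$require_creatinine)
  readr::write_csv(cohort, file.path(outdir, "subtypes.csv"),
                   progress = FALSE)
  clog <- attr(cohort, "log")
  summary$subtype <- c(clog, list(
    counts = as.list(table(cohort$subtype))))
  # patient conservation: everyone with an index EF is either excluded for a
  # logged reason or present in the cohort
  stopifnot(clog$n_with_ef ==
              clog$n_cohort + clog$n_missing_registry +
              clog$n_missing_creatinine)

  # --- validate ------------------------------------------------------------
  if (!is.null(gold)) {
    pred <- cohort[cohort$patient_id %in% gold$patient_id,
                   c("patient_id", "subtype")]
    gold_sub <- gold[gold$patient_id %in% pred$patient_id, , drop = FALSE]
    if (nrow(pred) > 0) {
      cmat <- build_confusion(pred, gold_sub)
      metrics <- all_class_metrics(cmat)
      jsonlite::write_json(
        list(labels = cmat$labels, counts = cmat$counts, n = cmat$n,
             metrics = metrics),
        file.path(outdir, "metrics.json"), auto_unbox = TRUE, digits = NA)
      summary$validate <- list(
        n_validated = cmat$n,
        n_excluded_indeterminate = attr(cmat, "n_excluded_indeterminate"),
        accuracy_4class = 100 * sum(diag(cmat$counts)) / cmat$n)
    }
  }

  # --- survive -------------------------------------------------------------
  if (all(c("entry_age", "exit_age", "died") %in% names(registry))) {
    records <- prepare_survival(cohort, registry)
    if (sum(records$event) > 0 &&
        all(table(records$subtype[records$event == 1]) >= 0)) {
      fit_warnings <- character()
      fit <- tryCatch(
        withCallingHandlers(
          fit_cox(records),
          warning = function(w) {
            fit_warnings <<- c(fit_warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
          }),
        error = function(e) NULL)
      if (!is.null(fit)) {
        jsonlite::write_json(fit$estimates,
                             file.path(outdir, "hazards.json"),
                             auto_unbox = TRUE, digits = NA)
        summary$survive <- list(
          n_records = nrow(records),
          n_events = sum(records$event),
          terms = fit$estimates$term,
          warnings = fit_warnings)
      }
    }
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
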