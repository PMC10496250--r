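# Reading and writing the pipeline's tabular artifacts: notes, labs,
# registry, mention audit trails. Schema validation is strict: malformed
# records are reported with their record index rather than silently dropped.

audit_columns <- c(
  "patient_id", "note_id", "note_date", "sentence", "span_start", "span_end",
  "source_kind", "raw_value_low", "raw_value_high", "resolved_value",
  "status", "reject_reason"
)

#' Read clinical notes from JSONL or CSV
#'
#' Each record must carry `patient_id`, `note_id`, `note_date` (ISO-8601)
#' and `text`. Missing fields or unparseable dates raise a schema error
#' naming the field and the 1-based record index.
#'
#' @param path path to the notes file.
#' @param format `"jsonl"` (one JSON object per line), `"csv"`, or `"auto"`
#'   (by file extension, default).
#' @return tibble with columns `patient_id`, `note_id`, `note_date` (Date),
#'   `text`, in file order.
#' @export
read_notes <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_efminer("notes file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  required <- c("patient_id", "note_id", "note_date", "text")

  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(tibble(patient_id = character(), note_id = character(),
                    note_date = as.Date(character()), text = character()))
    }
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        abort_efminer("notes record ", i, ": invalid JSON (",
                                      conditionMessage(e), ")")
                      })
      miss <- setdiff(required, names(rec))
      if (length(miss) > 0) {
        abort_efminer("notes record ", i, ": missing field '", miss[1], "'")
      }
      recs[[i]] <- tibble(
        patient_id = as.character(rec$patient_id),
        note_id = as.character(rec$note_id),
        note_date_raw = as.character(rec$note_date),
        text = as.character(rec$text)
      )
    }
    df <- bind_rows(recs)
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    miss <- setdiff(required, names(df))
    if (length(miss) > 0) {
      abort_efminer("notes file missing column '", miss[1], "'")
    }
    df <- tibble(
      patient_id = df$patient_id, note_id = df$note_id,
      note_date_raw = df$note_date,
      text = ifelse(is.na(df$text), "", df$text)
    )
  }

  for (fld in c("patient_id", "note_id")) {
    bad <- which(is.na(df[[fld]]) | !nzchar(df[[fld]]))
    if (length(bad) > 0) {
      abort_efminer("notes record ", bad[1], ": missing field '", fld, "'")
    }
  }
  dates <- parse_iso_date(df$note_date_raw)
  bad <- which(is.na(dates))
  if (length(bad) > 0) {
    abort_efminer("notes record ", bad[1], ": unparseable note_date '",
                  df$note_date_raw[bad[1]], "' (expected ISO-8601)")
  }
  tibble(patient_id = df$patient_id, note_id = df$note_id,
         note_date = dates, text = df$text)
}

# default analyte name normalisation
default_analyte_map <- function() {
  c("probnp" = "probnp", "nt-probnp" = "probnp", "ntprobnp" = "probnp",
    "nt_probnp" = "probnp", "bnp-prohormone" = "probnp",
    "creatinine" = "creatinine", "krea" = "creatinine",
    "s-krea" = "creatinine")
}

# unit -> multiplicative factor to the canonical unit, per analyte.
# Canonical: proBNP ng/l (= pg/ml), creatinine umol/l.
default_unit_map <- function() {
  list(
    probnp = c("ng/l" = 1, "pg/ml" = 1),
    creatinine = c("umol/l" = 1, "µmol/l" = 1, "mg/dl" = 88.42)
  )
}

#' Read structured laboratory results
#'
#' Expects CSV with columns `patient_id`, `sample_date`, `analyte`,
#' `value`, `unit`. Analyte names are normalised to `probnp` /
#' `creatinine`; values are converted to canonical units (proBNP ng/l,
#' creatinine µmol/l; creatinine in mg/dl is multiplied by 88.42).
#' Rows with analytes outside the map are skipped and counted in the
#' `skipped_analytes` attribute with a warning; an unknown unit for a known
#' analyte is an error.
#'
#' @param path path to the labs CSV.
#' @param unit_map optional list of named conversion-factor vectors per
#'   analyte, overriding [the defaults][read_labs].
#' @param analyte_map optional named character vector mapping source analyte
#'   names (lower case) to `"probnp"` / `"creatinine"`.
#' @return tibble `patient_id`, `sample_date` (Date), `analyte`, `value`,
#'   `unit` (canonical), with attribute `skipped_analytes` (count).
#' @export
read_labs <- function(path, unit_map = NULL, analyte_map = NULL) {
  if (!file.exists(path)) abort_efminer("labs file not found: ", path)
  unit_map <- unit_map %||% default_unit_map()
  analyte_map <- analyte_map %||% default_analyte_map()

  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("patient_id", "sample_date", "analyte", "value", "unit")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) abort_efminer("labs file missing column '", miss[1], "'")

  analyte <- unname(analyte_map[tolower(trimws(df$analyte))])
  skipped <- sum(is.na(analyte))
  if (skipped > 0) {
    warning(skipped, " lab row(s) with unmapped analyte skipped",
            call. = FALSE)
  }
  keep <- !is.na(analyte)
  df <- df[keep, , drop = FALSE]
  analyte <- analyte[keep]

  value <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(value) | value < 0)) {
    abort_efminer("labs: non-numeric or negative value at row ",
                  which(is.na(value) | value < 0)[1])
  }
  dates <- parse_iso_date(df$sample_date)
  if (any(is.na(dates))) {
    abort_efminer("labs: unparseable sample_date at row ",
                  which(is.na(dates))[1])
  }

  unit <- tolower(trimws(df$unit))
  canonical <- c(probnp = "ng/l", creatinine = "umol/l")
  out_value <- numeric(length(value))
  for (i in seq_along(value)) {
    factors <- unit_map[[analyte[i]]]
    if (!unit[i] %in% names(factors)) {
      abort_efminer("labs: unknown unit '", df$unit[i], "' for analyte '",
                    analyte[i], "' at row ", i)
    }
    out_value[i] <- value[i] * factors[[unit[i]]]
  }

  out <- tibble(
    patient_id = df$patient_id, sample_date = dates,
    analyte = analyte, value = out_value,
    unit = unname(canonical[analyte])
  )
  attr(out, "skipped_analytes") <- skipped
  out
}

#' Read a patient registry table
#'
#' CSV with columns `patient_id`, `sex` (`female`/`male`), `birth_date`
#' (ISO-8601), comorbidity flags (`hypertension`, `ihd`, `t2d`, `copd`,
#' `renal_failure`; 0/1 or TRUE/FALSE), and — when follow-up is available —
#' `entry_age`, `exit_age` (years) and `died` (0/1).
#'
#' @param path path to the registry CSV.
#' @return tibble with typed columns; follow-up columns present only when in
#'   the file.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) abort_efminer("registry file not found: ", path)
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("patient_id", "sex", "birth_date")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort_efminer("registry file missing column '", miss[1], "'")
  }
  sex <- tolower(trimws(df$sex))
  if (any(!sex %in% c("female", "male"))) {
    abort_efminer("registry: sex must be 'female' or 'male' (row ",
                  which(!sex %in% c("female", "male"))[1], ")")
  }
  out <- tibble(patient_id = df$patient_id, sex = sex,
                birth_date = parse_iso_date(df$birth_date))
  if (any(is.na(out$birth_date))) {
    abort_efminer("registry: unparseable birth_date at row ",
                  which(is.na(out$birth_date))[1])
  }
  as_flag <- function(x) {
    v <- tolower(trimws(x))
    out <- v %in% c("1", "true", "t", "yes")
    bad <- !v %in% c("1", "true", "t", "yes", "0", "false", "f", "no")
    if (any(bad)) abort_efminer("registry: non-boolean flag value '",
                                x[which(bad)[1]], "'")
    out
  }
  for (fl in c("hypertension", "ihd", "t2d", "copd", "renal_failure")) {
    if (fl %in% names(df)) out[[fl]] <- as_flag(df[[fl]])
  }
  for (ag in c("entry_age", "exit_age")) {
    if (ag %in% names(df)) out[[ag]] <- as.numeric(df[[ag]])
  }
  if ("died" %in% names(df)) out$died <- as_flag(df$died)
  out
}

#' Write / read the EF-mention audit trail
#'
#' One CSV row per candidate mention — accepted or rejected — with the
#' source sentence, character span, raw/resolved values, status and reject
#' reason. `read_audit()` is the exact inverse: the pair round-trips
#' losslessly.
#'
#' @param mentions tibble of mentions from [extract_mentions()] /
#'   [mine_notes()].
#' @param path output CSV path.
#' @return `write_audit()`: the path, invisibly. `read_audit()`: the
#'   mentions tibble.
#' @export
write_audit <- function(mentions, path) {
  df <- mentions[, audit_columns, drop = FALSE]
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_audit
#' @export
read_audit <- function(path) {
  if (!file.exists(path)) abort_efminer("audit file not found: ", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = "c", note_id = "c", note_date = readr::col_date(),
    sentence = "c", span_start = "i", span_end = "i", source_kind = "c",
    raw_value_low = "d", raw_value_high = "d", resolved_value = "d",
    status = "c", reject_reason = "c"
  ), progress = FALSE)
  miss <- setdiff(audit_columns, names(df))
  if (length(miss) > 0) {
    abort_efminer("audit file missing column '", miss[1], "'")
  }
  df$sentence[is.na(df$sentence)] <- ""
  as_tibble(df[, audit_columns])
}
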