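# Consolidation of accepted mentions into per-patient, per-date EF
# measurements: same-date averaging, outlier removal, index selection.

#' Average accepted EF mentions within each patient-day
#'
#' Groups accepted mentions by `(patient_id, note_date)` and takes the
#' arithmetic mean of the resolved values — several readings observed on the
#' same date collapse into one measurement.
#'
#' @param mentions tibble of accepted EF mentions (every row must have
#'   `status == "accepted"`).
#' @return tibble `patient_id`, `measure_date`, `ef_percent`, `n_mentions`,
#'   ordered by patient then date.
#' @export
daily_mean <- function(mentions) {
  if (nrow(mentions) > 0 && any(mentions$status != "accepted")) {
    abort_efminer("daily_mean: all mentions must be accepted; filter first")
  }
  if (nrow(mentions) == 0) {
    return(tibble(patient_id = character(),
                  measure_date = as.Date(character()),
                  ef_percent = numeric(), n_mentions = integer()))
  }
  mentions |>
    group_by(patient_id = .data$patient_id,
             measure_date = .data$note_date) |>
    summarise(ef_percent = mean(.data$resolved_value),
              n_mentions = dplyr::n(), .groups = "drop") |>
    arrange(.data$patient_id, .data$measure_date)
}

#' Remove EF outliers outside the plausible band
#'
#' Measurements strictly below 10% or strictly above 90% are removed; the
#' boundary values 10 and 90 themselves are kept. Removals are recorded in
#' the `removed` attribute (patient and date) for auditing.
#'
#' @param measurements tibble from [daily_mean()].
#' @param lower,upper inclusive bounds (defaults 10 and 90).
#' @return the filtered tibble, with attribute `removed`.
#' @export
filter_outliers <- function(measurements, lower = 10, upper = 90) {
  keep <- measurements$ef_percent >= lower & measurements$ef_percent <= upper
  out <- measurements[keep, , drop = FALSE]
  attr(out, "removed") <-
    measurements[!keep, c("patient_id", "measure_date", "ef_percent"),
                 drop = FALSE]
  out
}

#' Select one index EF measurement per patient
#'
#' The index EF is the single measurement that represents the patient's
#' state for subtyping. Policies: `"latest"` (default — subtype reflects the
#' most recent assessment), `"earliest"`, or `"nearest"` to a reference date
#' (ties broken toward the earlier date).
#'
#' @param measurements tibble from [filter_outliers()] (any patients).
#' @param policy `"latest"`, `"earliest"` or `"nearest"`.
#' @param ref_date reference `Date`, required for `policy = "nearest"`.
#' @return tibble with one row per patient that has at least one
#'   measurement; patients without measurements are simply absent.
#' @export
select_index_ef <- function(measurements, policy = "latest", ref_date = NULL) {
  if (!policy %in% c("latest", "earliest", "nearest")) {
    abort_efminer("unknown index policy: '", policy, "'")
  }
  if (nrow(measurements) == 0) return(measurements)
  if (policy == "latest") {
    out <- measurements |> group_by(.data$patient_id) |>
      slice_max(.data$measure_date, n = 1, with_ties = FALSE) |> ungroup()
  } else if (policy == "earliest") {
    out <- measurements |> group_by(.data$patient_id) |>
      slice_min(.data$measure_date, n = 1, with_ties = FALSE) |> ungroup()
  } else {
    if (is.null(ref_date)) {
      abort_efminer("policy 'nearest' requires a reference date")
    }
    out <- measurements |>
      mutate(.dist = abs(as.numeric(.data$measure_date - as.Date(ref_date)))) |>
      arrange(.data$patient_id, .data$.dist, .data$measure_date) |>
      group_by(.data$patient_id) |>
      dplyr::slice(1) |> ungroup() |> select(-".dist")
  }
  arrange(out, .data$patient_id)
}
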