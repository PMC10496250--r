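# Cox proportional-hazards modelling of all-cause mortality by HF subtype
# with age as the time scale (left truncation at entry age), and the
# Schoenfeld-residual proportionality check.

#' Prepare per-patient survival records
#'
#' Merges the subtyped cohort with registry follow-up (entry age, exit age,
#' death indicator), drops `Indeterminate` patients (no adjudicated
#' subtype), encodes subtype as a factor with `NoHF` as the reference, and
#' rejects records with `exit_age <= entry_age` (listing their ids in a
#' warning and the log).
#'
#' @param cohort tibble from [build_cohort()].
#' @param registry registry tibble from [read_registry()] with `entry_age`,
#'   `exit_age`, `died` and comorbidity flags.
#' @return tibble `patient_id`, `entry_age`, `exit_age`, `event`,
#'   `subtype` (factor, reference NoHF), `sex`, `egfr` and the five
#'   comorbidity flags present in the registry; attribute `log` holds
#'   `n_indeterminate` and `n_rejected_followup`.
#' @export
prepare_survival <- function(cohort, registry) {
  need <- c("patient_id", "entry_age", "exit_age", "died")
  miss <- setdiff(need, names(registry))
  if (length(miss) > 0) {
    abort_efminer("registry lacks follow-up column '", miss[1], "'")
  }
  flags <- intersect(c("hypertension", "ihd", "t2d", "copd", "renal_failure"),
                     names(registry))
  reg <- registry[, c(need, flags), drop = FALSE]
  merged <- dplyr::inner_join(cohort, reg, by = "patient_id")

  log <- list(n_indeterminate = sum(merged$subtype == "Indeterminate"))
  merged <- merged[merged$subtype != "Indeterminate", , drop = FALSE]

  bad <- is.na(merged$exit_age) | is.na(merged$entry_age) |
    merged$exit_age <= merged$entry_age
  log$n_rejected_followup <- sum(bad)
  if (any(bad)) {
    warning("rejected ", sum(bad), " record(s) with exit_age <= entry_age: ",
            paste(utils::head(merged$patient_id[bad], 5), collapse = ", "),
            call. = FALSE)
    merged <- merged[!bad, , drop = FALSE]
  }

  out <- tibble(
    patient_id = merged$patient_id,
    entry_age = merged$entry_age,
    exit_age = merged$exit_age,
    event = as.integer(merged$died),
    subtype = factor(merged$subtype,
                     levels = c("NoHF", "HFrEF", "HFmrEF", "HFpEF")),
    sex = factor(merged$sex, levels = c("female", "male")),
    egfr = merged$egfr
  )
  for (fl in flags) out[[fl]] <- merged[[fl]]
  attr(out, "log") <- log
  out
}

#' Fit the age-scale Cox proportional-hazards model
#'
#' Partial-likelihood fit of all-cause mortality on HF subtype (three
#' indicators against the NoHF reference) plus covariates, with age as the
#' time scale: left truncation at `entry_age`, right censoring at
#' `exit_age`, `survival::coxph` as the backend, Efron tie handling by
#' default. 95% CIs come from the asymptotic normal approximation on the
#' log-hazard scale.
#'
#' @param records tibble from [prepare_survival()].
#' @param covariates character vector of covariate column names to adjust
#'   for (default: sex, eGFR and the five comorbidity flags, where
#'   present).
#' @param ties tie-handling method passed to [survival::coxph()].
#' @return list of class `ef_cox`: `fit` (the `coxph` object) and
#'   `estimates`, a tibble with `term`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, `n_events` per model term.
#' @export
fit_cox <- function(records,
                    covariates = intersect(
                      c("sex", "egfr", "hypertension", "ihd", "t2d", "copd",
                        "renal_failure"), names(records)),
                    ties = "efron") {
  if (sum(records$event) == 0) abort_efminer("fit_cox: no events in data")
  for (st in c("HFrEF", "HFmrEF", "HFpEF")) {
    rows <- records$subtype == st
    if (any(rows) && sum(records$event[rows]) == 0) {
      abort_efminer("fit_cox: no events for modelled term 'subtype", st, "'")
    }
  }
  rhs <- paste(c("subtype", covariates), collapse = " + ")
  fml <- stats::as.formula(
    paste0("survival::Surv(entry_age, exit_age, event) ~ ", rhs))
  fit <- survival::coxph(fml, data = records, ties = ties)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort_efminer("fit_cox: inestimable term(s): ",
                  paste(bad, collapse = ", "))
  }
  conv <- fit$info
  if (!is.null(conv) && "convergence" %in% names(conv) &&
      conv[["convergence"]] != 0) {
    abort_efminer("fit_cox: model did not converge")
  }
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(abs(stats::coef(fit)) > 15)) {
    bad <- names(stats::coef(fit))[abs(stats::coef(fit)) > 15][1]
    abort_efminer("fit_cox: apparent separation for term '", bad, "'")
  }

  beta <- stats::coef(fit)
  term_events <- vapply(names(beta), function(tm) {
    if (startsWith(tm, "subtype")) {
      st <- sub("^subtype", "", tm)
      sum(records$event[records$subtype == st])
    } else {
      sum(records$event)
    }
  }, numeric(1))
  estimates <- tibble(
    term = names(beta),
    log_hr = unname(beta),
    se = unname(se),
    hazard_ratio = exp(unname(beta)),
    ci_low = exp(unname(beta) - 1.96 * unname(se)),
    ci_high = exp(unname(beta) + 1.96 * unname(se)),
    n_events = as.integer(term_events)
  )
  structure(list(fit = fit, estimates = estimates), class = "ef_cox")
}

#' @export
print.ef_cox <- function(x, ...) {
  cat("<ef_cox> age-scale Cox model,", x$fit$nevent, "events\n")
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-22s HR %5.2f (95%% CI %5.2f-%5.2f)\n",
                est$term[i], est$hazard_ratio[i], est$ci_low[i],
                est$ci_high[i]))
  }
  invisible(x)
}

#' Schoenfeld-residual proportionality check
#'
#' Scaled Schoenfeld residuals against event age (identity time transform)
#' with the standard per-term linear-trend score test, via
#' [survival::cox.zph()]. The residual table has one row per event time and
#' term, ready for plotting.
#'
#' @param fit an `ef_cox` object from [fit_cox()].
#' @return list: `residuals` (tibble `event_age`, `term`, `residual`) and
#'   `tests` (tibble `term`, `chisq`, `df`, `p`).
#' @export
schoenfeld_check <- function(fit) {
  if (!inherits(fit, "ef_cox")) abort_efminer("expected an ef_cox object")
  if (fit$fit$nevent == 0) abort_efminer("no events: residuals undefined")
  zph <- survival::cox.zph(fit$fit, transform = "identity", terms = FALSE)
  resid <- as.matrix(zph$y)
  res_tbl <- tibble(
    event_age = rep(as.numeric(zph$x), ncol(resid)),
    term = rep(colnames(resid), each = nrow(resid)),
    residual = as.vector(resid)
  )
  tab <- zph$table
  tab <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
  tests <- tibble(
    term = rownames(tab),
    chisq = tab[, "chisq"],
    df = tab[, "df"],
    p = tab[, "p"]
  )
  list(residuals = res_tbl, tests = tests)
}
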