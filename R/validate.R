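# Validation against a gold standard: 4-class confusion matrix,
# one-vs-rest diagnostic metrics (including the HF-any collapse), and
# EF value agreement.

#' Build the 4-class algorithm-vs-gold confusion matrix
#'
#' Rows are the algorithm's labels, columns the gold-standard (clinician)
#' labels, over `HFrEF`, `HFmrEF`, `HFpEF`, `NoHF`. The two inputs must
#' cover the same patients. Algorithm-side `Indeterminate` patients are
#' excluded (validation mirrors a setting where proBNP was available) and
#' counted in the `n_excluded_indeterminate` attribute.
#'
#' @param pred tibble with `patient_id` and `subtype` (algorithm).
#' @param gold tibble with `patient_id` and `subtype` (gold standard).
#' @return an `ef_confusion` object: list with `labels`, `counts` (4x4
#'   integer matrix) and `n`.
#' @export
build_confusion <- function(pred, gold) {
  only_pred <- setdiff(pred$patient_id, gold$patient_id)
  only_gold <- setdiff(gold$patient_id, pred$patient_id)
  if (length(only_pred) > 0 || length(only_gold) > 0) {
    abort_efminer(
      "pred/gold patient sets differ: ",
      paste(utils::head(c(only_pred, only_gold), 5), collapse = ", "))
  }
  if (anyDuplicated(pred$patient_id) || anyDuplicated(gold$patient_id)) {
    abort_efminer("duplicate patient_id in pred or gold")
  }
  merged <- left_join(pred, gold, by = "patient_id",
                      suffix = c("_pred", "_gold"))
  n_ind <- sum(merged$subtype_pred == "Indeterminate")
  merged <- merged[merged$subtype_pred != "Indeterminate", , drop = FALSE]

  labels <- hf_labels()
  bad <- !merged$subtype_pred %in% labels | !merged$subtype_gold %in% labels
  if (any(bad)) {
    abort_efminer("labels outside the 4-class set for patient(s): ",
                  paste(utils::head(merged$patient_id[bad], 5),
                        collapse = ", "))
  }
  counts <- table(factor(merged$subtype_pred, levels = labels),
                  factor(merged$subtype_gold, levels = labels))
  counts <- matrix(as.integer(counts), nrow = 4, dimnames = dimnames(counts))
  out <- structure(
    list(labels = labels, counts = counts, n = sum(counts)),
    class = "ef_confusion")
  attr(out, "n_excluded_indeterminate") <- n_ind
  out
}

#' Construct an `ef_confusion` object from a counts matrix
#'
#' @param counts 4x4 non-negative integer matrix, rows = algorithm label,
#'   columns = gold label, in the order HFrEF, HFmrEF, HFpEF, NoHF.
#' @return an `ef_confusion` object.
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4, 4)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort_efminer("counts must be a 4x4 non-negative integer matrix")
  }
  labels <- hf_labels()
  dimnames(counts) <- list(labels, labels)
  structure(list(labels = labels,
                 counts = matrix(as.integer(counts), 4,
                                 dimnames = dimnames(counts)),
                 n = sum(counts)),
            class = "ef_confusion")
}

#' @export
print.ef_confusion <- function(x, ...) {
  cat("<ef_confusion> n =", x$n, "(rows: algorithm, cols: gold)\n")
  print(x$counts)
  invisible(x)
}

collapse_binary <- function(cm, target) {
  pos_rows <- if (target == "HF-any") {
    c("HFrEF", "HFmrEF", "HFpEF")
  } else {
    target
  }
  pos <- rownames(cm$counts) %in% pos_rows
  tp <- sum(cm$counts[pos, pos, drop = FALSE])
  fp <- sum(cm$counts[pos, !pos, drop = FALSE])
  fn <- sum(cm$counts[!pos, pos, drop = FALSE])
  tn <- sum(cm$counts[!pos, !pos, drop = FALSE])
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Diagnostic metrics for one class (or the HF-any collapse)
#'
#' One-vs-rest collapse of the confusion matrix; for `"HF-any"`, positive
#' means any of HFrEF/HFmrEF/HFpEF. Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN), accuracy = (TP+TN)/n,
#' all as percents at full precision; a zero denominator yields `NA`
#' (undefined, never reported as 0). Use [round_half_up()] for display at
#' integer precision.
#'
#' @param cm an `ef_confusion` object.
#' @param target one of `"HFrEF"`, `"HFmrEF"`, `"HFpEF"`, `"NoHF"`,
#'   `"HF-any"`.
#' @return one-row tibble: `class`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (percents in `[0, 100]`).
#' @export
class_metrics <- function(cm, target) {
  if (cm$n == 0) abort_efminer("class_metrics: empty confusion matrix")
  if (!target %in% c(cm$labels, "HF-any")) {
    abort_efminer("unknown target class: '", target, "'")
  }
  ct <- collapse_binary(cm, target)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble(
    class = target,
    tp = ct[["tp"]], fp = ct[["fp"]], fn = ct[["fn"]], tn = ct[["tn"]],
    sensitivity = ratio(ct[["tp"]], ct[["tp"]] + ct[["fn"]]),
    specificity = ratio(ct[["tn"]], ct[["tn"]] + ct[["fp"]]),
    ppv = ratio(ct[["tp"]], ct[["tp"]] + ct[["fp"]]),
    npv = ratio(ct[["tn"]], ct[["tn"]] + ct[["fn"]]),
    accuracy = ratio(ct[["tp"]] + ct[["tn"]], cm$n)
  )
}

#' Metrics for all four classes plus HF-any
#'
#' @param cm an `ef_confusion` object.
#' @return tibble with five rows (HF-any first), as in [class_metrics()].
#' @export
all_class_metrics <- function(cm) {
  bind_rows(lapply(c("HF-any", cm$labels), function(t) class_metrics(cm, t)))
}

ef_band <- function(ef, edges = c(40, 50)) {
  findInterval(ef, edges)   # 0: reduced, 1: mildly reduced, 2: preserved
}

#' EF value agreement between algorithm and gold standard
#'
#' Reports three paired-agreement proportions: exact match, absolute
#' difference within `tolerance` EF percentage points (default 5), and
#' same ESC band (`< 40`, `40-49`, `>= 50`).
#'
#' @param algo_ef,gold_ef paired numeric EF vectors (same patients, same
#'   order).
#' @param tolerance agreement tolerance in EF percentage points.
#' @param band_edges EF band edges (default `c(40, 50)`).
#' @return an `ef_agreement` object: list with `n`, `exact`,
#'   `within_tolerance`, `same_band` (proportions in `[0, 1]`) and
#'   `tolerance`.
#' @export
ef_agreement <- function(algo_ef, gold_ef, tolerance = 5,
                         band_edges = c(40, 50)) {
  if (length(algo_ef) != length(gold_ef)) {
    abort_efminer("ef_agreement: inputs must be paired (equal length)")
  }
  if (length(algo_ef) == 0) abort_efminer("ef_agreement: empty pairing")
  structure(list(
    n = length(algo_ef),
    exact = mean(algo_ef == gold_ef),
    within_tolerance = mean(abs(algo_ef - gold_ef) <= tolerance),
    same_band = mean(ef_band(algo_ef, band_edges) ==
                       ef_band(gold_ef, band_edges)),
    tolerance = tolerance
  ), class = "ef_agreement")
}

#' @export
print.ef_agreement <- function(x, ...) {
  cat("<ef_agreement> n =", x$n, "\n")
  cat(sprintf("  exact match:     %g%%\n", round_half_up(100 * x$exact)))
  cat(sprintf("  within %g points: %g%%\n", x$tolerance,
              round_half_up(100 * x$within_tolerance)))
  cat(sprintf("  same EF band:    %g%%\n", round_half_up(100 * x$same_band)))
  invisible(x)
}
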