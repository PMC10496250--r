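# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive expected values by routes different from the
# package implementation.

# Published 100-patient validation matrix (rows: algorithm label, columns:
# gold label, order HFrEF/HFmrEF/HFpEF/NoHF) and its printed per-class
# metrics (sensitivity, specificity, PPV, NPV, accuracy; integer percent).
validation_matrix_counts <- function() {
  matrix(c(17, 0, 0, 0,
           1, 17, 1, 1,
           0, 0, 27, 24,
           0, 0, 0, 12),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("HFrEF", "HFmrEF", "HFpEF", "NoHF"),
                         c("HFrEF", "HFmrEF", "HFpEF", "NoHF")))
}

validation_printed_metrics <- function() {
  rbind(
    "HF-any" = c(100, 32, 72, 100, 75),
    "HFrEF"  = c(94, 100, 100, 99, 99),
    "HFmrEF" = c(100, 96, 85, 100, 97),
    "HFpEF"  = c(96, 67, 53, 98, 75),
    "NoHF"   = c(32, 100, 100, 72, 75)
  )
}

# Brute-force one-vs-rest 2x2 collapse: iterate the cells of the matrix and
# tally each patient one at a time.
oracle_binary_metrics <- function(counts, positive_rows) {
  tp <- fp <- fn <- tn <- 0
  for (i in rownames(counts)) {
    for (j in colnames(counts)) {
      k <- counts[i, j]
      pred_pos <- i %in% positive_rows
      gold_pos <- j %in% positive_rows
      if (pred_pos && gold_pos) tp <- tp + k
      else if (pred_pos && !gold_pos) fp <- fp + k
      else if (!pred_pos && gold_pos) fn <- fn + k
      else tn <- tn + k
    }
  }
  div <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  c(sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
    accuracy = div(tp + tn, sum(counts)))
}

# Independent coding of the subtyping rule text, written as a literal
# decision list rather than vectorised arithmetic.
oracle_subtype <- function(ef, probnp) {
  if (ef < 40) return("HFrEF")
  if (ef < 50) return("HFmrEF")
  if (is.na(probnp)) return("Indeterminate")
  if (probnp > 125) return("HFpEF")
  "NoHF"
}

# One-row note constructor
make_note <- function(text, patient_id = "p1", note_id = "n1",
                      note_date = as.Date("2019-03-02")) {
  list(patient_id = patient_id, note_id = note_id, note_date = note_date,
       text = text)
}

# Mention tibble builder for aggregator/audit tests
make_mentions <- function(patient_id, note_date, value,
                          status = "accepted",
                          reject_reason = "none",
                          source_kind = "numeric") {
  n <- max(length(patient_id), length(note_date), length(value))
  tibble::tibble(
    patient_id = rep_len(patient_id, n),
    note_id = paste0("n", seq_len(n)),
    note_date = rep_len(as.Date(note_date), n),
    sentence = paste0("EF ", rep_len(value, n), "%"),
    span_start = 3L, span_end = 6L,
    source_kind = rep_len(source_kind, n),
    raw_value_low = rep_len(value, n),
    raw_value_high = rep_len(value, n),
    resolved_value = rep_len(value, n),
    status = rep_len(status, n),
    reject_reason = rep_len(reject_reason, n)
  )
}
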