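#' Apoptosis-rate summary (flow-cytometry reporting)
#'
#' Totals late and early apoptosis percentages per group, reported to two
#' decimals — the arithmetic behind a standard apoptosis-rate table.
#'
#' @param records Data frame with columns `group`, `late` and `early`
#'   (percentages in `[0, 100]`); an optional `viable` column is carried
#'   through.
#' @return Tibble: group, late, early, total (= late + early, 2 dp),
#'   viable (if given), in input order.
#' @examples
#' summarize_apoptosis(data.frame(group = "LN", late = 19.78, early = 4.45))
#' @export
summarize_apoptosis <- function(records) {
  records <- tibble::as_tibble(records)
  if (!all(c("group", "late", "early") %in% names(records)))
    abort("records need columns group, late, early")
  rates <- c(records$late, records$early)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 100))
    abort("rates must lie in [0, 100]")
  out <- tibble(group = records$group,
                late = records$late,
                early = records$early,
                total = round(records$late + records$early, 2))
  if ("viable" %in% names(records)) out$viable <- records$viable
  out
}

#' Differential-expression count line
#'
#' Formats up/down counts as "N (U upregulated and D downregulated)".
#'
#' @param de A DE tibble with a `call` column.
#' @return A string.
#' @export
de_summary <- function(de) {
  up <- sum(de$call == "up")
  down <- sum(de$call == "down")
  sprintf("%d (%d upregulated and %d downregulated)", up + down, up, down)
}

#' Recovery of planted ceRNA triples
#'
#' Precision, recall and F1 of the emitted (circRNA, miRNA, mRNA) triples
#' against the planted ground truth, on exact identity matches.
#'
#' @param triples A `spng_triples` tibble (columns circ, mirna, mrna).
#' @param truth A ground-truth list with a `planted_triples` tibble.
#' @return List: n_emitted, n_true, n_matched, precision, recall, f1.
#' @export
evaluate_recovery <- function(triples, truth) {
  key <- function(d) paste(d$circ, d$mirna, d$mrna, sep = "|")
  emitted <- unique(key(triples))
  planted <- unique(key(truth$planted_triples))
  hit <- length(intersect(emitted, planted))
  precision <- if (length(emitted) > 0) hit / length(emitted) else NA_real_
  recall <- if (length(planted) > 0) hit / length(planted) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  list(n_emitted = length(emitted), n_true = length(planted),
       n_matched = hit, precision = precision, recall = recall, f1 = f1)
}
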