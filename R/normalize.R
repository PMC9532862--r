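#' Per-layer abundance normalization: RPM, TPM and FPKM
#'
#' The three measures used to quantify the three RNA layers: reads per
#' million mapped reads (`rpm()`, circRNA), transcripts per million
#' (`tpm()`, miRNA), and fragments per kilobase per million mapped reads
#' (`fpkm()`, mRNA). The per-sample total of assigned reads (column sum)
#' serves as the mapped-read denominator, and the effective length is the
#' given length — choices documented in the methods vignette.
#'
#' Definitions, per feature i and sample j with count c_ij, column total
#' N_j and length L_i (nt):
#' \itemize{
#'   \item RPM_ij  = c_ij * 1e6 / N_j              (columns sum to 1e6)
#'   \item TPM_ij  = r_ij * 1e6 / sum_i r_ij, with r_ij = c_ij / L_i
#'                                                  (columns sum to 1e6)
#'   \item FPKM_ij = c_ij * 1e9 / (L_i * N_j)      (no column-sum constraint)
#' }
#'
#' @param counts A raw-count [expr_matrix()].
#' @param lengths Named vector of effective feature lengths in nucleotides
#'   (required for TPM/FPKM; every feature must be present).
#' @return A `spng_expr` in the corresponding unit.
#' @examples
#' m <- expr_matrix(matrix(c(25, 75), 2, 1,
#'        dimnames = list(c("a", "b"), "s1")), layer = "circRNA")
#' rpm(m)
#' @export
rpm <- function(counts) {
  assert_raw_counts(counts)
  v <- expr_values(counts)
  cs <- colSums(v)
  if (any(cs == 0)) abort("zero column sum: cannot compute RPM")
  out <- sweep(v, 2, cs, "/") * 1e6
  rebuild_expr(counts, out, "RPM")
}

#' @rdname rpm
#' @export
tpm <- function(counts, lengths) {
  assert_raw_counts(counts)
  v <- expr_values(counts)
  L <- match_lengths(lengths, rownames(v))
  rate <- v / L
  rs <- colSums(rate)
  if (any(rs == 0)) abort("zero length-normalized rate sum: cannot compute TPM")
  out <- sweep(rate, 2, rs, "/") * 1e6
  rebuild_expr(counts, out, "TPM")
}

#' @rdname rpm
#' @export
fpkm <- function(counts, lengths) {
  assert_raw_counts(counts)
  v <- expr_values(counts)
  cs <- colSums(v)
  if (any(cs == 0)) abort("zero column sum: cannot compute FPKM")
  L <- match_lengths(lengths, rownames(v))
  out <- sweep(v / L, 2, cs, "/") * 1e9
  rebuild_expr(counts, out, "FPKM")
}

match_lengths <- function(lengths, features) {
  if (is.null(names(lengths))) abort("lengths must be a named vector")
  missing <- setdiff(features, names(lengths))
  if (length(missing))
    abort(sprintf("missing lengths for %d feature(s), e.g. %s",
                  length(missing), missing[1]))
  L <- as.numeric(lengths[features])
  if (any(!is.finite(L)) || any(L < 1)) abort("lengths must be >= 1")
  L
}

rebuild_expr <- function(template, values, unit) {
  tbl <- tibble::tibble(feature = rownames(values), !!!as.data.frame(values))
  new_spng_expr(tbl, unit, expr_layer(template))
}

#' Drop weakly expressed features
#'
#' Keeps features whose value is at least `min_value` in at least
#' `min_samples` samples; row order is preserved. Defaults keep everything
#' (no silent filtering).
#'
#' @param x A `spng_expr` in any unit.
#' @param min_value,min_samples Non-negative thresholds.
#' @return The filtered `spng_expr`.
#' @export
filter_low_expression <- function(x, min_value = 0, min_samples = 0) {
  if (min_value < 0 || min_samples < 0) abort("thresholds must be >= 0")
  v <- expr_values(x)
  if (min_samples > ncol(v))
    abort("min_samples exceeds the number of samples")
  keep <- rowSums(v >= min_value) >= min_samples
  new_spng_expr(x[keep, , drop = FALSE], expr_unit(x), expr_layer(x))
}

#' Normalize one layer with its conventional unit
#'
#' circRNA counts are scaled to RPM, miRNA counts to TPM and mRNA counts to
#' FPKM, mirroring how the three layers are conventionally quantified.
#'
#' @inheritParams rpm
#' @return A normalized `spng_expr`.
#' @export
normalize_layer <- function(counts, lengths = NULL) {
  switch(expr_layer(counts),
    circRNA = rpm(counts),
    miRNA   = tpm(counts, lengths),
    mRNA    = fpkm(counts, lengths))
}
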