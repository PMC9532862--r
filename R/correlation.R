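#' Spearman and Pearson correlation with an explicit undefined marker
#'
#' Thin wrappers around [stats::cor()] that enforce the pipeline's
#' contracts: paired finite vectors of length >= 3, and `NA` (never a
#' number) when either vector is constant, so undefined correlations can
#' never pass a filter. Spearman uses midranks for ties.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' spearman_cor(c(1, 2, 3), c(3, 2, 1))   # -1
#' pearson_cor(c(1, 2, 3), 2 * c(1, 2, 3))  # 1
#' @export
spearman_cor <- function(x, y) {
  check_cor_input(x, y)
  if (constant_vec(x) || constant_vec(y)) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' @rdname spearman_cor
#' @export
pearson_cor <- function(x, y) {
  check_cor_input(x, y)
  if (constant_vec(x) || constant_vec(y)) return(NA_real_)
  cor(x, y, method = "pearson")
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) abort("vectors differ in length")
  if (length(x) < 3) abort("need >= 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("non-finite values")
}

constant_vec <- function(x) diff(range(x)) == 0

#' Log-scale expression for correlation filtering
#'
#' Correlations are computed on log2(normalized + 1) values restricted to
#' the samples of the comparison at hand.
#'
#' @param x A normalized `spng_expr`.
#' @param samples Sample ids to keep.
#' @return A numeric matrix (features x samples) of log2 values.
#' @export
log_expression <- function(x, samples = expr_samples(x)) {
  missing <- setdiff(samples, expr_samples(x))
  if (length(missing))
    abort(paste("unknown sample(s):", paste(missing, collapse = ", ")))
  log2(expr_values(x)[, samples, drop = FALSE] + 1)
}

#' Negative-coexpression filter for miRNA-target candidates
#'
#' Keeps candidate (miRNA, target) pairs whose Spearman rank correlation
#' across the comparison samples is strictly below `threshold`
#' (default -0.7), the expected sign when a miRNA represses — or is
#' sponged by — its partner. Undefined correlations (constant profiles)
#' are dropped with a warning.
#'
#' @param candidates Tibble from [predict_pairs()] (columns mirna, target).
#' @param mirna_log,target_log Log-expression matrices from
#'   [log_expression()], sharing the same sample columns.
#' @param threshold Strict upper bound on the coefficient.
#' @return Tibble: mirna, target, kind, coefficient, method, n_samples,
#'   passed — one row per candidate with a defined coefficient.
#' @export
filter_negative_pairs <- function(candidates, mirna_log, target_log,
                                  threshold = -0.7) {
  if (nrow(candidates) == 0)
    return(tibble(mirna = character(), target = character(),
                  kind = character(), coefficient = numeric(),
                  method = character(), n_samples = integer(),
                  passed = logical()))
  check_known(candidates$mirna, rownames(mirna_log), "miRNA")
  check_known(candidates$target, rownames(target_log), "target")
  kind <- if (identical(unique(candidates$layer), "circRNA"))
    "circRNA-miRNA" else "miRNA-mRNA"
  cc <- purrr::map2_dbl(candidates$mirna, candidates$target,
                        function(m, t) spearman_cor(mirna_log[m, ],
                                                    target_log[t, ]))
  out <- tibble(mirna = candidates$mirna, target = candidates$target,
                kind = kind, coefficient = cc, method = "spearman",
                n_samples = ncol(mirna_log), passed = !is.na(cc) & cc < threshold)
  drop_undefined(out)
}

#' Positive-coexpression filter for circRNA-mRNA pairs
#'
#' Candidate circRNA-mRNA pairs (those sharing at least one predicted
#' miRNA) are kept when their Pearson correlation across the comparison
#' samples is strictly above `threshold` (default 0.9) — the ceRNA
#' expectation that a sponge and its protected target co-vary.
#'
#' @param pairs Tibble with columns circ, mrna.
#' @param circ_log,mrna_log Log-expression matrices.
#' @param threshold Strict lower bound on the coefficient.
#' @return Tibble: circ, mrna, kind, coefficient, method, n_samples, passed.
#' @export
filter_positive_pairs <- function(pairs, circ_log, mrna_log, threshold = 0.9) {
  if (nrow(pairs) == 0)
    return(tibble(circ = character(), mrna = character(), kind = character(),
                  coefficient = numeric(), method = character(),
                  n_samples = integer(), passed = logical()))
  check_known(pairs$circ, rownames(circ_log), "circRNA")
  check_known(pairs$mrna, rownames(mrna_log), "mRNA")
  cc <- purrr::map2_dbl(pairs$circ, pairs$mrna,
                        function(c, g) pearson_cor(circ_log[c, ], mrna_log[g, ]))
  out <- tibble(circ = pairs$circ, mrna = pairs$mrna, kind = "circRNA-mRNA",
                coefficient = cc, method = "pearson",
                n_samples = ncol(circ_log), passed = !is.na(cc) & cc > threshold)
  drop_undefined(out)
}

drop_undefined <- function(out) {
  n_undef <- sum(is.na(out$coefficient))
  if (n_undef > 0) {
    warn(sprintf("%d pair(s) dropped: undefined correlation (constant profile)",
                 n_undef))
    out <- out[!is.na(out$coefficient), , drop = FALSE]
  }
  out
}

check_known <- function(ids, known, what) {
  missing <- setdiff(ids, known)
  if (length(missing))
    abort(sprintf("unknown %s feature(s): %s", what,
                  paste(head(missing, 3), collapse = ", ")))
}
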