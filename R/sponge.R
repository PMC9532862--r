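#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n items from a
#' universe of N containing K marked items. Computed by summing
#' log-binomial terms (numerically stable for any arguments within
#' bounds); this one kernel backs both the shared-miRNA sponge test and
#' over-representation analysis.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Marked-set size.
#' @param n Draw size.
#' @param N Universe size, `K, n <= N`.
#' @return P(X >= k) in (0, 1]; `k = 0` gives 1 exactly.
#' @examples
#' hypergeom_sf(3, 4, 5, 10)  # 66/252
#' @export
hypergeom_sf <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    abort("require 0 <= k <= min(K, n) and K, n <= N")
  if (k == 0) return(1)
  i <- k:min(K, n)
  terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  p <- sum(exp(terms))
  min(max(p, .Machine$double.xmin), 1)
}

#' Shared-miRNA sponge test for one circRNA-mRNA pair
#'
#' Tests whether a circRNA and an mRNA share more predicted miRNAs than
#' expected by chance — the statistical signature of a common sponge.
#' Given the circRNA's predicted miRNA set, the mRNA's predicted miRNA
#' set, and the universe of testable miRNAs, the overlap k is referred to
#' the hypergeometric upper tail. The pair passes when p < alpha and at
#' least one miRNA is shared.
#'
#' @param circ_mirnas,mrna_mirnas Character vectors of predicted miRNA ids.
#' @param universe Character vector of all testable miRNAs (non-empty;
#'   both sets must be subsets).
#' @param alpha Significance level (strict), default 0.05.
#' @return Tibble: k, K, n, N, p, passed.
#' @export
sponge_test <- function(circ_mirnas, mrna_mirnas, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty miRNA universe")
  circ_mirnas <- unique(circ_mirnas)
  mrna_mirnas <- unique(mrna_mirnas)
  if (!all(circ_mirnas %in% universe) || !all(mrna_mirnas %in% universe))
    abort("miRNA sets must be subsets of the universe")
  k <- length(intersect(circ_mirnas, mrna_mirnas))
  p <- hypergeom_sf(k, length(circ_mirnas), length(mrna_mirnas),
                    length(universe))
  tibble(k = k, K = length(circ_mirnas), n = length(mrna_mirnas),
         N = length(universe), p = p, passed = p < alpha && k >= 1)
}
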