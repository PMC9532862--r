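#' Library-size equalization
#'
#' Rescales every sample's counts to the geometric mean library size and
#' rounds half-to-even, so that two-group tests can condition on totals
#' without a library-size nuisance. Deterministic.
#'
#' @param counts A raw-count [expr_matrix()].
#' @return A `spng_expr` of equalized integer counts.
#' @export
equalize_library_sizes <- function(counts) {
  assert_raw_counts(counts)
  v <- expr_values(counts)
  cs <- colSums(v)
  if (any(cs == 0)) abort("zero column sum: cannot equalize library sizes")
  target <- exp(mean(log(cs)))
  out <- round(sweep(v, 2, target / cs, "*"))
  rebuild_expr(counts, out, "raw-count")
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-feature dispersion under Var = mu + phi * mu^2, estimated on
#' library-size-equalized counts with group means removed:
#' phi_i = max(0, (s2_i - m_i) / m_i^2), where m_i is the feature's grand
#' mean and s2_i the pooled within-group variance. The common dispersion is
#' the median of the finite per-feature values.
#'
#' @param counts A raw-count [expr_matrix()] covering both groups.
#' @param design A [sample_design()] table for (at least) those samples.
#' @param groups Character vector of the two group labels to use.
#' @return A list with `per_feature` (tibble: feature, phi) and `common`.
#' @export
estimate_dispersion <- function(counts, design, groups) {
  design <- sample_design(design)
  if (length(groups) != 2) abort("exactly two groups required")
  samp <- lapply(groups, function(g) design_samples(design, g))
  if (any(lengths(samp) < 2)) abort("need >= 2 replicates per group")
  sub <- counts[, c("feature", unlist(samp)), drop = FALSE]
  sub <- new_spng_expr(sub, expr_unit(counts), expr_layer(counts))
  v <- expr_values(equalize_library_sizes(sub))
  grp <- rep(seq_along(samp), lengths(samp))
  n <- ncol(v); G <- 2L
  gm <- vapply(split(seq_len(n), grp),
               function(j) rowMeans(v[, j, drop = FALSE]), numeric(nrow(v)))
  resid2 <- (v - gm[, grp])^2
  s2 <- rowSums(resid2) / (n - G)
  m <- rowMeans(v)
  phi <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
  common <- median(phi[is.finite(phi)])
  list(per_feature = tibble(feature = rownames(v), phi = unname(phi)),
       common = common, method = "method-of-moments")
}

#' Exact conditional negative-binomial two-group test
#'
#' Conditions on the combined total t = sumA + sumB of the (equalized)
#' group totals. Each group total is modelled as negative binomial with
#' size n_g / phi (Poisson when phi = 0) and null mean proportional to its
#' sample count; the two-sided p-value sums the probabilities of all splits
#' no more likely than the observed one (ties included). At phi = 0 the
#' conditional law is exactly Binomial(t, n_A / (n_A + n_B)).
#'
#' @param counts_a,counts_b Non-negative integer count vectors for one
#'   feature, after library-size equalization.
#' @param phi Non-negative, finite dispersion.
#' @return p-value in (0, 1].
#' @examples
#' exact_nb_test(c(1, 1, 0), c(3, 3, 2), phi = 0)  # 112/1024
#' @export
exact_nb_test <- function(counts_a, counts_b, phi = 0) {
  if (!is.finite(phi) || phi < 0) abort("phi must be finite and >= 0")
  if (any(counts_a < 0) || any(counts_b < 0)) abort("negative counts")
  sa <- sum(counts_a); sb <- sum(counts_b)
  na <- length(counts_a); nb <- length(counts_b)
  t <- sa + sb
  if (t == 0) return(1)
  a <- 0:t
  mu <- t / (na + nb)
  if (phi == 0) {
    logp <- dpois(a, na * mu, log = TRUE) + dpois(t - a, nb * mu, log = TRUE)
  } else {
    logp <- dnbinom(a, size = na / phi, mu = na * mu, log = TRUE) +
            dnbinom(t - a, size = nb / phi, mu = nb * mu, log = TRUE)
  }
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[sa + 1L]
  p <- sum(pr[pr <= obs * (1 + 1e-12)])
  min(max(p, .Machine$double.xmin), 1)
}

#' Log2 fold change of group means
#'
#' log2((meanB + c) / (meanA + c)) with pseudocount c guarding zero means;
#' antisymmetric under swapping the groups.
#'
#' @param mean_a,mean_b Non-negative group means (B over A).
#' @param pseudocount Positive guard, default 1.
#' @return The log2 fold change.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  if (any(mean_a < 0) || any(mean_b < 0)) abort("means must be >= 0")
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]), returned in input
#' order.
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted values (monotone step-up, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Layer-specific differential-expression calls
#'
#' circRNA and miRNA features are significant at |log2FC| >= 1 and raw
#' p < 0.05; mRNA features at |log2FC| >= 1 and BH FDR < 0.05. Direction
#' follows the sign of the fold change.
#'
#' @param results Tibble with columns `log2fc`, `p`, `fdr`.
#' @param layer One of `"circRNA"`, `"miRNA"`, `"mRNA"`.
#' @return `results` with a `call` column (`"up"`, `"down"`, `"ns"`).
#' @export
call_de <- function(results, layer = c("circRNA", "miRNA", "mRNA")) {
  layer <- match.arg(layer)
  sig_stat <- if (layer == "mRNA") results$fdr < 0.05 else results$p < 0.05
  sig <- abs(results$log2fc) >= 1 & sig_stat
  results$call <- ifelse(!sig, "ns", ifelse(results$log2fc > 0, "up", "down"))
  results
}

#' Two-group differential expression for one layer
#'
#' Equalizes library sizes, estimates a common method-of-moments
#' dispersion, applies the exact conditional negative-binomial test per
#' feature, computes fold changes on equalized group means (pseudocount 1),
#' BH-adjusts, and applies the layer's decision rule. Comparison direction
#' is `groups[2]` over `groups[1]`.
#'
#' @inheritParams estimate_dispersion
#' @param phi Optional fixed dispersion overriding the estimate.
#' @param pseudocount Fold-change guard, default 1.
#' @return A `spng_de` tibble: feature, layer, comparison, base_mean_a,
#'   base_mean_b, log2fc, p, fdr, call.
#' @examples
#' cfg <- simulation_config(n_mrna = 40, n_mirna = 10, n_circ = 10,
#'                          n_planted_triples = 2, seed = 1)
#' sim <- simulate_counts(cfg)
#' de_test(sim$counts$mRNA, sim$design, c("TN", "TL"))
#' @export
de_test <- function(counts, design, groups, phi = NULL, pseudocount = 1) {
  design <- sample_design(design)
  if (length(groups) != 2) abort("exactly two groups required")
  missing_groups <- setdiff(groups, design$group)
  if (length(missing_groups))
    abort(paste("unknown group(s):", paste(missing_groups, collapse = ", ")))
  layer <- expr_layer(counts)
  sa <- design_samples(design, groups[1])
  sb <- design_samples(design, groups[2])
  sub <- new_spng_expr(counts[, c("feature", sa, sb), drop = FALSE],
                       expr_unit(counts), expr_layer(counts))
  eq <- expr_values(equalize_library_sizes(sub))
  if (is.null(phi)) {
    phi <- estimate_dispersion(counts, design, groups)$common
  }
  A <- eq[, sa, drop = FALSE]
  B <- eq[, sb, drop = FALSE]
  pvals <- vapply(seq_len(nrow(eq)),
                  function(i) exact_nb_test(A[i, ], B[i, ], phi),
                  numeric(1))
  res <- tibble(
    feature = rownames(eq),
    layer = layer,
    comparison = paste0(groups[1], "_vs_", groups[2]),
    base_mean_a = rowMeans(A),
    base_mean_b = rowMeans(B),
    log2fc = log2_fold_change(rowMeans(A), rowMeans(B), pseudocount),
    p = pvals,
    fdr = bh_adjust(pvals)
  )
  res <- call_de(res, layer)
  class(res) <- c("spng_de", class(res))
  attr(res, "phi") <- phi
  res
}
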