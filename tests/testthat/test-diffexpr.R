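toy_design <- function(reps = 3) {
  sample_design(tibble::tibble(
    sample = paste0(rep(c("TN", "TL"), each = reps), "_", rep(1:reps, 2)),
    breed = "Tibetan",
    oxygen = rep(c("normoxic", "hypoxic"), each = reps),
    replicate = rep(1:reps, 2)))
}

test_that("dispersion estimate is zero for constant counts and matches the
           moment formula on an overdispersed toy", {
  d <- toy_design()
  m <- matrix(50, 3, 6, dimnames = list(c("a", "b", "c"), d$sample))
  est <- estimate_dispersion(expr_matrix(m), d, c("TN", "TL"))
  expect_equal(est$per_feature$phi, rep(0, 3))
  expect_equal(est$common, 0)

  # variance >> mean: phi = (s2 - m) / m^2 with pooled within-group
  # variance; a ballast feature keeps all library sizes equal so no
  # rescaling happens
  x <- c(10, 100, 40, 20, 90, 30)
  m2 <- rbind(f1 = x, ballast = 110 - x)
  colnames(m2) <- d$sample
  est2 <- estimate_dispersion(expr_matrix(m2), d, c("TN", "TL"))
  gm <- c(mean(x[1:3]), mean(x[4:6]))
  s2 <- sum((x - rep(gm, each = 3))^2) / 4
  mbar <- mean(x)
  expect_equal(est2$per_feature$phi[1], max(0, (s2 - mbar) / mbar^2))

  expect_error(estimate_dispersion(expr_matrix(m[, c(1, 4), drop = FALSE]),
                                   d[c(1, 4), ], c("TN", "TL")),
               ">= 2 replicates")
})

test_that("common dispersion is near zero on Poisson data", {
  d <- toy_design()
  set.seed(5)
  mu <- exp(runif(3000, log(30), log(300)))
  m <- matrix(rpois(3000 * 6, rep(mu, 6)), 3000, 6,
              dimnames = list(sprintf("g%04d", 1:3000), d$sample))
  est <- estimate_dispersion(expr_matrix(m), d, c("TN", "TL"))
  expect_lt(est$common, 0.02)
})

test_that("exact NB test reduces to the conditional binomial at phi = 0", {
  # identical totals with equal group sizes: observed split is modal
  expect_equal(exact_nb_test(c(5, 5, 5), c(5, 5, 5), phi = 0), 1)
  # worked split 2 vs 8: double tail of Binomial(10, 1/2)
  expect_equal(exact_nb_test(c(1, 1, 0), c(3, 3, 2), phi = 0), 112 / 1024)
})

test_that("exact NB test equals split enumeration for all totals <= 50", {
  for (phi in c(0, 0.1, 1)) {
    for (t in c(1:15, 20, 30, 40, 50)) {
      for (sa in 0:t) {
        got <- exact_nb_test(c(sa, 0, 0), c(t - sa, 0, 0), phi = phi)
        want <- oracle_exact_nb(sa, t - sa, 3, 3, phi)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
    # unequal group sizes
    for (sa in c(0, 3, 7, 12)) {
      got <- exact_nb_test(c(sa, 0), c(12 - sa, 0, 0, 0), phi = phi)
      expect_equal(got, oracle_exact_nb(sa, 12 - sa, 2, 4, phi),
                   tolerance = 1e-12)
    }
  }
  expect_error(exact_nb_test(c(-1, 2), c(1, 1), 0), "negative")
  expect_error(exact_nb_test(c(1, 2), c(1, 1), -0.1), "phi")
})

test_that("log2 fold change is antisymmetric with a pseudocount guard", {
  expect_equal(log2_fold_change(10, 10), 0)
  expect_equal(log2_fold_change(9, 39, pseudocount = 1), log2(40 / 10))
  expect_equal(log2_fold_change(3, 17), -log2_fold_change(17, 3))
  expect_equal(log2_fold_change(0, 0), 0)
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "pseudocount")
})

test_that("BH adjustment reproduces the step-up by hand and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(8)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm])[order(perm)], q)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("layer-specific significance rules gate calls as printed", {
  res <- tibble::tibble(log2fc = c(0.5, 2, 2, -1.8, 1.2, -0.2),
                        p = c(1e-6, 0.04, 0.04, 0.001, 0.2, 0.01),
                        fdr = c(1e-5, 0.2, 0.2, 0.03, 0.6, 0.4))
  # FC gate fails despite tiny p
  expect_equal(call_de(res, "miRNA")$call[1], "ns")
  # p < 0.05 suffices for circRNA, FDR rule blocks the same row for mRNA
  expect_equal(call_de(res, "circRNA")$call[2], "up")
  expect_equal(call_de(res, "mRNA")$call[2], "ns")
  # manual application of both rules across the toy table
  expect_equal(call_de(res, "circRNA")$call,
               c("ns", "up", "up", "down", "ns", "ns"))
  expect_equal(call_de(res, "mRNA")$call,
               c("ns", "ns", "ns", "down", "ns", "ns"))
})

test_that("planted four-fold changes at quantifiable depth are recovered", {
  cfg <- simulation_config(n_mrna = 300, n_mirna = 40, n_circ = 40,
                           n_planted_triples = 0,
                           n_planted_de_per_layer = 30,
                           effect_log2fc = 2, nb_dispersion = 0.05,
                           seed = 21)
  sim <- simulate_counts(cfg)
  de <- de_test(sim$counts$mRNA, sim$design, c("TN", "TL"))
  planted <- dplyr::filter(sim$truth$planted_de, layer == "mRNA")
  calls <- de$call[match(planted$feature, de$feature)]
  expect_gte(mean(calls != "ns"), 0.9)
  dirs <- ifelse(calls == "up", "up", ifelse(calls == "down", "down", NA))
  expect_true(all(dirs[!is.na(dirs)] == planted$direction[!is.na(dirs)]))
})
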