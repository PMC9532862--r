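test_that("configuration invariants are enforced", {
  expect_error(simulation_config(replicates_per_group = 1), "replicates")
  expect_error(simulation_config(n_planted_triples = 200), "exceeds")
  expect_error(simulation_config(nb_dispersion = -1), "dispersion")
  expect_error(simulation_config(effect_log2fc = 0), "effect_log2fc")
  expect_error(simulation_config(mirna_length_range = c(18, 22)), "21")
  expect_error(simulation_config(library_size_range = c(-1, 10)), "library")
})

test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- tiny_config()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  # a different seed changes the counts
  c <- simulate_counts(tiny_config(seed = 8))
  expect_false(identical(expr_values(a$counts$mRNA),
                         expr_values(c$counts$mRNA)))
})

test_that("ground truth is internally consistent", {
  ds <- simulate_dataset(tiny_config())
  tt <- ds$truth$planted_triples
  de <- ds$truth$planted_de
  # every triple member is a planted DE feature with consistent direction:
  # miRNA opposite to circRNA and mRNA
  for (i in seq_len(nrow(tt))) {
    d_c <- de$direction[de$feature == tt$circ[i]]
    d_m <- de$direction[de$feature == tt$mirna[i]]
    d_g <- de$direction[de$feature == tt$mrna[i]]
    expect_length(d_c, 1); expect_length(d_m, 1); expect_length(d_g, 1)
    expect_identical(d_c, d_g)
    expect_false(identical(d_m, d_c))
  }
  # every triple has at least one planted site on its circRNA and mRNA
  st <- ds$truth$planted_sites
  for (i in seq_len(nrow(tt))) {
    expect_gte(nrow(st[st$mirna == tt$mirna[i] & st$target == tt$circ[i], ]), 1)
    expect_gte(nrow(st[st$mirna == tt$mirna[i] & st$target == tt$mrna[i], ]), 1)
  }
})

test_that("without planted effects the generator is a calibrated null", {
  cfg <- simulation_config(n_mrna = 800, n_mirna = 10, n_circ = 10,
                           n_planted_triples = 0,
                           n_planted_de_per_layer = 0,
                           nb_dispersion = 0, seed = 5)
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$truth$planted_de), 0)
  de <- de_test(sim$counts$mRNA, sim$design, c("TN", "TL"))
  expect_gt(mean(de$p < 0.05), 0.02)
  expect_lt(mean(de$p < 0.05), 0.08)
})

test_that("planted triples carry the ceRNA correlation signature", {
  # miRNA anticorrelated with mRNA, circRNA positively correlated with
  # mRNA, within the Tibetan samples — recomputed from the raw matrices
  cfg <- simulation_config(n_mrna = 200, n_mirna = 50, n_circ = 60,
                           n_planted_triples = 10, effect_log2fc = 2,
                           nb_dispersion = 0.05, seed = 42)
  sim <- simulate_counts(cfg)
  samples <- sim$design$sample[sim$design$breed == "Tibetan"]
  mir <- expr_values(sim$counts$miRNA)[, samples]
  mrna <- expr_values(sim$counts$mRNA)[, samples]
  circ <- expr_values(sim$counts$circRNA)[, samples]
  tt <- sim$truth$planted_triples
  for (i in seq_len(nrow(tt))) {
    expect_lt(spearman_cor(mir[tt$mirna[i], ], mrna[tt$mrna[i], ]), 0)
    expect_gt(pearson_cor(circ[tt$circ[i], ], mrna[tt$mrna[i], ]), 0)
  }
})

test_that("planted sequence sites scan back exactly, junction sites
           included", {
  ds <- simulate_dataset(tiny_config())
  st <- ds$truth$planted_sites
  expect_gt(nrow(st), 0)
  for (i in seq_len(nrow(st))) {
    topo <- if (st$layer[i] == "circRNA") "circular" else "linear"
    seqs <- if (topo == "circular") ds$sequences$circ else ds$sequences$utr
    found <- find_seed_sites(ds$sequences$mirna[[st$mirna[i]]],
                             seqs[[st$target[i]]], topology = topo)
    hit <- found[found$position == st$position[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$site_type, st$site_type[i])
    expect_equal(hit$spans_junction, st$spans_junction[i])
  }
  # junction sites are invisible to a linear scan of the raw string
  junc <- st[st$spans_junction, ]
  for (i in seq_len(nrow(junc))) {
    lin <- find_seed_sites(ds$sequences$mirna[[junc$mirna[i]]],
                           ds$sequences$circ[[junc$target[i]]],
                           topology = "linear")
    expect_false(junc$position[i] %in% lin$position)
  }
})

test_that("background targets carry no sites for planted miRNAs", {
  ds <- simulate_dataset(tiny_config())
  planted <- unique(ds$truth$planted_pairs$mirna)
  bg_utr <- setdiff(names(ds$sequences$utr),
                    ds$truth$planted_pairs$target)
  bg_circ <- setdiff(names(ds$sequences$circ),
                     ds$truth$planted_pairs$target)
  for (m in planted) {
    for (t in head(bg_utr, 10))
      expect_equal(nrow(find_seed_sites(ds$sequences$mirna[[m]],
                                        ds$sequences$utr[[t]])), 0)
    for (t in head(bg_circ, 5))
      expect_equal(nrow(find_seed_sites(ds$sequences$mirna[[m]],
                                        ds$sequences$circ[[t]],
                                        topology = "circular")), 0)
  }
})

test_that("fixture bundles round-trip and have stable checksums", {
  ds <- simulate_dataset(tiny_config())
  dir1 <- withr::local_tempdir()
  man1 <- write_fixture_bundle(ds, dir1)
  expect_setequal(names(man1$files),
                  c("counts_circRNA.tsv", "counts_miRNA.tsv",
                    "counts_mRNA.tsv", "design.tsv", "lengths.tsv",
                    "mirna.fa", "utr.fa", "circ.fa", "ground_truth.json"))
  back <- read_fixture_bundle(dir1)
  expect_equal(expr_values(back$counts$mRNA), expr_values(ds$counts$mRNA))
  expect_equal(back$sequences$mirna, ds$sequences$mirna)
  expect_equal(back$design$group, ds$design$group)
  expect_equal(tibble::as_tibble(back$truth$planted_triples),
               tibble::as_tibble(ds$truth$planted_triples))
  expect_equal(back$lengths[names(ds$lengths)], ds$lengths)
  # regenerating under the same seed yields identical checksums
  dir2 <- withr::local_tempdir()
  man2 <- write_fixture_bundle(simulate_dataset(tiny_config()), dir2)
  expect_equal(unlist(man1$files), unlist(man2$files))
})
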