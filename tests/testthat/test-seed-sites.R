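test_that("reverse complement is a length-preserving involution", {
  expect_equal(reverse_complement("ACGU"), "ACGU")
  expect_equal(reverse_complement(""), "")
  expect_equal(reverse_complement("GAGGUAG"), "CUACCUC")
  expect_equal(reverse_complement("ACGT"), "ACGU")  # DNA accepted
  set.seed(2)
  for (i in 1:20) {
    s <- random_rna_str(sample(5:40, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(nchar(reverse_complement(s)), nchar(s))
  }
  expect_error(reverse_complement("ACGX"), "non-ACGU")
})

test_that("the canonical let-7 8mer site is found at position 4 and site
           classes follow the priority rule", {
  hits <- find_seed_sites(let7, "AAACUACCUCAAAA")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_type, "8mer")
  expect_equal(hits$position, 4L)
  expect_false(hits$spans_junction)

  # same seed match without the trailing A: 7mer-m8
  hits7 <- find_seed_sites(let7, "AAACUACCUCGGGG")
  expect_equal(hits7$site_type, "7mer-m8")
  expect_equal(hits7$position, 4L)

  # core only, with and without the A1 adenosine
  expect_equal(find_seed_sites(let7, "GGUACCUCAGG")$site_type, "7mer-A1")
  expect_equal(find_seed_sites(let7, "GGUACCUCGGG")$site_type, "6mer")

  # no complementarity
  expect_equal(nrow(find_seed_sites(let7, "AAAAAAAA")), 0)
  expect_error(find_seed_sites("UGAGGUA", "AAACUACCUC"), ">= 8")
  expect_error(find_seed_sites(let7, "ACGUA"), ">= 6")
})

test_that("junction-spanning sites are found only by the circular scan", {
  target <- "CUCAGGGGGCUAC"
  circ <- find_seed_sites(let7, target, topology = "circular")
  expect_equal(nrow(circ), 1)
  expect_true(circ$spans_junction)
  expect_equal(nrow(find_seed_sites(let7, target, topology = "linear")), 0)
})

test_that("circular scan equals the brute-force rotation oracle", {
  set.seed(77)
  n_with_sites <- 0
  for (i in 1:60) {
    mirna <- random_rna_str(22)
    circ <- random_rna_str(sample(30:70, 1))
    # splice a site into some targets so the comparison is not vacuous
    if (i %% 3 == 0) {
      core <- reverse_complement(substr(mirna, 2, 8))
      p <- sample(nchar(circ) - 8, 1)
      substr(circ, p, p + 7) <- paste0(core, "A")
    }
    got <- find_seed_sites(mirna, circ, topology = "circular")
    want <- oracle_circular_sites(mirna, circ)
    expect_equal(got$position, want$position)
    expect_equal(got$site_type, want$site_type)
    n_with_sites <- n_with_sites + (nrow(got) > 0)
    # classes are exclusive per position
    expect_false(anyDuplicated(got$position) > 0)
  }
  expect_gt(n_with_sites, 10)
})

test_that("interaction scores add class weights", {
  none <- find_seed_sites(let7, "AAAAAAAA")
  expect_equal(score_interaction(none), 0)
  two <- tibble::tibble(site_type = c("8mer", "6mer"),
                        position = c(4L, 30L),
                        spans_junction = FALSE, topology = "linear")
  expect_equal(score_interaction(two), 4)
  expect_equal(score_interaction(two[rep(1:2, 2), ]), 8)
})

test_that("all-vs-all prediction recovers planted pairs and is
           deterministic", {
  ds <- simulate_dataset(tiny_config())
  truth_pairs <- ds$truth$planted_pairs
  mir <- ds$sequences$mirna[unique(truth_pairs$mirna)]
  for (ly in c("mRNA", "circRNA")) {
    targets <- if (ly == "mRNA") ds$sequences$utr else ds$sequences$circ
    cand <- predict_pairs(mir, targets, layer = ly)
    want <- truth_pairs[truth_pairs$layer == ly, ]
    expect_true(all(paste(want$mirna, want$target) %in%
                    paste(cand$mirna, cand$target)))
    cand2 <- predict_pairs(mir, targets, layer = ly)
    expect_identical(cand, cand2)
  }
  expect_equal(nrow(predict_pairs(character(), ds$sequences$utr)), 0)
  expect_error(predict_pairs(c(a = let7, a = let7), ds$sequences$utr),
               "duplicate")
})

test_that("per-pair site counts by class sum to total reported sites", {
  set.seed(12)
  for (i in 1:20) {
    mirna <- random_rna_str(22)
    target <- random_rna_str(300)
    hits <- find_seed_sites(mirna, target)
    tab <- table(factor(hits$site_type, levels = c("8mer", "7mer-m8",
                                                   "7mer-A1", "6mer")))
    expect_equal(sum(tab), nrow(hits))
  }
})
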