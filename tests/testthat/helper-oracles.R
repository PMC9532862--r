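# Independent oracles used across the suite. Each re-derives the quantity
# by a different route than the package (explicit lgamma/choose arithmetic,
# subset enumeration, rotation scans) so agreement is evidence, not
# tautology.

# Exact conditional two-group NB test by direct enumeration of all splits
# of the total t, with the NB mass written out via lgamma (Poisson limit at
# phi = 0 via factorials).
oracle_exact_nb <- function(sum_a, sum_b, n_a, n_b, phi) {
  t <- sum_a + sum_b
  if (t == 0) return(1)
  mu <- t / (n_a + n_b)
  mass <- function(x, n) {
    if (phi == 0) {
      lam <- n * mu
      exp(x * log(lam) - lam - lgamma(x + 1))
    } else {
      r <- n / phi
      m <- n * mu
      exp(lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
            r * log(r / (r + m)) + x * log(m / (r + m)))
    }
  }
  a <- 0:t
  pr <- mass(a, n_a) * mass(t - a, n_b)
  pr <- pr / sum(pr)
  obs <- pr[sum_a + 1]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Hypergeometric upper tail by enumerating every n-subset of the universe
# (feasible for N <= 12).
oracle_hypergeom_sf <- function(k, K, n, N) {
  if (k == 0) return(1)
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)   # items 1..K are the marked ones
  mean(overlaps >= k)
}

# Spearman via explicit midranks then the textbook product-moment formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Circular-target site scan by brute force over all rotations: linear-scan
# each rotation, map starts back to original coordinates, then keep the
# strongest class per seed anchor (same tie rule as the scanner).
oracle_circular_sites <- function(mirna, target) {
  len <- nchar(target)
  anchor_off <- c(`8mer` = 6L, `7mer-m8` = 6L, `7mer-A1` = 5L, `6mer` = 5L)
  rank <- c(`6mer` = 1L, `7mer-A1` = 2L, `7mer-m8` = 3L, `8mer` = 4L)
  all_hits <- list()
  for (r in 0:(len - 1)) {
    rot <- paste0(substr(target, r + 1, len), substr(target, 1, r))
    s <- find_seed_sites(mirna, rot, topology = "linear")
    if (nrow(s) == 0) next
    orig <- ((s$position - 1L + r) %% len) + 1L
    all_hits[[length(all_hits) + 1L]] <-
      data.frame(site_type = s$site_type, position = orig)
  }
  hits <- do.call(rbind, all_hits)
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(site_type = character(), position = integer()))
  hits$anchor <- ((hits$position + anchor_off[hits$site_type] - 1L) %% len) + 1L
  hits$rank <- rank[hits$site_type]
  hits <- hits[order(hits$anchor, -hits$rank, hits$position), ]
  hits <- hits[!duplicated(hits$anchor), ]
  hits <- unique(hits[, c("site_type", "position")])
  hits[order(hits$position), ]
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# small simulated dataset shared by several tests
tiny_config <- function(seed = 7, ...) {
  simulation_config(n_mrna = 60, n_mirna = 20, n_circ = 20,
                    n_planted_triples = 3, n_planted_de_per_layer = 8,
                    seed = seed, ...)
}

let7 <- "UGAGGUAGUAGGUUGUAUAGUU"
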