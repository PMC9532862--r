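#' Configuration for the synthetic three-layer ceRNA dataset
#'
#' Defines the study conditions the generator emulates: four groups
#' crossing breed (Tibetan/Landrace) with oxygen (normoxic 21\% O2 /
#' hypoxic 2\% O2), three replicates per group, negative-binomial counts,
#' planted differentially expressed features (|log2FC| >= `effect_log2fc`
#' in the hypoxic groups) and planted ceRNA triples in which two shared
#' miRNAs are anticorrelated with both their circRNA sponge and their mRNA
#' target while circRNA and mRNA co-vary positively — with the
#' corresponding seed sites physically written into the generated
#' sequences.
#'
#' @param n_mrna,n_mirna,n_circ Feature counts per layer.
#' @param replicates_per_group Replicates in each of TN, TL, LN, LL
#'   (default 3).
#' @param n_planted_triples Number of planted circRNA-mRNA sponge pairs;
#'   each carries `n_shared_mirnas` anchoring miRNAs, so the ground truth
#'   lists `n_planted_triples * n_shared_mirnas` (circ, miRNA, mRNA) rows.
#' @param n_shared_mirnas Shared miRNAs per planted triple (default 2; a
#'   sponge and its protected mRNA sharing a single miRNA is statistically
#'   indistinguishable from chance under the strict sponge test).
#' @param n_planted_de_per_layer Total planted DE features per layer,
#'   triple members included (topped up with independent DE features).
#' @param effect_log2fc Planted absolute log2 fold change (hypoxic over
#'   normoxic), default 2.
#' @param nb_dispersion Negative-binomial dispersion phi in
#'   Var = mu + phi mu^2; 0 gives Poisson counts.
#' @param sponge_factor_sd Per-sample latent "sponge activity" SD on the
#'   log2 scale coupling each triple's members within groups (loadings +1
#'   for circRNA/mRNA, -1 for the miRNAs). The factor is centered within
#'   each group, so it shapes correlations without moving group means;
#'   0 disables the coupling.
#' @param breed_log2fc Baseline log2 offset of Tibetan over Landrace
#'   samples (default 0).
#' @param baseline_mean_log_range Log2 range for log-uniform baseline
#'   means.
#' @param planted_mean_log_floor Minimum log2 baseline mean for planted
#'   features (detectability floor; planted effects at unquantifiable
#'   depth would be invisible to any method).
#' @param library_size_range Range the per-sample library-size factors are
#'   drawn from (only their ratios matter).
#' @param utr_length_range,circ_length_range 3'UTR and circRNA sequence
#'   lengths (nt).
#' @param mirna_length_range Mature miRNA lengths, within 21-24 nt.
#' @param junction_site_fraction Fraction of planted circRNA sites that
#'   span the back-splice junction.
#' @param planted_site_type Seed-site class written into the sequences.
#' @param seed Integer RNG seed; identical config + seed reproduces every
#'   output bit-for-bit.
#' @return A `spng_sim_config` list.
#' @export
simulation_config <- function(n_mrna = 400, n_mirna = 80, n_circ = 100,
                              replicates_per_group = 3,
                              n_planted_triples = 10,
                              n_shared_mirnas = 2,
                              n_planted_de_per_layer = 25,
                              effect_log2fc = 2,
                              nb_dispersion = 0.05,
                              sponge_factor_sd = 1.2,
                              breed_log2fc = 0,
                              baseline_mean_log_range = c(log2(20), log2(2000)),
                              planted_mean_log_floor = log2(200),
                              library_size_range = c(8e5, 1.2e6),
                              utr_length_range = c(300, 800),
                              circ_length_range = c(200, 1000),
                              mirna_length_range = c(21, 24),
                              junction_site_fraction = 0.3,
                              planted_site_type = "8mer",
                              seed = 42) {
  cfg <- list(n_mrna = n_mrna, n_mirna = n_mirna, n_circ = n_circ,
              replicates_per_group = replicates_per_group,
              groups = c("TN", "TL", "LN", "LL"),
              n_planted_triples = n_planted_triples,
              n_shared_mirnas = n_shared_mirnas,
              n_planted_de_per_layer = n_planted_de_per_layer,
              effect_log2fc = effect_log2fc,
              nb_dispersion = nb_dispersion,
              sponge_factor_sd = sponge_factor_sd,
              breed_log2fc = breed_log2fc,
              baseline_mean_log_range = baseline_mean_log_range,
              planted_mean_log_floor = planted_mean_log_floor,
              library_size_range = library_size_range,
              utr_length_range = utr_length_range,
              circ_length_range = circ_length_range,
              mirna_length_range = mirna_length_range,
              junction_site_fraction = junction_site_fraction,
              planted_site_type = planted_site_type,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "spng_sim_config")
}

validate_sim_config <- function(cfg) {
  nums <- unlist(cfg[setdiff(names(cfg), c("groups", "planted_site_type"))])
  if (any(!is.finite(nums))) abort("non-finite configuration value")
  with(cfg, {
    if (n_mrna < 1 || n_mirna < 1 || n_circ < 1) abort("feature counts must be >= 1")
    if (replicates_per_group < 2) abort("need >= 2 replicates per group")
    if (n_planted_triples < 0 || n_planted_de_per_layer < 0)
      abort("planted counts must be >= 0")
    if (n_planted_triples > min(n_mrna, n_circ))
      abort("n_planted_triples exceeds the smallest target layer")
    if (n_planted_triples * n_shared_mirnas > n_mirna)
      abort("not enough miRNAs for the requested planted triples")
    if (n_planted_triples > 0 && effect_log2fc <= 0)
      abort("effect_log2fc must be > 0")
    if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
    if (sponge_factor_sd < 0) abort("sponge_factor_sd must be >= 0")
    if (any(library_size_range <= 0)) abort("library sizes must be > 0")
    if (mirna_length_range[1] < 21 || mirna_length_range[2] > 24)
      abort("mirna_length_range must lie within [21, 24]")
    if (junction_site_fraction < 0 || junction_site_fraction > 1)
      abort("junction_site_fraction must be in [0, 1]")
    if (!planted_site_type %in% SITE_TYPES) abort("unknown planted_site_type")
  })
  invisible(cfg)
}

feature_ids <- function(prefix, n) sprintf("%s_%04d", prefix, seq_len(n))

#' Simulate three-layer count matrices with planted ground truth
#'
#' Draws feature-wise negative-binomial counts (Poisson at dispersion 0)
#' for the 4 x `replicates_per_group` samples, with per-sample library
#' size factors, planted DE mean shifts of `effect_log2fc` in the hypoxic
#' groups (TL, LL), and planted ceRNA triples whose members additionally
#' share a per-sample latent factor (miRNAs loaded negatively, circRNA and
#' mRNA positively). Triple orientation alternates: odd-numbered triples
#' have miRNAs down / circRNA and mRNA up in hypoxia, even-numbered the
#' mirror image.
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (named list of raw-count [expr_matrix()]s),
#'   `design` (a [sample_design()] tibble) and `truth` (planted_de,
#'   planted_triples, planted_pairs tibbles).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_counts_impl(config))
}

simulate_counts_impl <- function(cfg) {
  reps <- cfg$replicates_per_group
  design <- sample_design(tibble(
    sample = paste0(rep(cfg$groups, each = reps), "_", rep(seq_len(reps), 4)),
    breed = rep(c("Tibetan", "Tibetan", "Landrace", "Landrace"), each = reps),
    oxygen = rep(c("normoxic", "hypoxic", "normoxic", "hypoxic"), each = reps),
    replicate = rep(seq_len(reps), 4)
  ))
  n_samp <- nrow(design)
  hypoxic <- design$oxygen == "hypoxic"
  tibetan <- design$breed == "Tibetan"
  lib <- runif(n_samp, cfg$library_size_range[1], cfg$library_size_range[2])
  sf <- lib / mean(lib)

  ids <- list(circRNA = feature_ids("circ", cfg$n_circ),
              miRNA = feature_ids("miR", cfg$n_mirna),
              mRNA = feature_ids("mRNA", cfg$n_mrna))

  # planted triples: distinct circ / mRNA anchors, n_shared_mirnas each
  nt <- cfg$n_planted_triples
  nm <- cfg$n_shared_mirnas
  tri_circ <- if (nt > 0) sample(ids$circRNA, nt) else character()
  tri_mrna <- if (nt > 0) sample(ids$mRNA, nt) else character()
  tri_mirna <- if (nt > 0) matrix(sample(ids$miRNA, nt * nm), nrow = nt)
               else matrix(character(), 0, 0)
  orientation <- if (nt > 0) rep_len(c(1, -1), nt) else numeric()  # circ/mRNA sign

  planted_triples <- if (nt > 0) {
    purrr::map_dfr(seq_len(nt), function(t) {
      tibble(circ = tri_circ[t], mirna = tri_mirna[t, ], mrna = tri_mrna[t],
             orientation = ifelse(orientation[t] > 0, "mirna_down", "mirna_up"))
    }) |> arrange(.data$circ, .data$mirna)
  } else {
    tibble(circ = character(), mirna = character(), mrna = character(),
           orientation = character())
  }

  # planted DE assignments: triple members first, then independent extras
  de <- list()
  for (layer in names(ids)) {
    members <- switch(layer,
      circRNA = tibble(feature = tri_circ, dir = orientation),
      mRNA = tibble(feature = tri_mrna, dir = orientation),
      miRNA = if (nt > 0)
        tibble(feature = as.vector(tri_mirna),
               dir = rep(-orientation, times = nm)) else
        tibble(feature = character(), dir = numeric()))
    n_extra <- max(0, cfg$n_planted_de_per_layer - nrow(members))
    pool <- setdiff(ids[[layer]], members$feature)
    extra <- if (n_extra > 0 && length(pool) > 0) {
      picked <- sample(pool, min(n_extra, length(pool)))
      tibble(feature = picked, dir = rep_len(c(1, -1), length(picked)))
    } else tibble(feature = character(), dir = numeric())
    de[[layer]] <- bind_rows(members, extra) |> mutate(layer = layer)
  }
  planted_de <- bind_rows(de) |>
    mutate(direction = ifelse(.data$dir > 0, "up", "down")) |>
    select("layer", "feature", "direction") |>
    arrange(.data$layer, .data$feature)

  # per-triple latent "sponge activity" factor (log2 scale), centered
  # within each group so planted effect sizes stay exactly effect_log2fc
  raw_f <- if (nt > 0 && cfg$sponge_factor_sd > 0)
    matrix(rnorm(nt * n_samp, 0, cfg$sponge_factor_sd), nrow = nt)
  else matrix(0, nrow = max(nt, 0), ncol = n_samp)
  # normalize the multiplier's arithmetic group mean to 1 (per loading
  # sign) so planted fold changes on count means stay exactly
  # 2^effect_log2fc while within-group covariation is preserved
  center_factor <- function(f) {
    for (g in unique(design$group)) {
      j <- which(design$group == g)
      f[, j] <- f[, j, drop = FALSE] -
        log2(rowMeans(2^f[, j, drop = FALSE]))
    }
    f
  }
  f_pos <- center_factor(raw_f)    # circRNA / mRNA shift
  f_neg <- center_factor(-raw_f)   # miRNA shift (anticorrelated)

  counts <- list()
  for (layer in names(ids)) {
    n_feat <- length(ids[[layer]])
    base_log <- runif(n_feat, cfg$baseline_mean_log_range[1],
                      cfg$baseline_mean_log_range[2])
    names(base_log) <- ids[[layer]]
    pl <- de[[layer]]
    base_log[pl$feature] <- pmax(base_log[pl$feature],
                                 cfg$planted_mean_log_floor)
    shift <- matrix(0, n_feat, n_samp, dimnames = list(ids[[layer]], NULL))
    if (nrow(pl) > 0)
      shift[pl$feature, hypoxic] <- shift[pl$feature, hypoxic] +
        pl$dir * cfg$effect_log2fc
    if (cfg$breed_log2fc != 0)
      shift[, tibetan] <- shift[, tibetan] + cfg$breed_log2fc
    if (nt > 0 && cfg$sponge_factor_sd > 0) {
      for (t in seq_len(nt)) {
        members <- switch(layer, circRNA = tri_circ[t], mRNA = tri_mrna[t],
                          miRNA = tri_mirna[t, ])
        fac <- if (layer == "miRNA") f_neg[t, ] else f_pos[t, ]
        shift[members, ] <- shift[members, , drop = FALSE] +
          matrix(rep(fac, each = length(members)), nrow = length(members))
      }
    }
    mu <- 2^(base_log + shift) * rep(sf, each = n_feat)
    x <- if (cfg$nb_dispersion == 0) rpois(length(mu), mu)
         else rnbinom(length(mu), size = 1 / cfg$nb_dispersion, mu = mu)
    m <- matrix(x, n_feat, n_samp,
                dimnames = list(ids[[layer]], design$sample))
    counts[[layer]] <- expr_matrix(m, unit = "raw-count", layer = layer)
  }

  planted_pairs <- if (nt > 0) {
    bind_rows(
      purrr::map_dfr(seq_len(nt), function(t)
        tibble(mirna = tri_mirna[t, ], target = tri_circ[t], layer = "circRNA")),
      purrr::map_dfr(seq_len(nt), function(t)
        tibble(mirna = tri_mirna[t, ], target = tri_mrna[t], layer = "mRNA"))
    ) |> arrange(.data$layer, .data$mirna, .data$target)
  } else tibble(mirna = character(), target = character(), layer = character())

  list(counts = counts, design = design,
       truth = list(planted_de = planted_de,
                    planted_triples = planted_triples,
                    planted_pairs = planted_pairs))
}
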