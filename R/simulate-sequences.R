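RNA_BASES <- c("A", "C", "G", "U")

random_rna <- function(n) paste(sample(RNA_BASES, n, replace = TRUE),
                                collapse = "")

site_pattern <- function(mirna, type) {
  rc7 <- reverse_complement(substr(mirna, 2, 8))
  rc6 <- reverse_complement(substr(mirna, 2, 7))
  switch(type,
         `8mer` = paste0(rc7, "A"),
         `7mer-m8` = rc7,
         `7mer-A1` = paste0(rc6, "A"),
         `6mer` = rc6)
}

#' Simulate mature miRNA, 3'UTR and circRNA sequences with planted sites
#'
#' Generates random RNA sequences for every feature of the count
#' simulation and writes the planted seed sites into them: for each
#' planted (miRNA, target) pair, the reverse complement of the miRNA seed
#' (with the class-specific flank) is placed at a recorded position on the
#' target. A configurable fraction of circRNA sites spans the back-splice
#' junction (the written site wraps from the sequence end to its start).
#' All generated targets are rejection-sampled so that no chance seed site
#' (any canonical class) for any planted miRNA survives outside the
#' recorded positions: since every canonical site contains the reverse
#' complement of seed positions 2-7, scrubbing those 6-mers suffices. The
#' emitted site table is therefore the exact scan result for planted
#' miRNAs.
#'
#' @param config The [simulation_config()] used for [simulate_counts()].
#' @param sim The list returned by [simulate_counts()] (same config).
#' @return List with `mirna`, `utr`, `circ` (named RNA character vectors),
#'   `sites` (tibble: mirna, target, layer, position, site_type,
#'   spans_junction) and `lengths` (named vector over all features).
#' @export
simulate_sequences <- function(config, sim) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 1L, simulate_sequences_impl(config, sim))
}

simulate_sequences_impl <- function(cfg, sim) {
  ids <- purrr::map(sim$counts, ~ .x$feature)
  pairs <- sim$truth$planted_pairs
  planted_mirnas <- unique(pairs$mirna)

  # mature miRNAs: random. Planted miRNAs need pairwise-compatible seeds:
  # distinct cores (a shared core would make their sites
  # indistinguishable), and no core may occur inside another planted
  # miRNA's full site pattern — otherwise every planted site for one
  # embeds an unscrubbable chance site for the other.
  mirna_seqs <- character(length(ids$miRNA))
  names(mirna_seqs) <- ids$miRNA
  seen_cores <- character()
  seen_patterns <- character()
  for (id in ids$miRNA) {
    repeat {
      s <- random_rna(sample(seq(cfg$mirna_length_range[1],
                                 cfg$mirna_length_range[2]), 1))
      if (!(id %in% planted_mirnas)) break
      core <- reverse_complement(substr(s, 2, 7))
      pattern <- site_pattern(s, "8mer")
      ok <- !core %in% seen_cores &&
        !any(vapply(seen_patterns, function(p) grepl(core, p, fixed = TRUE),
                    logical(1))) &&
        !any(vapply(seen_cores, function(cr) grepl(cr, pattern, fixed = TRUE),
                    logical(1)))
      if (ok) {
        seen_cores <- c(seen_cores, core)
        seen_patterns <- c(seen_patterns, pattern)
        break
      }
    }
    mirna_seqs[id] <- s
  }
  cores <- vapply(mirna_seqs[planted_mirnas], function(s)
    reverse_complement(substr(s, 2, 7)), character(1))

  utr_len <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]),
                    length(ids$mRNA), replace = TRUE)
  circ_len <- sample(seq(cfg$circ_length_range[1], cfg$circ_length_range[2]),
                     length(ids$circRNA), replace = TRUE)
  names(utr_len) <- ids$mRNA
  names(circ_len) <- ids$circRNA

  build <- function(target_ids, lens, layer, topology) {
    out <- character(length(target_ids))
    names(out) <- target_ids
    sites <- list()
    for (id in target_ids) {
      want <- pairs[pairs$target == id, , drop = FALSE]
      res <- generate_clean_target(lens[[id]], want, mirna_seqs, cores,
                                   cfg, topology)
      out[id] <- res$seq
      if (nrow(res$sites) > 0)
        sites[[id]] <- mutate(res$sites, target = id, layer = layer)
    }
    list(seqs = out, sites = bind_rows(sites))
  }

  utr <- build(ids$mRNA, utr_len, "mRNA", "linear")
  circ <- build(ids$circRNA, circ_len, "circRNA", "circular")

  sites <- bind_rows(utr$sites, circ$sites)
  if (nrow(sites) == 0)
    sites <- tibble(mirna = character(), target = character(),
                    layer = character(), position = integer(),
                    site_type = character(), spans_junction = logical())
  sites <- sites |>
    select("mirna", "target", "layer", "position", "site_type",
           "spans_junction") |>
    arrange(.data$layer, .data$mirna, .data$target, .data$position)

  lengths <- c(setNames(nchar(mirna_seqs), names(mirna_seqs)),
               utr_len, circ_len)
  list(mirna = mirna_seqs, utr = utr$seqs, circ = circ$seqs,
       sites = sites, lengths = lengths)
}

# Draw a random target, write the wanted sites in, then scrub every
# off-site occurrence of any planted miRNA's seed core; re-drawn wholesale
# if scrubbing cannot be reconciled with the planted spans (rare).
generate_clean_target <- function(len, want, mirna_seqs, cores, cfg,
                                  topology) {
  for (attempt in 1:100) {
    chars <- strsplit(random_rna(len), "")[[1]]
    planted <- plant_sites(chars, want, mirna_seqs, cfg, topology)
    if (is.null(planted)) next
    cleaned <- scrub_seed_cores(planted$chars, planted$span_of, cores,
                                topology)
    if (is.null(cleaned)) next
    seq <- paste(cleaned, collapse = "")
    if (verify_planted(seq, planted$sites, mirna_seqs, topology))
      return(list(seq = seq, sites = planted$sites))
  }
  abort("failed to generate a clean target sequence (increase length?)")
}

plant_sites <- function(chars, want, mirna_seqs, cfg, topology) {
  len <- length(chars)
  span_of <- list()   # miRNA id -> positions its planted sites occupy
  sites <- list()
  if (nrow(want) > 0) {
    junction <- if (topology == "circular")
      runif(nrow(want)) < cfg$junction_site_fraction
    else rep(FALSE, nrow(want))
    occupied <- integer()
    for (i in seq_len(nrow(want))) {
      pat <- site_pattern(mirna_seqs[[want$mirna[i]]], cfg$planted_site_type)
      L <- nchar(pat)
      if (len < L + 2) return(NULL)
      pos <- pick_site_position(len, L, occupied, junction[i])
      if (is.null(pos)) return(NULL)
      idx <- ((pos - 1L + seq_len(L) - 1L) %% len) + 1L
      chars[idx] <- strsplit(pat, "")[[1]]
      occupied <- c(occupied, idx)
      m <- want$mirna[i]
      span_of[[m]] <- c(span_of[[m]], idx)
      sites[[i]] <- tibble(mirna = m, position = pos,
                           site_type = cfg$planted_site_type,
                           spans_junction = (pos + L - 1L) > len)
    }
  }
  list(chars = chars, span_of = span_of, sites = bind_rows(sites))
}

pick_site_position <- function(len, L, occupied, junction) {
  cand <- if (junction) (len - L + 2L):len else 1:(len - L + 1L)
  cand <- sample(cand)
  for (pos in cand) {
    idx <- ((pos - 1L + seq_len(L) - 1L) %% len) + 1L
    if (!any(idx %in% occupied)) return(pos)
  }
  NULL
}

# Remove every occurrence of a planted miRNA's seed core (rc of seed 2-7)
# outside that miRNA's own planted spans. Any canonical site class
# contains this 6-mer, so a core-free sequence carries no chance sites.
scrub_seed_cores <- function(chars, span_of, cores, topology) {
  if (length(cores) == 0) return(chars)
  len <- length(chars)
  all_spans <- unlist(span_of, use.names = FALSE)
  for (iter in 1:50) {
    seq <- paste(chars, collapse = "")
    scan_seq <- if (topology == "circular")
      paste0(seq, substr(seq, 1, 5)) else seq
    dirty <- FALSE
    for (m in names(cores)) {
      hits <- gregexpr(cores[[m]], scan_seq, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      own <- span_of[[m]]
      for (p in as.integer(hits)) {
        idx <- ((p - 1L + 0:5) %% len) + 1L
        if (!is.null(own) && all(idx %in% own)) next  # the planted core
        mutable <- setdiff(idx, all_spans)
        if (length(mutable) == 0) return(NULL)
        j <- mutable[1]
        chars[j] <- sample(setdiff(RNA_BASES, chars[j]), 1)
        dirty <- TRUE
      }
    }
    if (!dirty) return(chars)
  }
  NULL
}

verify_planted <- function(seq, sites, mirna_seqs, topology) {
  if (nrow(sites) == 0) return(TRUE)
  for (i in seq_len(nrow(sites))) {
    found <- find_seed_sites(mirna_seqs[[sites$mirna[i]]], seq, topology)
    hit <- found[found$position == sites$position[i] &
                 found$site_type == sites$site_type[i], , drop = FALSE]
    if (nrow(hit) == 0) return(FALSE)
  }
  TRUE
}
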