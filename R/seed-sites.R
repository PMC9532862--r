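SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")  # ascending strength

site_rank <- function(type) match(type, SITE_TYPES)

#' Reverse complement of an RNA string
#'
#' Alphabet ACGU; DNA T is accepted and mapped to U first. An involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq RNA (or DNA) string.
#' @return The reverse complement, as RNA.
#' @examples
#' reverse_complement("ACGU")  # "ACGU"
#' @export
reverse_complement <- function(seq) {
  seq <- rna_upper(seq)
  if (nchar(seq) == 0) return("")
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

rna_upper <- function(seq) {
  seq <- chartr("t", "u", tolower(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGU]", seq)) abort("sequence contains non-ACGU(T) characters")
  seq
}

#' Canonical miRNA seed sites on a linear or circular target
#'
#' Scans the target (5'->3') for the four canonical seed-match classes,
#' defined from the miRNA seed (positions 2-8, 5'->3'):
#' \itemize{
#'   \item 8mer: reverse complement of seed 2-8 followed by an A
#'   \item 7mer-m8: reverse complement of seed 2-8
#'   \item 7mer-A1: reverse complement of seed 2-7 followed by an A
#'   \item 6mer: reverse complement of seed 2-7
#' }
#' The A opposite miRNA position 1 is a literal target adenosine. Matches
#' that pair the same seed anchor report only their highest-priority class
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer). With `topology = "circular"` the
#' scan runs over the sequence extended by its first 7 nucleotides, so
#' sites spanning the back-splice junction are found; their positions are
#' reported modulo the target length with `spans_junction = TRUE`.
#'
#' @param mirna Mature miRNA sequence (>= 8 nt, 5'->3').
#' @param target Target sequence (>= 6 nt, 5'->3').
#' @param topology `"linear"` (mRNA 3'UTR) or `"circular"` (circRNA).
#' @return Tibble: site_type, position (1-based site start on the target),
#'   spans_junction, topology.
#' @examples
#' find_seed_sites("UGAGGUAGUAGGUUGUAUAGUU", "AAACUACCUCAAAA")
#' @export
find_seed_sites <- function(mirna, target, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  mirna <- rna_upper(mirna)
  target <- rna_upper(target)
  if (nchar(mirna) < 8) abort("miRNA must be >= 8 nt")
  if (nchar(target) < 6) abort("target must be >= 6 nt")
  rc7 <- reverse_complement(substr(mirna, 2, 8))
  rc6 <- reverse_complement(substr(mirna, 2, 7))
  scan_sites(rc7, rc6, target, topology)
}

# workhorse shared with predict_pairs (patterns precomputed per miRNA)
scan_sites <- function(rc7, rc6, target, topology) {
  len <- nchar(target)
  scan_seq <- if (topology == "circular")
    paste0(target, substr(target, 1, 7)) else target

  pos <- list(fixed_hits(scan_seq, paste0(rc7, "A")),  # 8mer
              fixed_hits(scan_seq, rc7),               # 7mer-m8
              fixed_hits(scan_seq, paste0(rc6, "A")),  # 7mer-A1
              fixed_hits(scan_seq, rc6))               # 6mer
  type <- rep(c("8mer", "7mer-m8", "7mer-A1", "6mer"), lengths(pos))
  rank <- rep(c(4L, 3L, 2L, 1L), lengths(pos))
  anchor_off <- rep(c(6L, 6L, 5L, 5L), lengths(pos))
  site_len <- rep(c(8L, 7L, 7L, 6L), lengths(pos))
  position <- unlist(pos, use.names = FALSE)
  if (length(position) == 0) return(empty_sites(topology))

  end <- position + site_len - 1L
  anchor <- position + anchor_off
  if (topology == "circular") {
    spans <- end > len
    keep <- position <= len
    anchor <- ((anchor[keep] - 1L) %% len) + 1L
    position <- ((position[keep] - 1L) %% len) + 1L
    spans <- spans[keep]; rank <- rank[keep]; type <- type[keep]
  } else {
    keep <- end <= len
    anchor <- anchor[keep]; position <- position[keep]
    rank <- rank[keep]; type <- type[keep]
    spans <- rep(FALSE, length(position))
  }
  if (length(position) == 0) return(empty_sites(topology))
  # one site per seed anchor: keep the strongest class
  o <- order(anchor, -rank, position)
  keep <- o[!duplicated(anchor[o])]
  keep <- keep[order(position[keep])]
  tibble(site_type = type[keep], position = position[keep],
         spans_junction = spans[keep], topology = topology)
}

empty_sites <- function(topology) {
  tibble(site_type = character(), position = integer(),
         spans_junction = logical(), topology = character())
}

fixed_hits <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' Score a set of seed matches for one miRNA-target pair
#'
#' Additive site-class weights: 3 per 8mer, 2 per 7mer-m8 or 7mer-A1,
#' 1 per 6mer.
#'
#' @param matches Tibble of sites as returned by [find_seed_sites()].
#' @return Non-negative score; 0 iff no sites.
#' @export
score_interaction <- function(matches) {
  if (nrow(matches) == 0) return(0)
  w <- c(`8mer` = 3, `7mer-m8` = 2, `7mer-A1` = 2, `6mer` = 1)
  sum(w[matches$site_type])
}

#' All-vs-all miRNA target prediction
#'
#' Scans every miRNA against every target and emits a candidate
#' interaction when at least one site of class `min_site_type` or stronger
#' is present. circRNA targets are scanned circularly (back-splice
#' junction-spanning sites included).
#'
#' @param mirnas Named character vector (or `Biostrings::RNAStringSet`) of
#'   mature miRNA sequences.
#' @param targets Named character vector (or `RNAStringSet`) of target
#'   sequences.
#' @param layer Target layer: `"mRNA"` (linear) or `"circRNA"` (circular).
#' @param min_site_type Weakest class that qualifies a pair
#'   (default `"7mer-A1"`).
#' @return Tibble: mirna, target, layer, n_8mer, n_7mer_m8, n_7mer_A1,
#'   n_6mer, score — ordered by (mirna, target).
#' @export
predict_pairs <- function(mirnas, targets, layer = c("mRNA", "circRNA"),
                          min_site_type = "7mer-A1") {
  layer <- match.arg(layer)
  mirnas <- as_named_seqs(mirnas, "miRNA")
  targets <- as_named_seqs(targets, "target")
  if (length(mirnas) == 0 || length(targets) == 0)
    return(empty_candidates(layer))
  if (!min_site_type %in% SITE_TYPES) abort("unknown min_site_type")
  topology <- if (layer == "circRNA") "circular" else "linear"
  min_rank <- site_rank(min_site_type)

  rc7s <- vapply(mirnas, function(s) reverse_complement(substr(s, 2, 8)),
                 character(1))
  rc6s <- vapply(mirnas, function(s) reverse_complement(substr(s, 2, 7)),
                 character(1))
  rows <- list()
  for (m in names(mirnas)) {
    for (t in names(targets)) {
      sites <- scan_sites(rc7s[[m]], rc6s[[m]], targets[[t]], topology)
      if (nrow(sites) == 0 || max(site_rank(sites$site_type)) < min_rank)
        next
      rows[[length(rows) + 1L]] <- tibble(
        mirna = m, target = t, layer = layer,
        n_8mer = sum(sites$site_type == "8mer"),
        n_7mer_m8 = sum(sites$site_type == "7mer-m8"),
        n_7mer_A1 = sum(sites$site_type == "7mer-A1"),
        n_6mer = sum(sites$site_type == "6mer"),
        score = score_interaction(sites))
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty_candidates(layer))
  arrange(out, .data$mirna, .data$target)
}

empty_candidates <- function(layer) {
  tibble(mirna = character(), target = character(), layer = character(),
         n_8mer = integer(), n_7mer_m8 = integer(), n_7mer_A1 = integer(),
         n_6mer = integer(), score = numeric())
}

as_named_seqs <- function(x, what) {
  if (inherits(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (length(x) == 0) return(character())
  if (is.null(names(x)) || any(names(x) == ""))
    abort(sprintf("%s sequences must be named", what))
  if (anyDuplicated(names(x))) abort(sprintf("duplicate %s ids", what))
  vapply(x, rna_upper, character(1))
}

#' Read RNA FASTA
#'
#' Reads a FASTA file into a named character vector of RNA sequences; DNA
#' input (T) is converted to RNA (U) on read.
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- vapply(as.character(set), rna_upper, character(1))
  setNames(seqs, sub("\\s.*$", "", names(set)))
}

write_rna_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
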