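#' Annotation maps for over-representation analysis
#'
#' An annotation map pairs term ids with feature sets over a universe. The
#' default universe is every feature appearing in the map (the common ORA
#' convention when the assay universe is unknown); pass `universe` to use
#' the experiment's feature set instead.
#'
#' @param terms Tibble (or data frame) with columns `term` and `feature`;
#'   optionally `name` (term description).
#' @param universe Optional character vector of background features.
#' @return An `spng_annotation` list: `sets` (named list of feature sets),
#'   `names` (term descriptions), `universe`.
#' @export
annotation_map <- function(terms, universe = NULL) {
  terms <- tibble::as_tibble(terms)
  if (!all(c("term", "feature") %in% names(terms)))
    abort("annotation needs columns 'term' and 'feature'")
  terms <- distinct(terms, .data$term, .data$feature, .keep_all = TRUE)
  if (is.null(universe)) universe <- sort(unique(terms$feature))
  keep <- terms$feature %in% universe
  if (!all(keep)) {
    warn(sprintf("%d annotation row(s) outside the universe dropped",
                 sum(!keep)))
    terms <- terms[keep, , drop = FALSE]
  }
  sets <- split(terms$feature, terms$term)
  sets <- sets[lengths(sets) > 0]
  nm <- if ("name" %in% names(terms))
    terms |> distinct(.data$term, .data$name) |>
      (\(d) setNames(d$name, d$term))() else NULL
  structure(list(sets = sets, names = nm, universe = universe),
            class = "spng_annotation")
}

#' Read annotation tables
#'
#' `read_annotation_tsv()` reads a two-column TSV (term, feature; an
#' optional third column is the term name). `read_gmt()` reads the GMT
#' dialect (term, description, then member features, tab-separated).
#'
#' @param path File path.
#' @param universe Optional background feature set.
#' @return An `spng_annotation`.
#' @export
read_annotation_tsv <- function(path, universe = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1:2] <- c("term", "feature")
  if (ncol(tbl) >= 3) names(tbl)[3] <- "name"
  annotation_map(tbl, universe)
}

#' @rdname read_annotation_tsv
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  rows <- purrr::map(lines[nzchar(lines)], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort("malformed GMT line (need term, name, members)")
    tibble(term = f[1], name = f[2], feature = f[-(1:2)])
  })
  annotation_map(bind_rows(rows), universe)
}

#' Hypergeometric over-representation analysis
#'
#' Tests every annotation term for over-representation of the query set:
#' p = P(X >= k) with X ~ Hypergeometric(N, K, n), where k is the overlap,
#' K the term size, n the (universe-restricted) query size and N the
#' universe size. P-values are BH-adjusted across all tested terms;
#' a term is significant at FDR <= 0.05. Query features outside the
#' universe are dropped with a warning.
#'
#' @param query Character vector of feature ids.
#' @param annotation An [annotation_map()].
#' @param fdr_threshold Significance threshold on the adjusted p
#'   (default 0.05, non-strict).
#' @return A `spng_enrichment` tibble sorted by p: term, name, k, K, n, N,
#'   p, fdr, significant.
#' @export
ora <- function(query, annotation, fdr_threshold = 0.05) {
  if (!inherits(annotation, "spng_annotation"))
    abort("annotation must come from annotation_map()")
  universe <- annotation$universe
  if (length(universe) == 0) abort("empty universe")
  query <- unique(query)
  if (length(query) == 0) abort("empty query set")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query feature(s) outside the universe dropped",
                 length(outside)))
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) abort("no query features left inside the universe")
  N <- length(universe)
  n <- length(query)
  res <- purrr::imap(annotation$sets, function(members, term) {
    K <- length(members)
    k <- length(intersect(members, query))
    tibble(term = term, k = k, K = K, n = n, N = N,
           p = hypergeom_sf(k, K, n, N))
  }) |> bind_rows()
  res$fdr <- bh_adjust(res$p)
  res$significant <- res$fdr <= fdr_threshold
  res$name <- if (!is.null(annotation$names))
    unname(annotation$names[res$term]) else NA_character_
  res <- res |>
    select("term", "name", "k", "K", "n", "N", "p", "fdr", "significant") |>
    arrange(.data$p, .data$term)
  class(res) <- c("spng_enrichment", class(res))
  res
}
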