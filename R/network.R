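#' Assemble ceRNA triples from filtered edges and sponge tests
#'
#' A triple (circRNA, miRNA, mRNA) is emitted when all four conditions
#' hold: the circRNA-miRNA and miRNA-mRNA pairs passed the negative
#' Spearman filter, the circRNA-mRNA pair passed the positive Pearson
#' filter, and the circRNA-mRNA pair passed the shared-miRNA sponge test.
#' Duplicate input rows do not duplicate triples; output order is
#' deterministic (circ, mirna, mrna).
#'
#' @param circ_mir_edges,mir_mrna_edges Edge tibbles from
#'   [filter_negative_pairs()] (only rows with `passed` are used).
#' @param circ_mrna_edges Edge tibble from [filter_positive_pairs()].
#' @param sponge_results Tibble with columns circ, mrna, k, p, passed
#'   (one row per tested circRNA-mRNA pair; see [sponge_test()]).
#' @return A `spng_triples` tibble: circ, mirna, mrna, scc_circ_mir,
#'   scc_mir_mrna, pcc_circ_mrna, shared_mirnas, sponge_p.
#' @export
assemble_triples <- function(circ_mir_edges, mir_mrna_edges,
                             circ_mrna_edges, sponge_results) {
  cm <- distinct(filter(circ_mir_edges, .data$passed),
                 circ = .data$target, mirna = .data$mirna,
                 scc_circ_mir = .data$coefficient)
  mg <- distinct(filter(mir_mrna_edges, .data$passed),
                 mirna = .data$mirna, mrna = .data$target,
                 scc_mir_mrna = .data$coefficient)
  cg <- distinct(filter(circ_mrna_edges, .data$passed),
                 circ = .data$circ, mrna = .data$mrna,
                 pcc_circ_mrna = .data$coefficient)
  sp <- distinct(filter(sponge_results, .data$passed),
                 circ = .data$circ, mrna = .data$mrna,
                 shared_mirnas = .data$k, sponge_p = .data$p)
  out <- cm |>
    inner_join(mg, by = "mirna", relationship = "many-to-many") |>
    inner_join(cg, by = c("circ", "mrna")) |>
    inner_join(sp, by = c("circ", "mrna")) |>
    distinct(.data$circ, .data$mirna, .data$mrna, .keep_all = TRUE) |>
    select("circ", "mirna", "mrna", "scc_circ_mir", "scc_mir_mrna",
           "pcc_circ_mrna", "shared_mirnas", "sponge_p") |>
    arrange(.data$circ, .data$mirna, .data$mrna)
  class(out) <- c("spng_triples", class(out))
  out
}

#' Build a typed ceRNA network from triples
#'
#' Nodes are typed (circRNA / miRNA / mRNA); each triple contributes a
#' circRNA-miRNA edge and a miRNA-mRNA edge (carrying their Spearman
#' coefficients and the triple's sponge p), and optionally the supporting
#' circRNA-mRNA edge. No self-loops; duplicate edges are collapsed.
#'
#' @param triples A `spng_triples` tibble from [assemble_triples()].
#' @param include_circ_mrna Also add the circRNA-mRNA coexpression edges.
#' @return A `spng_network`: list with `nodes` (id, type, degree), `edges`
#'   (from, to, kind, coefficient, sponge_p) and the underlying
#'   `igraph` graph.
#' @export
build_network <- function(triples, include_circ_mrna = FALSE) {
  edges <- bind_rows(
    triples |> distinct(from = .data$circ, to = .data$mirna,
                        coefficient = .data$scc_circ_mir,
                        sponge_p = .data$sponge_p) |>
      mutate(kind = "circRNA-miRNA"),
    triples |> distinct(from = .data$mirna, to = .data$mrna,
                        coefficient = .data$scc_mir_mrna,
                        sponge_p = .data$sponge_p) |>
      mutate(kind = "miRNA-mRNA"),
    if (include_circ_mrna)
      triples |> distinct(from = .data$circ, to = .data$mrna,
                          coefficient = .data$pcc_circ_mrna,
                          sponge_p = .data$sponge_p) |>
        mutate(kind = "circRNA-mRNA")
  )
  edges <- edges |>
    distinct(.data$from, .data$to, .data$kind, .keep_all = TRUE) |>
    arrange(.data$kind, .data$from, .data$to)
  nodes <- bind_rows(
    tibble(id = unique(triples$circ), type = "circRNA"),
    tibble(id = unique(triples$mirna), type = "miRNA"),
    tibble(id = unique(triples$mrna), type = "mRNA")
  )
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "kind", "coefficient", "sponge_p")],
    directed = FALSE, vertices = nodes)
  nodes$degree <- as.integer(igraph::degree(g)[nodes$id])
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "spng_network")
}

#' @export
print.spng_network <- function(x, ...) {
  cat(network_summary(x), "\n")
  invisible(x)
}

#' One-line network composition summary
#'
#' Formats node-type and edge counts in the conventional reporting style,
#' e.g. "53 circRNA nodes, 44 miRNA nodes, 1375 mRNA nodes, and 428
#' edges".
#'
#' @param network A `spng_network`.
#' @return A string.
#' @export
network_summary <- function(network) {
  tc <- table(factor(network$nodes$type,
                     levels = c("circRNA", "miRNA", "mRNA")))
  sprintf("%d circRNA nodes, %d miRNA nodes, %d mRNA nodes, and %d edges",
          tc[["circRNA"]], tc[["miRNA"]], tc[["mRNA"]], nrow(network$edges))
}

#' Degree-ranked hub nodes
#'
#' Nodes sorted by degree (descending), ties broken lexicographically by
#' id — the "core node" criterion.
#'
#' @param network A `spng_network`.
#' @return Tibble: id, type, degree, ordered.
#' @export
hub_rank <- function(network) {
  if (nrow(network$nodes) == 0) abort("empty network")
  network$nodes |>
    arrange(desc(.data$degree), .data$id) |>
    select("id", "type", "degree")
}

#' Top-k relationship-pair sub-network
#'
#' Keeps the k best edges, ranked by sponge p ascending, then |coefficient|
#' descending, then (from, to) ids; returns the induced sub-network.
#' `k` larger than the edge count returns the full network.
#'
#' @param network A `spng_network`.
#' @param k Number of edges to keep (default 50).
#' @return A `spng_network` on the retained edges.
#' @export
top_edges <- function(network, k = 50) {
  if (k < 1) abort("k must be >= 1")
  ranked <- network$edges |>
    arrange(.data$sponge_p, desc(abs(.data$coefficient)),
            .data$from, .data$to) |>
    head(k)
  ids <- unique(c(ranked$from, ranked$to))
  nodes <- filter(network$nodes, .data$id %in% ids)
  g <- igraph::graph_from_data_frame(
    ranked[, c("from", "to", "kind", "coefficient", "sponge_p")],
    directed = FALSE, vertices = nodes[, c("id", "type")])
  nodes$degree <- as.integer(igraph::degree(g)[nodes$id])
  structure(list(nodes = nodes, edges = ranked, graph = g),
            class = "spng_network")
}

#' Export a ceRNA network
#'
#' GraphML (Cytoscape-compatible, with node type and edge attributes) and
#' SIF ("from<TAB>kind<TAB>to") writers, plus a node-attribute TSV.
#'
#' @param network A `spng_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_sif <- function(network, path) {
  lines <- sprintf("%s\t%s\t%s", network$edges$from, network$edges$kind,
                   network$edges$to)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_node_attributes <- function(network, path) {
  readr::write_tsv(network$nodes, path, progress = FALSE)
  invisible(path)
}
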