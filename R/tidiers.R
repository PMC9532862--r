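#' Broom-style tidiers and plots for spongenet results
#'
#' `tidy()` returns per-feature / per-edge rows; `glance()` a one-row
#' summary. `autoplot()` draws the standard visual for each result type:
#' a volcano plot for DE results, an enrichment dot chart, and a typed
#' force-layout graph for networks.
#'
#' @param x A `spng_de`, `spng_enrichment` or `spng_network` object.
#' @param ... Unused.
#' @name spongenet-tidiers
NULL

#' @rdname spongenet-tidiers
#' @export
tidy.spng_de <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname spongenet-tidiers
#' @export
glance.spng_de <- function(x, ...) {
  tibble(layer = x$layer[1] %||% NA_character_,
         comparison = x$comparison[1] %||% NA_character_,
         n_features = nrow(x),
         n_up = sum(x$call == "up"),
         n_down = sum(x$call == "down"),
         phi = attr(x, "phi") %||% NA_real_)
}

#' @rdname spongenet-tidiers
#' @export
tidy.spng_network <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' @rdname spongenet-tidiers
#' @export
glance.spng_network <- function(x, ...) {
  tc <- table(factor(x$nodes$type, levels = c("circRNA", "miRNA", "mRNA")))
  tibble(n_circ = as.integer(tc[["circRNA"]]),
         n_mirna = as.integer(tc[["miRNA"]]),
         n_mrna = as.integer(tc[["mRNA"]]),
         n_nodes = nrow(x$nodes),
         n_edges = nrow(x$edges))
}

#' @rdname spongenet-tidiers
#' @export
autoplot.spng_de <- function(x, ...) {
  d <- tibble::as_tibble(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#4575b4",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = sprintf("%s: %s", d$layer[1] %||% "",
                                  d$comparison[1] %||% "")) +
    ggplot2::theme_minimal()
}

#' @rdname spongenet-tidiers
#' @export
autoplot.spng_enrichment <- function(x, ...) {
  d <- head(tibble::as_tibble(x), 20)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$fdr), y = .data$term,
                                  size = .data$k,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = "-log10 FDR", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}

#' @rdname spongenet-tidiers
#' @export
autoplot.spng_network <- function(x, ...) {
  lay <- igraph::layout_with_fr(x$graph)
  nodes <- x$nodes
  nodes$x <- lay[, 1]; nodes$y <- lay[, 2]
  idx <- setNames(seq_len(nrow(nodes)), nodes$id)
  edges <- x$edges
  edges$x <- nodes$x[idx[edges$from]]; edges$y <- nodes$y[idx[edges$from]]
  edges$xend <- nodes$x[idx[edges$to]]; edges$yend <- nodes$y[idx[edges$to]]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$type,
                                     size = .data$degree)) +
    ggplot2::scale_colour_manual(values = c(circRNA = "#66c2a5",
                                            miRNA = "#fc8d62",
                                            mRNA = "#8da0cb")) +
    ggplot2::theme_void()
}
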