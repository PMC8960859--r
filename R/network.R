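# Network assembly, volcano data and presentation helpers for correlation
# results.

#' Assemble a bipartite precursor-protease network
#'
#' Builds an igraph network with precursor groups and protease groups as the
#' two node classes, one edge per correlation row. Edge attributes carry
#' `weight` (rho, rendered as edge width in Cytoscape), `p_adj`, `I` and
#' `genus`; node attribute `size` carries the member count when supplied
#' (rendered as node size).
#'
#' @param edges Edge tibble, typically after [filter_edges()].
#' @param node_sizes Optional tibble with columns `node` and `size`
#'   (member counts per group).
#' @return An igraph object; vertex attribute `kind` is `"precursor"` or
#'   `"protease"` and `type` (logical) marks the protease side, making the
#'   graph formally bipartite.
#' @export
assemble_network <- function(edges, node_sizes = NULL) {
  check_columns(edges, c("pre_group", "prot_group", "rho", "p_adj", "I"),
                "edge table")
  edges <- dplyr::filter(edges, !is.na(.data$rho))
  nodes <- tibble(
    name = c(unique(edges$pre_group), unique(edges$prot_group)),
    kind = c(rep("precursor", length(unique(edges$pre_group))),
             rep("protease", length(unique(edges$prot_group)))))
  nodes$type <- nodes$kind == "protease"
  if (!is.null(node_sizes)) {
    check_columns(node_sizes, c("node", "size"), "node size table")
    nodes <- dplyr::left_join(nodes, dplyr::rename(node_sizes, name = "node"),
                              by = "name")
  } else {
    nodes$size <- NA_real_
  }
  edge_df <- dplyr::select(edges, from = "pre_group", to = "prot_group",
                           weight = "rho", dplyr::any_of(c("p_adj", "I",
                                                           "genus")))
  igraph::graph_from_data_frame(edge_df, directed = FALSE, vertices = nodes)
}

#' Volcano-plot table of correlation tests
#'
#' One row per tested pair with a defined coefficient: `rho` against
#' `-log10(p_adj)`, with `p_adj` floored at `epsilon` before the log so that
#' clamped zero p-values stay finite.
#'
#' @param edges Edge tibble from [correlate_groups()] (unfiltered, usually).
#' @param epsilon Floor for `p_adj` (default 1e-300; `-log10` = 300).
#' @return A tibble with `genus`, `pre_group`, `prot_group`, `rho`,
#'   `neg_log10_p_adj`.
#' @export
volcano_table <- function(edges, epsilon = 1e-300) {
  check_columns(edges, c("rho", "p_adj"), "edge table")
  edges |>
    dplyr::filter(!is.na(.data$rho)) |>
    dplyr::mutate(neg_log10_p_adj = -log10(pmax(.data$p_adj, epsilon))) |>
    dplyr::select(dplyr::any_of(c("genus", "pre_group", "prot_group")),
                  "rho", "neg_log10_p_adj")
}

#' Volcano plot of genus-level correlations
#'
#' Scatter of rho against `-log10(p_adj)` for every tested pair, with the
#' prioritization region (rho > `rho_min`, p_adj < `padj_max`) highlighted.
#'
#' @param edges Edge tibble from [correlate_groups()].
#' @param rho_min,padj_max Thresholds drawn as guides (defaults 0.3, 1e-5).
#' @param epsilon Floor for `p_adj` before the log.
#' @return A ggplot object.
#' @export
plot_volcano <- function(edges, rho_min = 0.3, padj_max = 1e-5,
                         epsilon = 1e-300) {
  v <- volcano_table(edges, epsilon = epsilon)
  v$significant <- v$rho > rho_min & v$neg_log10_p_adj > -log10(padj_max)
  ggplot2::ggplot(v, ggplot2::aes(x = .data$rho, y = .data$neg_log10_p_adj,
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = rho_min, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(padj_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#2166ac"),
                                 guide = "none") +
    ggplot2::labs(x = "Spearman ρ",
                  y = expression(-log[10] ~ "adjusted p"),
                  title = "Genus-level precursor-protease correlations")
}

#' Plot a precursor-protease network
#'
#' Force-directed layout of the bipartite network; precursor groups drawn as
#' diamonds, protease groups as circles, node size proportional to member
#' count and edge width to correlation strength.
#'
#' @param graph An igraph object from [assemble_network()].
#' @param seed Layout seed for reproducibility.
#' @return A ggplot object.
#' @export
plot_network <- function(graph, seed = 42) {
  stopifnot(inherits(graph, "igraph"))
  lay <- with_seed(seed, igraph::layout_with_fr(graph))
  nodes <- tibble(name = igraph::V(graph)$name,
                  kind = igraph::V(graph)$kind,
                  size = igraph::V(graph)$size,
                  x = lay[, 1], y = lay[, 2])
  nodes$size[is.na(nodes$size)] <- 1
  ends <- igraph::as_data_frame(graph, what = "edges")
  ends <- dplyr::left_join(ends, nodes[c("name", "x", "y")],
                           by = c(from = "name"))
  ends <- dplyr::left_join(ends, nodes[c("name", "x", "y")],
                           by = c(to = "name"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ends,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$kind, size = .data$size,
                                     colour = .data$kind)) +
    ggplot2::scale_shape_manual(values = c(precursor = 18, protease = 16)) +
    ggplot2::scale_colour_manual(values = c(precursor = "#b2182b",
                                            protease = "#2166ac")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(shape = NULL, colour = NULL, size = "members",
                  linewidth = "ρ")
}

#' Volcano plot of a correlation result
#'
#' @param object A `lan_corr` object from [correlate_groups()].
#' @param ... Passed to [plot_volcano()].
#' @method autoplot lan_corr
#' @export
autoplot.lan_corr <- function(object, ...) {
  plot_volcano(object, ...)
}

#' Tidy a correlation result
#'
#' Returns the edge table as a plain tibble, one row per tested pair.
#'
#' @param x A `lan_corr` object from [correlate_groups()].
#' @param ... Unused.
#' @method tidy lan_corr
#' @export
tidy.lan_corr <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a correlation result
#'
#' @param x A `lan_corr` object from [correlate_groups()].
#' @param rho_min,padj_max,min_I Thresholds used to count prioritized edges
#'   (defaults are the published ones).
#' @param ... Unused.
#' @return A one-row tibble: number of tests, defined tests, genera, and
#'   prioritized edges, plus the BH scope used.
#' @method glance lan_corr
#' @export
glance.lan_corr <- function(x, rho_min = 0.3, padj_max = 1e-5, min_I = 10,
                            ...) {
  tb <- tidy(x)
  tibble(
    n_tests = nrow(tb),
    n_defined = sum(!is.na(tb$rho)),
    n_genera = length(unique(tb$genus)),
    n_prioritized = nrow(filter_edges(tb, rho_min, padj_max, min_I)),
    bh_scope = attr(x, "bh_scope") %||% "pooled")
}
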