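#' Build a signed co-occurrence network from a correlation fit
#'
#' Draws an edge for every taxon pair with `|rho| >= r_min` and adjusted
#' `p <= alpha`; edge weight is the basis correlation, edge sign its sign.
#' Every taxon is kept as a node (isolated nodes included), annotated with
#' its mean relative abundance and ubiquity.
#'
#' @param fit A [sparcc()] fit, with p-values attached via
#'   [sparcc_pvalues()] unless `alpha >= 1`.
#' @param ct The [count_table()] the fit was computed on (node annotations).
#' @param r_min Minimum `|rho|` for an edge, in `[0, 1]`. Default 0.3.
#' @param alpha Significance level applied to Benjamini-Hochberg adjusted
#'   permutation p-values (`p_adjust = "BH"`); `alpha >= 1` keeps every pair
#'   regardless of p. Default 0.05.
#' @param p_adjust Multiple-testing correction over all pairs, passed to
#'   [stats::p.adjust()]. Default `"BH"`.
#' @return A `signed_network`: `nodes` tibble (`taxon`,
#'   `mean_relative_abundance`, `ubiquity`), `edges` tibble (`taxon_a`,
#'   `taxon_b`, `weight`, `sign`, `p`), and the build parameters.
#' @export
build_network <- function(fit, ct, r_min = 0.3, alpha = 0.05,
                          p_adjust = "BH") {
  stopifnot(inherits(fit, "sparcc_fit"))
  if (r_min < 0 || r_min > 1) abort("r_min must lie in [0, 1]")
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (!identical(rownames(m), rownames(fit$rho))) {
    abort("count table and correlation fit disagree on taxa")
  }
  taxa <- rownames(fit$rho)
  ut <- which(upper.tri(fit$rho), arr.ind = TRUE)
  rho <- fit$rho[ut]
  if (alpha < 1) {
    if (is.null(fit$pvals)) {
      abort("fit has no p-values; run sparcc_pvalues() or set alpha >= 1")
    }
    p_raw <- fit$pvals[ut]
    p_adj <- p.adjust(p_raw, method = p_adjust)
  } else {
    p_adj <- rep(0, length(rho))
  }
  keep <- abs(rho) >= r_min & p_adj <= alpha
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  nodes <- tibble(
    taxon = taxa,
    mean_relative_abundance = unname(rowMeans(rel)),
    ubiquity = unname(rowMeans(m > 0))
  )
  edges <- tibble(
    taxon_a = taxa[ut[keep, 1]],
    taxon_b = taxa[ut[keep, 2]],
    weight = rho[keep],
    sign = ifelse(rho[keep] >= 0, "positive", "negative"),
    p = if (alpha < 1) p_adj[keep] else rep(NA_real_, sum(keep))
  )
  structure(
    list(
      nodes = nodes, edges = edges,
      params = list(r_min = r_min, alpha = alpha, p_adjust = p_adjust)
    ),
    class = "signed_network"
  )
}

#' Assemble a signed network directly from node and edge tables
#'
#' Useful for toy networks in examples and tests, or for re-importing an
#' edge list written by [write_edge_list()].
#'
#' @param edges Data frame with `taxon_a`, `taxon_b`, `weight` and
#'   optionally `p`.
#' @param nodes Optional data frame with `taxon` (and optionally abundance /
#'   ubiquity columns); defaults to the taxa appearing in `edges`.
#' @param r_min,alpha Recorded build parameters.
#' @return A `signed_network`.
#' @export
as_signed_network <- function(edges, nodes = NULL, r_min = 0, alpha = 1) {
  edges <- as_tibble(edges)
  if (!all(c("taxon_a", "taxon_b", "weight") %in% names(edges))) {
    abort("edges need columns taxon_a, taxon_b, weight")
  }
  if (any(edges$taxon_a == edges$taxon_b)) abort("self-loops not allowed")
  key <- paste(
    pmin(edges$taxon_a, edges$taxon_b),
    pmax(edges$taxon_a, edges$taxon_b)
  )
  if (anyDuplicated(key)) abort("duplicate edges not allowed")
  edges$sign <- ifelse(edges$weight >= 0, "positive", "negative")
  if (!"p" %in% names(edges)) edges$p <- NA_real_
  if (is.null(nodes)) {
    nodes <- tibble(taxon = sort(unique(c(edges$taxon_a, edges$taxon_b))))
  } else {
    nodes <- as_tibble(nodes)
  }
  if (!"mean_relative_abundance" %in% names(nodes)) {
    nodes$mean_relative_abundance <- NA_real_
  }
  if (!"ubiquity" %in% names(nodes)) nodes$ubiquity <- NA_real_
  structure(
    list(
      nodes = nodes,
      edges = edges[c("taxon_a", "taxon_b", "weight", "sign", "p")],
      params = list(r_min = r_min, alpha = alpha, p_adjust = "none")
    ),
    class = "signed_network"
  )
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf(
    "<signed_network> %d nodes, %d edges (%d positive / %d negative)\n",
    nrow(x$nodes), nrow(x$edges),
    sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")
  ))
  invisible(x)
}

#' @rdname build_network
#' @param x A `signed_network`.
#' @param ... Unused.
#' @export
tidy.signed_network <- function(x, ...) x$edges

#' @rdname build_network
#' @export
glance.signed_network <- function(x, ...) summarize_topology(x)

# igraph view of a signed network; absolute weights on the `w` attribute
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("taxon_a", "taxon_b")],
    directed = FALSE,
    vertices = net$nodes["taxon"]
  )
  igraph::E(g)$weight <- net$edges$weight
  igraph::E(g)$w <- abs(net$edges$weight)
  g
}

#' Plot a signed co-occurrence network
#'
#' Fruchterman-Reingold layout; edge colour encodes the correlation sign,
#' node size the mean relative abundance.
#'
#' @param object A `signed_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signed_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  xy <- with_seed(
    seed,
    igraph::layout_with_fr(g, weights = igraph::E(g)$w)
  )
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  ed <- object$edges
  ed$x <- nodes$x[match(ed$taxon_a, nodes$taxon)]
  ed$y <- nodes$y[match(ed$taxon_a, nodes$taxon)]
  ed$xend <- nodes$x[match(ed$taxon_b, nodes$taxon)]
  ed$yend <- nodes$y[match(ed$taxon_b, nodes$taxon)]
  size <- nodes$mean_relative_abundance
  nodes$size <- if (all(is.na(size))) 1 else size
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        colour = .data$sign, linewidth = abs(.data$weight)
      ),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size)
    ) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#2166AC", negative = "#B2182B")
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::scale_size(range = c(1, 6), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "interaction")
}
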