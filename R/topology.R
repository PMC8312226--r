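#' Topology summary of a signed co-occurrence network
#'
#' One-row tibble with node/edge counts, signed-edge percentages (rounded
#' to 1 decimal, as conventionally reported), unweighted diameter and
#' average path length on the largest connected component, average degree
#' (`2E/N`), weighted degree (mean per-node sum of `|weight|`), modularity
#' and module count from greedy modularity maximisation on absolute
#' weights, and the average local clustering coefficient.
#'
#' @param net A `signed_network`.
#' @return One-row tibble. For an edgeless network the path-based and
#'   community fields are `NA`.
#' @export
summarize_topology <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  n_nodes <- nrow(net$nodes)
  n_edges <- nrow(net$edges)
  n_pos <- sum(net$edges$sign == "positive")
  n_neg <- n_edges - n_pos
  if (n_edges == 0) {
    return(tibble(
      n_nodes = n_nodes, n_edges = 0L, n_positive = 0L, n_negative = 0L,
      pct_positive = NA_real_, pct_negative = NA_real_,
      diameter = NA_real_, average_degree = 0,
      weighted_degree = 0, average_path_length = NA_real_,
      modularity = NA_real_, n_modules = NA_integer_,
      average_clustering = NA_real_
    ))
  }
  g <- as_igraph(net)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize))
  )
  dmat <- igraph::distances(giant, weights = NA)
  finite_off <- dmat[upper.tri(dmat)]
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$w)
  strength <- igraph::strength(g, weights = igraph::E(g)$w)
  tibble(
    n_nodes = n_nodes,
    n_edges = n_edges,
    n_positive = n_pos,
    n_negative = n_neg,
    pct_positive = round(100 * n_pos / n_edges, 1),
    pct_negative = round(100 * n_neg / n_edges, 1),
    diameter = max(finite_off),
    average_degree = 2 * n_edges / n_nodes,
    weighted_degree = mean(strength),
    average_path_length = mean(finite_off),
    modularity = igraph::modularity(comm),
    n_modules = length(comm),
    average_clustering = igraph::transitivity(g,
      type = "localaverage",
      isolates = "zero"
    )
  )
}

#' Worked-example arithmetic for reported network summaries
#'
#' Recomputes the derived columns of a published topology table from its
#' printed counts: signed-edge percentages (`100 * count / edges`, 1
#' decimal) and average degree (`2 * edges / nodes`).
#'
#' @param n_nodes,n_edges,n_positive,n_negative Printed counts (vectorised).
#' @return Tibble with `pct_positive`, `pct_negative`, `average_degree`.
#' @export
topology_arithmetic <- function(n_nodes, n_edges, n_positive, n_negative) {
  tibble(
    n_nodes = n_nodes, n_edges = n_edges,
    pct_positive = round(100 * n_positive / n_edges, 1),
    pct_negative = round(100 * n_negative / n_edges, 1),
    average_degree = 2 * n_edges / n_nodes
  )
}

net_adjacency <- function(net) {
  taxa <- net$nodes$taxon
  a <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  if (nrow(net$edges) > 0) {
    ia <- match(net$edges$taxon_a, taxa)
    ib <- match(net$edges$taxon_b, taxa)
    a[cbind(ia, ib)] <- abs(net$edges$weight)
    a[cbind(ib, ia)] <- abs(net$edges$weight)
  }
  a
}

power_iteration <- function(a, tol = 1e-10, max_iter = 100000L) {
  # positive diagonal shift: same eigenvectors, but strict dominance of the
  # leading eigenvalue even on bipartite graphs (star), where unshifted
  # power iteration oscillates between the two ends of the spectrum
  shift <- 0.5 * max(rowSums(abs(a)))
  v <- rep(1, nrow(a))
  for (i in seq_len(max_iter)) {
    nv <- as.vector(a %*% v) + shift * v
    nrm <- sqrt(sum(nv^2))
    if (nrm == 0) abort("power iteration collapsed (edgeless graph?)")
    nv <- nv / nrm
    if (max(abs(nv - v)) < tol) {
      v <- nv
      break
    }
    v <- nv
  }
  v
}

#' Eigenvector centrality on absolute edge weights
#'
#' Power iteration on the `|weight|` adjacency matrix to tolerance 1e-10,
#' started from the uniform vector (deterministic for symmetric ties), and
#' normalised so the maximum is 1. In disconnected graphs the component
#' with the dominant eigenvalue carries the signal; other components decay
#' towards 0.
#'
#' @param net A `signed_network` with at least one edge.
#' @param tol Convergence tolerance. Default 1e-10.
#' @return Named numeric vector over all nodes, max 1.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10) {
  stopifnot(inherits(net, "signed_network"))
  if (nrow(net$edges) == 0) abort("centrality undefined on an edgeless graph")
  a <- net_adjacency(net)
  v <- power_iteration(a, tol = tol)
  v <- abs(v)
  setNames(v / max(v), rownames(a))
}

#' Kleinberg hub scores
#'
#' Alternating hub/authority updates (`h <- A a`, `a <- t(A) h`); on an
#' undirected graph both fixed points coincide with the eigenvector
#' centrality, which serves as a consistency check. Max-normalised.
#'
#' @param net A `signed_network` with at least one edge.
#' @param tol Convergence tolerance. Default 1e-10.
#' @return Named numeric vector over all nodes, max 1.
#' @export
hub_scores <- function(net, tol = 1e-10) {
  stopifnot(inherits(net, "signed_network"))
  if (nrow(net$edges) == 0) abort("hub scores undefined on an edgeless graph")
  a <- net_adjacency(net)
  h <- rep(1, nrow(a))
  for (i in seq_len(100000L)) {
    auth <- as.vector(crossprod(a, h))
    auth <- auth / sqrt(sum(auth^2))
    nh <- as.vector(a %*% auth)
    nh <- nh / sqrt(sum(nh^2))
    if (max(abs(nh - h)) < tol) {
      h <- nh
      break
    }
    h <- nh
  }
  h <- abs(h)
  setNames(h / max(h), rownames(a))
}

#' Per-taxon ubiquity
#'
#' Fraction of samples in which each taxon is detected (count > 0).
#'
#' @param ct A [count_table()] or count matrix.
#' @return Named numeric vector in `[0, 1]`.
#' @export
ubiquity <- function(ct) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  rowMeans(m > 0)
}

#' Keystone-taxon scoring
#'
#' Applies the three keystoneness criteria: (i) eigenvector centrality at or
#' above the `centrality_quantile` of all node centralities; (ii) ubiquity
#' at least `ubiquity_min`; (iii) mean relative abundance at or above the
#' `abundance_quantile` combined with criterion (i). The composite keystone
#' flag requires all three.
#'
#' @param net A `signed_network` over the taxa of `ct`.
#' @param ct The matching [count_table()].
#' @param centrality_quantile Quantile cut for "high" centrality.
#'   Default 0.9.
#' @param ubiquity_min Minimum presence fraction. Default 0.8.
#' @param abundance_quantile Quantile cut for "high" relative abundance.
#'   Default 0.75.
#' @return Tibble ranked by centrality: `taxon`, `centrality`, `ubiquity`,
#'   `mean_relative_abundance`, `high_centrality`, `ubiquitous`,
#'   `high_abundance_central`, `keystone`.
#' @export
keystoneness <- function(net, ct, centrality_quantile = 0.9,
                         ubiquity_min = 0.8, abundance_quantile = 0.75) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (!setequal(rownames(m), net$nodes$taxon)) {
    abort("network nodes and count-table taxa differ")
  }
  cent <- eigenvector_centrality(net)
  ubiq <- ubiquity(m)[names(cent)]
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  abund <- rowMeans(rel)[names(cent)]
  crit_cent <- cent >= quantile(cent, centrality_quantile)
  crit_ubiq <- ubiq >= ubiquity_min
  crit_abund <- (abund >= quantile(abund, abundance_quantile)) & crit_cent
  out <- tibble(
    taxon = names(cent),
    centrality = unname(cent),
    ubiquity = unname(ubiq),
    mean_relative_abundance = unname(abund),
    high_centrality = unname(crit_cent),
    ubiquitous = unname(crit_ubiq),
    high_abundance_central = unname(crit_abund),
    keystone = unname(crit_cent & crit_ubiq & crit_abund)
  )
  dplyr::arrange(out, dplyr::desc(.data$centrality))
}
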