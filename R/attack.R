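#' Connectivity loss after node removal
#'
#' `CL = 1 - reachable_pairs(after removal) / reachable_pairs(intact)`,
#' where reachable pairs are unordered node pairs joined by a path. For a
#' connected intact graph the denominator is `N (N - 1) / 2`; using the
#' intact graph's own reachable pairs keeps `CL = 0` at zero removals even
#' when isolated nodes are retained.
#'
#' @param net A `signed_network` (or igraph graph).
#' @param removed_nodes Character vector of node names to remove (subset of
#'   the node set; may be empty).
#' @return Connectivity loss in `[0, 1]`.
#' @export
connectivity_loss <- function(net, removed_nodes = character()) {
  g <- if (inherits(net, "signed_network")) as_igraph(net) else net
  all_names <- igraph::V(g)$name
  if (!all(removed_nodes %in% all_names)) {
    abort("removed_nodes must be a subset of the node set")
  }
  base <- reachable_pairs(g)
  if (base == 0) {
    return(0)
  }
  keep <- setdiff(all_names, removed_nodes)
  sub <- igraph::induced_subgraph(g, keep)
  1 - reachable_pairs(sub) / base
}

reachable_pairs <- function(g) {
  if (igraph::vcount(g) == 0) {
    return(0)
  }
  sz <- igraph::components(g)$csize
  sum(sz * (sz - 1) / 2)
}

cl_along_order <- function(g, order_names) {
  base <- reachable_pairs(g)
  n <- igraph::vcount(g)
  cl <- numeric(n + 1)
  cl[1] <- 0
  remaining <- igraph::V(g)$name
  for (k in seq_along(order_names)) {
    remaining <- setdiff(remaining, order_names[k])
    sub <- igraph::induced_subgraph(g, remaining)
    cl[k + 1] <- if (base == 0) 0 else 1 - reachable_pairs(sub) / base
  }
  cl
}

#' Attack-tolerance curve of a network
#'
#' Removes nodes one at a time and tracks connectivity loss.
#' `strategy = "random"` averages the loss curve over `n_iterations`
#' independent uniformly random removal orders; `strategy = "directed"`
#' removes nodes in decreasing order of betweenness centrality computed on
#' the intact unweighted simple graph (ties broken by node ID), optionally
#' recomputing betweenness after each removal.
#'
#' @param net A `signed_network`.
#' @param strategy `"random"` or `"directed"`.
#' @param n_iterations Random-order iterations (random strategy only).
#'   Default 100.
#' @param seed Seed for the random removal orders.
#' @param recompute Recompute betweenness after every removal (directed
#'   strategy only). Default `FALSE`: a single precomputed ranking.
#' @return An `attack_curve`: tibble-backed list with `curve`
#'   (`n_removed`, `fraction`, `cl`), `strategy`, `n_iterations`, and
#'   `removal_order` (directed strategy).
#' @export
attack <- function(net, strategy = c("random", "directed"),
                   n_iterations = 100, seed = 1, recompute = FALSE) {
  strategy <- match.arg(strategy)
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 1) abort("empty network")
  removal_order <- NULL
  if (strategy == "random") {
    if (n_iterations < 1) abort("n_iterations must be >= 1")
    curves <- with_seed(seed, {
      vapply(
        seq_len(n_iterations),
        function(i) cl_along_order(g, sample(igraph::V(g)$name)),
        numeric(n + 1)
      )
    })
    cl <- rowMeans(curves)
    n_iter <- n_iterations
  } else {
    if (recompute) {
      remaining_g <- g
      removal_order <- character(0)
      while (igraph::vcount(remaining_g) > 0) {
        bt <- igraph::betweenness(remaining_g, weights = NA)
        nm <- igraph::V(remaining_g)$name
        pick <- nm[order(-bt, nm)][1]
        removal_order <- c(removal_order, pick)
        remaining_g <- igraph::induced_subgraph(
          remaining_g, setdiff(nm, pick)
        )
      }
    } else {
      bt <- igraph::betweenness(g, weights = NA)
      nm <- igraph::V(g)$name
      removal_order <- nm[order(-bt, nm)]
    }
    cl <- cl_along_order(g, removal_order)
    n_iter <- 1L
  }
  structure(
    list(
      curve = tibble(
        n_removed = 0:n,
        fraction = (0:n) / n,
        cl = cl
      ),
      strategy = strategy,
      n_iterations = n_iter,
      removal_order = removal_order
    ),
    class = "attack_curve"
  )
}

#' @export
print.attack_curve <- function(x, ...) {
  cat(sprintf(
    "<attack_curve> strategy '%s'; %d nodes; CL 0.90 at removal fraction %.3f\n",
    x$strategy, nrow(x$curve) - 1,
    removal_fraction_at_loss(x, 0.90)
  ))
  invisible(x)
}

#' @rdname attack
#' @param x An `attack_curve`.
#' @param ... Unused.
#' @export
tidy.attack_curve <- function(x, ...) {
  dplyr::mutate(x$curve, strategy = x$strategy, .before = 1)
}

#' Removal fraction at a target connectivity loss
#'
#' Smallest removal fraction `k/N` whose (step-function) connectivity loss
#' reaches the target; no interpolation.
#'
#' @param curve An [attack()] result.
#' @param loss_target Target loss in `[0, 1]`. Default 0.90.
#' @return Removal fraction in `[0, 1]`.
#' @export
removal_fraction_at_loss <- function(curve, loss_target = 0.90) {
  stopifnot(inherits(curve, "attack_curve"))
  hit <- which(curve$curve$cl >= loss_target)
  if (length(hit) == 0) {
    abort("loss target never reached (should be impossible at full removal)")
  }
  curve$curve$fraction[hit[1]]
}

#' Run both attack strategies and summarise tolerance
#'
#' @param net A `signed_network`.
#' @param n_iterations Random-attack iterations. Default 100.
#' @param seed Seed for the random attack.
#' @param loss_target Connectivity-loss target. Default 0.90.
#' @return List with `curves` (long tibble over both strategies) and
#'   `fractions` (tibble: strategy, removal fraction at the target).
#' @export
attack_tolerance <- function(net, n_iterations = 100, seed = 1,
                             loss_target = 0.90) {
  rnd <- attack(net, "random", n_iterations = n_iterations, seed = seed)
  dir <- attack(net, "directed")
  list(
    curves = dplyr::bind_rows(tidy(rnd), tidy(dir)),
    fractions = tibble(
      strategy = c("random", "directed"),
      fraction_at_loss = c(
        removal_fraction_at_loss(rnd, loss_target),
        removal_fraction_at_loss(dir, loss_target)
      ),
      loss_target = loss_target
    )
  )
}

#' Plot an attack-tolerance curve
#'
#' @param object An `attack_curve`.
#' @param loss_target Horizontal reference line. Default 0.90.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attack_curve <- function(object, loss_target = 0.90, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$fraction, y = .data$cl)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(
      yintercept = loss_target, linetype = "dashed",
      colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "fraction of nodes removed",
      y = "connectivity loss",
      title = paste0(object$strategy, " attack")
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
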