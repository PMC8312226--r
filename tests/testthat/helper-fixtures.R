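# shared fixtures and independent oracles, built in code

toy_counts <- function(seed = 1, n_taxa = 6, n_samples = 8, lambda = 40) {
  withr::with_seed(seed, {
    m <- matrix(
      rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
      dimnames = list(
        paste0("t", seq_len(n_taxa)),
        paste0("s", seq_len(n_samples))
      )
    )
    m[m == 0] <- 1
    m
  })
}

star_network <- function(n_leaves, weight = 1) {
  as_signed_network(tibble::tibble(
    taxon_a = "hub",
    taxon_b = sprintf("leaf%02d", seq_len(n_leaves)),
    weight = weight
  ))
}

path_network <- function(nodes = c("a", "b", "c", "d")) {
  as_signed_network(tibble::tibble(
    taxon_a = nodes[-length(nodes)],
    taxon_b = nodes[-1],
    weight = 1
  ))
}

complete_network <- function(n) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  as_signed_network(tibble::tibble(
    taxon_a = pairs[, 1], taxon_b = pairs[, 2], weight = 1
  ))
}

random_network <- function(n, p_edge, seed, hub = FALSE) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  withr::with_seed(seed, {
    keep <- runif(nrow(pairs)) < p_edge
    if (hub) keep <- keep | pairs[, 1] == nodes[1]
    as_signed_network(
      tibble::tibble(
        taxon_a = pairs[keep, 1], taxon_b = pairs[keep, 2],
        weight = runif(sum(keep), 0.3, 1) * sample(c(-1, 1), sum(keep),
          replace = TRUE
        )
      ),
      nodes = tibble::tibble(taxon = nodes)
    )
  })
}

# --- independent oracles -------------------------------------------------

# brute-force per-pair variance of log ratios (double loop)
oracle_log_ratio_variance <- function(fractions) {
  d <- nrow(fractions)
  out <- matrix(0, d, d, dimnames = list(
    rownames(fractions),
    rownames(fractions)
  ))
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      out[i, j] <- stats::var(log(fractions[i, ] / fractions[j, ]))
    }
  }
  out
}

# one-shot basis decomposition written independently: explicit system
# matrix with D-1 diagonal / 1 off-diagonal, then the correlation formula
# in loops
oracle_basis_rho <- function(t_mat) {
  d <- nrow(t_mat)
  m <- matrix(1, d, d)
  diag(m) <- d - 1
  omega <- solve(m) %*% rowSums(t_mat)
  rho <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      rho[i, j] <- (omega[i] + omega[j] - t_mat[i, j]) /
        (2 * sqrt(omega[i] * omega[j]))
    }
  }
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

# reachable unordered pairs by BFS from every node (no igraph)
oracle_reachable_pairs <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges$taxon_a[k]
    b <- edges$taxon_b[k]
    if (a %in% nodes && b %in% nodes) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  count <- 0
  for (s in nodes) {
    seen <- s
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- setdiff(adj[[v]], seen)
      seen <- c(seen, nb)
      queue <- c(queue, nb)
    }
    count <- count + length(setdiff(seen, s))
  }
  count / 2
}

oracle_connectivity_loss <- function(net, removed) {
  nodes <- net$nodes$taxon
  base <- oracle_reachable_pairs(net$edges, nodes)
  after <- oracle_reachable_pairs(net$edges, setdiff(nodes, removed))
  1 - after / base
}

balanced_tree_4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}
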