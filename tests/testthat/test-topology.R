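test_that("triangle topology matches closed forms", {
  tri <- as_signed_network(tibble::tibble(
    taxon_a = c("a", "b", "a"), taxon_b = c("b", "c", "c"),
    weight = c(1, 1, 1)
  ))
  topo <- summarize_topology(tri)
  expect_equal(topo$average_degree, 2)
  expect_equal(topo$diameter, 1)
  expect_equal(topo$average_clustering, 1)
  expect_equal(topo$pct_positive, 100)
  expect_equal(topo$n_positive + topo$n_negative, topo$n_edges)
  expect_equal(topo$average_path_length, 1)
})

test_that("edgeless networks give a flagged empty report", {
  net <- as_signed_network(
    tibble::tibble(
      taxon_a = character(), taxon_b = character(),
      weight = numeric()
    ),
    nodes = tibble::tibble(taxon = c("a", "b"))
  )
  topo <- summarize_topology(net)
  expect_equal(topo$n_edges, 0L)
  expect_true(is.na(topo$diameter))
  expect_true(is.na(topo$modularity))
})

test_that("modularity of disjoint cliques equals its closed form", {
  k <- 3
  nets <- lapply(1:k, function(i) {
    nodes <- paste0("c", i, "_", 1:4)
    pairs <- t(utils::combn(nodes, 2))
    tibble::tibble(taxon_a = pairs[, 1], taxon_b = pairs[, 2], weight = 1)
  })
  net <- as_signed_network(dplyr::bind_rows(nets))
  topo <- summarize_topology(net)
  expect_equal(topo$modularity, 1 - 1 / k, tolerance = 1e-10)
  expect_equal(topo$n_modules, k)
})

test_that("published-summary arithmetic reproduces printed percentages", {
  pub <- published_network_summary()
  arith <- topology_arithmetic(
    pub$nodes, pub$edges, pub$positive_edges, pub$negative_edges
  )
  ctrl <- arith[pub$network == "control", ]
  expect_equal(ctrl$pct_positive, 73.7)
  expect_equal(ctrl$pct_negative, 26.3)
  expect_equal(round(ctrl$average_degree, 1), 11.2)
})

test_that("eigenvector centrality matches the analytic star solution", {
  star <- star_network(8)
  cent <- eigenvector_centrality(star)
  expect_equal(unname(cent["hub"]), 1)
  expect_equal(
    unname(cent[startsWith(names(cent), "leaf")]),
    rep(1 / sqrt(8), 8),
    tolerance = 1e-8
  )
  k5 <- complete_network(5)
  expect_equal(unname(eigenvector_centrality(k5)), rep(1, 5))
  expect_error(
    eigenvector_centrality(as_signed_network(
      tibble::tibble(
        taxon_a = character(), taxon_b = character(),
        weight = numeric()
      ),
      nodes = tibble::tibble(taxon = "a")
    )),
    "edgeless"
  )
})

test_that("power iteration agrees with dense eigendecomposition", {
  for (s in 1:5) {
    net <- random_network(30, 0.15, seed = s, hub = TRUE)
    cent <- eigenvector_centrality(net)
    a <- abs(micronet:::net_adjacency(net))
    ev <- abs(eigen(a, symmetric = TRUE)$vectors[, 1])
    ev <- ev / max(ev)
    expect_equal(unname(cent), ev, tolerance = 1e-8)
  }
})

test_that("hub scores equal eigenvector centrality on undirected graphs", {
  net <- random_network(20, 0.2, seed = 3)
  expect_equal(hub_scores(net), eigenvector_centrality(net),
    tolerance = 1e-8
  )
  expect_equal(unname(hub_scores(star_network(4))["hub"]), 1)
  # relabeling invariance
  ed <- net$edges
  relab <- function(x) paste0("X", x)
  net2 <- as_signed_network(
    dplyr::mutate(ed,
      taxon_a = relab(taxon_a),
      taxon_b = relab(taxon_b)
    ),
    nodes = tibble::tibble(taxon = relab(net$nodes$taxon))
  )
  h1 <- hub_scores(net)
  h2 <- hub_scores(net2)
  expect_equal(unname(h2[relab(names(h1))]), unname(h1), tolerance = 1e-9)
})

test_that("ubiquity is the presence fraction", {
  m <- matrix(0, 3, 12, dimnames = list(c("all", "none", "some"), NULL))
  m["all", ] <- 5
  m["some", 1:3] <- 2
  colnames(m) <- paste0("s", 1:12)
  u <- ubiquity(count_table(m))
  expect_equal(unname(u), c(1, 0, 0.25))
})

test_that("keystoneness flags a central, ubiquitous, abundant taxon", {
  cfg <- sim_config(depletion_factor = 1, seed = 101)
  ct <- simulate_counts(cfg)
  fit <- sparcc(ct, seed = 102)
  net <- build_network(fit, ct, r_min = 0.3, alpha = 1)
  ks <- keystoneness(net, ct)
  expect_true(ks$keystone[ks$taxon == "hub"])
  # a rare background taxon never qualifies
  rare <- ks[ks$taxon == "taxon_21", ]
  expect_false(rare$keystone)
  expect_error(
    keystoneness(net, count_table(toy_counts())),
    "differ"
  )
})

test_that("composite keystone flag is the conjunction of the criteria", {
  net <- random_network(12, 0.3, seed = 9)
  m <- toy_counts(seed = 9, n_taxa = 12, n_samples = 10)
  rownames(m) <- net$nodes$taxon
  ks <- keystoneness(net, m)
  expect_equal(
    ks$keystone,
    ks$high_centrality & ks$ubiquitous & ks$high_abundance_central
  )
  expect_true(all(ks$high_abundance_central <= ks$high_centrality))
  expect_equal(max(ks$centrality), 1)
})
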