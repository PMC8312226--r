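test_that("rarefaction conserves depth and full draws are identity", {
  ct <- count_table(toy_counts(seed = 2, lambda = 100))
  r <- rarefy(ct, depth = 300, seed = 1)
  expect_true(all(colSums(r$counts) == 300))
  full <- rarefy(ct, depth = min(colSums(ct$counts)), seed = 1)
  j <- which.min(colSums(ct$counts))
  expect_equal(full$counts[, j], ct$counts[, j])
  expect_identical(rarefy(ct, 300, seed = 1)$counts, r$counts)
  expect_error(rarefy(ct, depth = 0), "positive")
  expect_warning(rarefy(ct, depth = max(colSums(ct$counts))), "dropping")
})

test_that("rarefied counts match the hypergeometric mean", {
  m <- matrix(c(400, 300, 200, 100), 4, 1,
    dimnames = list(paste0("t", 1:4), "s1")
  )
  ct <- count_table(m)
  depth <- 250
  draws <- vapply(
    1:1000,
    function(s) rarefy(ct, depth, seed = s)$counts[, 1],
    numeric(4)
  )
  expect_equal(
    rowMeans(draws),
    depth * m[, 1] / sum(m),
    tolerance = 0.02
  )
})

test_that("Faith PD reproduces hand-enumerated subtrees", {
  tr <- balanced_tree_4()
  m <- matrix(0, 4, 3, dimnames = list(c("A", "B", "C", "D"), c("s1", "s2", "s3")))
  m[, 1] <- 1 # all taxa
  m["A", 2] <- 1 # one tip
  m[c("A", "C"), 3] <- 1 # two tips across the root
  pd <- faith_pd(count_table(m), tr)
  expect_equal(pd$faith_pd[pd$sample == "s1"], 6)
  expect_equal(pd$faith_pd[pd$sample == "s2"], 2)
  expect_equal(pd$faith_pd[pd$sample == "s3"], 4)
  bad <- rbind(m, E = 1)
  expect_error(faith_pd(count_table(bad), tr), "E")
})

test_that("Faith PD is monotone under added taxa", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_microbiome(cfg)
  m <- sim$counts$counts
  base <- m
  base["hub", ] <- 0
  more <- m
  pd0 <- faith_pd(count_table(base), sim$tree)$faith_pd
  pd1 <- faith_pd(count_table(more), sim$tree)$faith_pd
  expect_true(all(pd1 >= pd0 - 1e-12))
})

test_that("Shannon and Pielou match closed forms and scale invariance", {
  m <- cbind(
    uniform = rep(5, 8),
    skew = c(90, 10, rep(0, 6)),
    single = c(42, rep(0, 7))
  )
  rownames(m) <- paste0("t", 1:8)
  a <- alpha_diversity(count_table(m))
  expect_equal(a$shannon[a$sample == "uniform"], log(8))
  expect_equal(a$pielou[a$sample == "uniform"], 1)
  expect_equal(a$shannon[a$sample == "skew"],
    -0.9 * log(0.9) - 0.1 * log(0.1),
    tolerance = 1e-4
  )
  expect_true(is.na(a$pielou[a$sample == "single"]))
  expect_true(a$degenerate[a$sample == "single"])
  scaled <- alpha_diversity(count_table(m * 7))
  expect_equal(scaled$shannon, a$shannon)
})

test_that("Bray-Curtis matches its formula and metric properties", {
  m <- cbind(u = c(6, 0, 2), v = c(2, 2, 4), w = c(6, 0, 2), z = c(0, 9, 0))
  rownames(m) <- paste0("t", 1:3)
  bc <- bray_curtis(count_table(m))
  expect_equal(bc["u", "v"], 0.5)
  expect_equal(bc["u", "w"], 0) # identical samples
  expect_equal(bc["u", "z"], 1) # disjoint support
  expect_equal(bc, t(bc))
  expect_equal(unname(diag(bc)), rep(0, 4))
  withr::with_seed(8, {
    r <- matrix(rpois(5 * 20, 30), 5, 20,
      dimnames = list(paste0("t", 1:5), paste0("s", 1:20))
    )
  })
  bcr <- bray_curtis(count_table(r))
  expect_true(all(bcr >= 0 & bcr <= 1))
})

test_that("PERMANOVA separates disjoint groups and is order-invariant", {
  m <- cbind(
    matrix(c(30, 20, 0, 0), 4, 4), matrix(c(0, 0, 25, 15), 4, 4)
  )
  dimnames(m) <- list(paste0("t", 1:4), paste0("s", 1:8))
  m <- m + withr::with_seed(4, matrix(rbinom(32, 2, 0.5), 4, 8))
  labels <- rep(c("a", "b"), each = 4)
  bc <- bray_curtis(count_table(m))
  res <- permanova(bc, labels, n_perm = 199, seed = 1)
  # with 4+4 samples only C(8,4) = 70 distinct label permutations exist, so
  # repeated draws tie with the observed split; the attainable floor is a
  # few re-draws of the identity/complement above 1/200
  expect_lte(res$p, 0.05)
  expect_gt(res$pseudo_f, 10)
  perm <- c(3, 7, 1, 5, 2, 8, 6, 4)
  res2 <- permanova(bc[perm, perm], labels[perm], n_perm = 199, seed = 1)
  expect_equal(res2$pseudo_f, res$pseudo_f, tolerance = 1e-10)
  expect_error(permanova(bc, rep("a", 8)), "2 groups")
})

test_that("rank tests match closed forms and the exhaustive enumeration", {
  expect_equal(kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$statistic,
    0,
    tolerance = 1e-9
  )
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  # exhaustive rank-sum null at n = (4, 4): enumerate all assignments
  a <- c(1.3, 2.1, 4.7, 5.2)
  b <- c(0.8, 3.3, 3.9, 6.0)
  u_obs <- mann_whitney(a, b)$statistic
  pooled <- c(a, b)
  combos <- utils::combn(8, 4)
  u_null <- apply(combos, 2, function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - 4 * 5 / 2
  })
  p_exact <- mean(abs(u_null - 8) >= abs(u_obs - 8))
  expect_equal(mann_whitney(a, b, exact = TRUE)$p, p_exact)
  expect_true(kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3))$degenerate)
})

test_that("PCoA coordinates preserve the dominant separation", {
  m <- withr::with_seed(12, cbind(
    matrix(rpois(20, 40), 5, 4),
    matrix(rpois(20, 40), 5, 4) + 60
  ))
  dimnames(m) <- list(paste0("t", 1:5), paste0("s", 1:8))
  bc <- bray_curtis(count_table(m))
  co <- pcoa_coordinates(bc, k = 2)
  expect_named(co, c("sample", "axis_1", "axis_2"))
  groups <- rep(c(1, 2), each = 4)
  expect_gt(
    abs(mean(co$axis_1[groups == 1]) - mean(co$axis_1[groups == 2])),
    sd(co$axis_1[groups == 1]) + sd(co$axis_1[groups == 2])
  )
})
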