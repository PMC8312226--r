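test_that("fraction conversion normalises, is strict-positive and seeded", {
  m <- matrix(2, 4, 3, dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  f <- to_fractions(m, "pseudocount")
  expect_equal(unname(f[, 1]), rep(0.25, 4))
  d1 <- to_fractions(m, "dirichlet_draw", seed = 7)
  expect_true(all(d1 > 0 & d1 < 1))
  expect_equal(unname(colSums(d1)), rep(1, 3), tolerance = 1e-12)
  expect_identical(d1, to_fractions(m, "dirichlet_draw", seed = 7))
  zero <- m
  zero[, 2] <- 0
  expect_error(to_fractions(zero), "s2")
})

test_that("log-ratio variances match the brute-force double loop", {
  f <- to_fractions(toy_counts(seed = 2, n_taxa = 4, n_samples = 6))
  t_mat <- log_ratio_variance(f)
  expect_equal(t_mat, oracle_log_ratio_variance(f), tolerance = 1e-12)
  expect_equal(unname(diag(t_mat)), rep(0, 4))
  expect_true(all(t_mat >= 0))
  # perfectly proportional taxa have zero log-ratio variance
  f2 <- rbind(f, prop = 3 * f[1, ])
  f2 <- sweep(f2, 2, colSums(f2), "/")
  expect_equal(log_ratio_variance(f2)["t1", "prop"], 0, tolerance = 1e-12)
  expect_error(log_ratio_variance(f[, 1, drop = FALSE]), "2 samples")
})

test_that("basis decomposition matches the independent one-shot oracle", {
  withr::with_seed(10, {
    for (rep in 1:5) {
      n_taxa <- sample(5:10, 1)
      f <- to_fractions(toy_counts(
        seed = rep, n_taxa = n_taxa,
        n_samples = 12
      ))
      t_mat <- log_ratio_variance(f)
      bc <- basis_correlation(t_mat)
      expect_equal(bc$rho, oracle_basis_rho(t_mat),
        ignore_attr = TRUE, tolerance = 1e-10
      )
      expect_equal(unname(diag(bc$rho)), rep(1, n_taxa))
      expect_true(all(abs(bc$rho) <= 1))
    }
  })
  expect_error(basis_correlation(matrix(0, 3, 3)), "at least 4")
})

test_that("independent basis variables give near-zero correlations", {
  withr::with_seed(5, {
    la <- matrix(rnorm(12 * 500, 4, 1), 12, 500)
    f <- sweep(exp(la), 2, colSums(exp(la)), "/")
    rownames(f) <- paste0("t", 1:12)
  })
  bc <- basis_correlation(log_ratio_variance(f))
  expect_lt(mean(abs(bc$rho[upper.tri(bc$rho)])), 0.1)
})

test_that("a planted basis correlation is recovered", {
  withr::with_seed(6, {
    z <- rnorm(500)
    la <- matrix(rnorm(10 * 500, 4, 1), 10, 500)
    la[1, ] <- 4 + (0.9 * z + sqrt(1 - 0.81) * rnorm(500))
    la[2, ] <- 4 + (0.9 * z + sqrt(1 - 0.81) * rnorm(500))
    # planted pair correlates at 0.9^2 / 1 = 0.81... use direct construction
    la[2, ] <- 4 + 0.9 * (la[1, ] - 4) + sqrt(1 - 0.81) * rnorm(500)
    f <- sweep(exp(la), 2, colSums(exp(la)), "/")
    rownames(f) <- paste0("t", 1:10)
  })
  bc <- basis_correlation(log_ratio_variance(f))
  expect_equal(bc$rho["t1", "t2"], 0.9, tolerance = 0.15)
})

test_that("relabeling taxa permutes the correlation matrix identically", {
  m <- toy_counts(seed = 9, n_taxa = 6, n_samples = 10)
  bc <- basis_correlation(log_ratio_variance(to_fractions(m)))
  perm <- c(3, 1, 6, 2, 5, 4)
  bc_p <- basis_correlation(log_ratio_variance(to_fractions(m[perm, ])))
  expect_equal(bc_p$rho, bc$rho[perm, perm], tolerance = 1e-12)
})

test_that("sparcc with exclusion disabled is the median of plain draws", {
  m <- toy_counts(seed = 12, n_taxa = 6, n_samples = 10)
  fit <- sparcc(m,
    n_inference_iter = 5, exclusion_threshold = 1,
    seed = 99
  )
  expect_length(fit$excluded_pairs, 0)
  manual <- withr::with_seed(99L, {
    draws <- lapply(1:5, function(i) {
      f <- to_fractions(m, "dirichlet_draw")
      basis_correlation(log_ratio_variance(f))$rho
    })
    apply(simplify2array(draws), c(1, 2), median)
  })
  diag(manual) <- 1
  expect_equal(fit$rho, manual, tolerance = 1e-12)
})

test_that("sparcc is deterministic given a seed", {
  m <- toy_counts(seed = 13, n_taxa = 8, n_samples = 10)
  # near-null tables legitimately trigger the omega-clamp warning
  f1 <- suppressWarnings(sparcc(m, n_inference_iter = 1, seed = 3))
  f2 <- suppressWarnings(sparcc(m, n_inference_iter = 1, seed = 3))
  expect_identical(f1$rho, f2$rho)
})

test_that("correlations are robust to per-sample count rescaling", {
  cfg <- sim_config(n_samples_per_group = 12, seed = 17)
  ct <- simulate_counts(cfg)
  m <- ct$counts
  scaled <- round(sweep(
    m, 2, rep(c(1, 3, 0.5), length.out = ncol(m)), "*"
  ))
  f1 <- sparcc(m, n_inference_iter = 10, seed = 5)
  f2 <- sparcc(scaled, n_inference_iter = 10, seed = 5)
  off <- upper.tri(f1$rho)
  expect_lt(mean(abs(f1$rho[off] - f2$rho[off])), 0.05)
  expect_gt(cor(f1$rho[off], f2$rho[off]), 0.95)
})

test_that("planted hub-satellite correlations rank among the strongest", {
  cfg <- sim_config(depletion_factor = 1, seed = 23)
  ct <- simulate_counts(cfg)
  fit <- sparcc(ct, seed = 24)
  td <- tidy(fit)
  hub_sat <- td$rho[
    (td$taxon_a == "hub" & startsWith(td$taxon_b, "sat")) |
      (td$taxon_b == "hub" & startsWith(td$taxon_a, "sat"))
  ]
  expect_true(all(hub_sat > 0))
  top5 <- quantile(abs(td$rho), 0.95)
  expect_gt(mean(abs(hub_sat) >= top5), 0.5)
})

test_that("permutation pseudo-p-values honour their closed-form bounds", {
  m <- toy_counts(seed = 31, n_taxa = 5, n_samples = 12)
  fit <- suppressWarnings(sparcc(m, n_inference_iter = 2, seed = 1))
  fit <- suppressWarnings(sparcc_pvalues(fit, n_perm = 99, seed = 2))
  p <- fit$pvals[upper.tri(fit$pvals)]
  expect_true(all(p >= 1 / 100 & p <= 1))
  expect_error(sparcc_pvalues(fit, n_perm = 0), "n_perm")
})

test_that("a duplicated taxon pair attains the minimum pseudo-p-value", {
  # strong between-sample variation so the duplicated pair's correlation
  # survives Dirichlet resampling noise
  m <- withr::with_seed(33, {
    matrix(
      rpois(5 * 16, exp(rnorm(5 * 16, log(200), 1.2))) + 1, 5, 16,
      dimnames = list(paste0("t", 1:5), paste0("s", 1:16))
    )
  })
  m <- rbind(m, dup = m[1, ])
  fit <- sparcc(m,
    n_inference_iter = 3, exclusion_threshold = 1,
    seed = 4
  )
  expect_gt(fit$rho["t1", "dup"], 0.95)
  fit <- suppressWarnings(sparcc_pvalues(fit, n_perm = 19, seed = 5))
  expect_equal(fit$pvals["t1", "dup"], 1 / 20)
})
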