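test_that("configuration errors are caught", {
  expect_error(sim_config(depth = -1), "depth")
  expect_error(sim_config(hub_satellite_rho = 1.2), "rho")
  expect_error(sim_config(n_satellites = 30, n_taxa = 30), "n_satellites")
  expect_error(sim_config(depletion_factor = 0), "depletion_factor")
})

test_that("multinomial sampling conserves depth and is seed-reproducible", {
  cfg <- sim_config(seed = 11)
  ct <- simulate_counts(cfg)
  expect_true(all(colSums(ct$counts) == cfg$depth))
  expect_identical(simulate_counts(cfg)$counts, ct$counts)
  expect_false(identical(
    simulate_counts(sim_config(seed = 12))$counts, ct$counts
  ))
})

test_that("no-effect null leaves hub abundance comparable across groups", {
  cfg <- sim_config(depletion_factor = 1, seed = 21)
  ct <- simulate_counts(cfg)
  hub_clr <- clr_transform(ct)["hub", ]
  kw <- kruskal_wallis(hub_clr, ct$metadata$group)
  expect_gt(kw$p, 0.01)
})

test_that("planted hub-satellite coupling survives multinomial sampling", {
  cfg <- sim_config(
    n_samples_per_group = 50, depth = 50000,
    hub_satellite_rho = 0.8, depletion_factor = 1, seed = 31
  )
  ct <- simulate_counts(cfg)
  cl <- clr_transform(ct)
  r <- cor(cl["hub", ], cl["sat_1", ])
  expect_gt(r, 0.5)
})

test_that("hub lands at hub_index and depletion shifts only the hub", {
  cfg <- sim_config(hub_index = 5, seed = 41)
  ct <- simulate_counts(cfg)
  expect_identical(rownames(ct$counts)[5], "hub")
  cfg2 <- sim_config(hub_index = 5, depletion_factor = 0.1, seed = 41)
  ct2 <- simulate_counts(cfg2)
  grp <- ct$metadata$group
  rel1 <- relative_abundance(ct)
  rel2 <- relative_abundance(ct2)
  expect_lt(
    mean(rel2["hub", grp == "keystone_vax"]),
    0.5 * mean(rel1["hub", grp == "keystone_vax"])
  )
  # untouched groups keep identical latent draws
  expect_equal(
    mean(abs(
      rel1["hub", grp == "mock"] - rel2["hub", grp == "mock"]
    )), 0, tolerance = 0.002
  )
})

test_that("antibody ODs are non-negative with noise-free perfect coupling", {
  cfg <- sim_config(od_noise_sd = 0, seed = 51)
  ct <- simulate_counts(cfg)
  ab <- simulate_antibody(cfg, ct)
  expect_true(all(ab$od >= 0))
  pooled <- ab[ab$isotype == "IgG" & ab$day == 30 &
    ab$group %in% c("mock", "keystone_vax"), ]
  p_hub <- relative_abundance(ct)["hub", pooled$sample]
  expect_equal(
    cor(pooled$od, p_hub, method = "spearman"), -1
  )
  kv <- ab$od[ab$group == "keystone_vax" & ab$day == 30 & ab$isotype == "IgG"]
  mock <- ab$od[ab$group == "mock" & ab$day == 30 & ab$isotype == "IgG"]
  expect_gt(mean(kv), mean(mock))
  unfed <- ab$od[ab$group == "unfed" & ab$day == 30 & ab$isotype == "IgG"]
  expect_gt(min(kv), max(unfed))
})

test_that("coalescent tree covers the taxa and serialises losslessly", {
  cfg <- sim_config(seed = 61)
  tr <- simulate_tree(cfg)
  expect_setequal(tr$tip.label, rownames(simulate_counts(cfg)$counts))
  expect_true(all(tr$edge.length > 0))
  expect_identical(
    ape::write.tree(tr),
    ape::write.tree(simulate_tree(cfg))
  )
  tiny <- sim_config(n_taxa = 2, n_satellites = 0, seed = 62)
  tr2 <- simulate_tree(tiny)
  expect_equal(ape::Ntip(tr2), 2L)
  expect_gt(sum(tr2$edge.length), 0)
  expect_error(
    simulate_tree(sim_config(n_taxa = 1, n_satellites = 0)),
    "at least 2"
  )
})

test_that("gene content carries hub markers and a one-to-one pathway map", {
  cfg <- sim_config(seed = 71)
  ct <- simulate_counts(cfg)
  fg <- simulate_gene_content(cfg, ct)
  expect_equal(unname(fg$gene_content["hub", c("atoB", "eutD")]), c(1, 1))
  expect_true(all(fg$gene_content[-cfg$hub_index, c("atoB", "eutD")] == 0))
  expect_setequal(fg$pathway_map$gene, colnames(fg$gene_content))
  expect_false(anyDuplicated(fg$pathway_map$gene) > 0)
  expect_true(all(is.finite(fg$ct_table$ct)))
  expect_true(all(table(fg$ct_table$sample) == 3)) # 2 targets + housekeeping
})

test_that("marker ddCt fold change is depressed under keystone vaccination", {
  cfg <- sim_config(seed = 81)
  sim <- simulate_microbiome(cfg)
  fc <- ddct_fold_change(sim$ct_table, "atoB", "rsp4", "mock")
  gm <- fc$group_means
  expect_lt(
    gm$mean_fold_change[gm$group == "keystone_vax"], 1
  )
})

test_that("bundle writing produces re-readable plain-text files", {
  cfg <- sim_config(seed = 91)
  sim <- simulate_microbiome(cfg)
  dir <- withr::local_tempdir()
  write_bundle(sim, dir)
  back <- read_counts(
    file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv")
  )
  expect_equal(back$counts, sim$counts$counts)
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, sim$tree$tip.label)
})
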