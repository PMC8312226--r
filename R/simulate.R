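#' Configuration for the synthetic microbiome generator
#'
#' Describes a four-group tick-feeding study: unfed ticks, ticks fed on
#' mock-immunized hosts, on hosts immunized against the planted keystone
#' ("hub") taxon, and on hosts immunized against a non-keystone taxon.
#' Latent absolute abundances are log-normal with a correlation block tying
#' the hub to its satellite taxa; observed counts are multinomial
#' compositions at fixed sequencing depth.
#'
#' @param n_taxa Number of taxa (genus-level units). Default 30.
#' @param n_samples_per_group Samples (5-tick pools) per group. Default 7.
#' @param groups Group labels, in order.
#' @param depth Sequencing depth per sample (reads). Default 20000.
#' @param hub_index Row index of the planted keystone taxon. Default 1.
#' @param n_satellites Number of taxa latently correlated with the hub.
#' @param hub_satellite_rho Latent hub-satellite correlation in `[-1, 1]`.
#' @param depletion_factor Multiplier applied to the hub's latent abundance
#'   in the `keystone_vax` group; values in `(0, 1]`, 1 = no effect.
#' @param od_noise_sd Gaussian noise SD on simulated antibody OD values.
#' @param ct_noise_sd Gaussian noise SD on simulated qPCR Ct values.
#' @param log_sd Between-sample SD of latent log abundances. Samples model
#'   5-tick pools, whose averaging damps per-tick variability; the default
#'   0.4 corresponds to tick-level log-SD near 0.9 pooled five-fold.
#' @param seed Master seed; every sub-generator derives a child seed from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 30,
                       n_samples_per_group = 7,
                       groups = c(
                         "unfed", "mock", "keystone_vax",
                         "nonkeystone_vax"
                       ),
                       depth = 20000,
                       hub_index = 1,
                       n_satellites = 8,
                       hub_satellite_rho = 0.8,
                       depletion_factor = 0.25,
                       od_noise_sd = 0.1,
                       ct_noise_sd = 0.1,
                       log_sd = 0.4,
                       seed = 1) {
  cfg <- list(
    n_taxa = as.integer(n_taxa),
    n_samples_per_group = as.integer(n_samples_per_group),
    groups = as.character(groups),
    depth = depth,
    hub_index = as.integer(hub_index),
    n_satellites = as.integer(n_satellites),
    hub_satellite_rho = hub_satellite_rho,
    depletion_factor = depletion_factor,
    od_noise_sd = od_noise_sd,
    ct_noise_sd = ct_noise_sd,
    log_sd = log_sd,
    seed = as.integer(seed)
  )
  if (cfg$depth <= 0) abort("depth must be positive")
  if (cfg$n_taxa < 2) abort("need at least 2 taxa")
  if (cfg$n_satellites >= cfg$n_taxa) abort("n_satellites must be < n_taxa")
  if (abs(cfg$hub_satellite_rho) > 1) {
    abort("hub_satellite_rho must lie in [-1, 1]")
  }
  if (cfg$depletion_factor <= 0) abort("depletion_factor must be > 0")
  if (cfg$hub_index < 1 || cfg$hub_index > cfg$n_taxa) {
    abort("hub_index out of range")
  }
  if (cfg$od_noise_sd < 0 || cfg$ct_noise_sd < 0 || cfg$log_sd < 0) {
    abort("noise SDs must be non-negative")
  }
  class(cfg) <- "sim_config"
  cfg
}

# taxa in "role order": hub, satellites, background tail
sim_taxa_roles <- function(cfg) {
  n_bg <- cfg$n_taxa - 1 - cfg$n_satellites
  c(
    "hub",
    if (cfg$n_satellites > 0) paste0("sat_", seq_len(cfg$n_satellites)),
    if (n_bg > 0) paste0("taxon_", seq_len(n_bg))
  )
}

# row positions assigned to role order, so the hub sits at cfg$hub_index
sim_role_positions <- function(cfg) {
  c(cfg$hub_index, setdiff(seq_len(cfg$n_taxa), cfg$hub_index))
}

sim_taxa <- function(cfg) {
  taxa <- character(cfg$n_taxa)
  taxa[sim_role_positions(cfg)] <- sim_taxa_roles(cfg)
  taxa
}

sim_samples <- function(cfg) {
  unlist(lapply(cfg$groups, function(g) {
    paste0(g, "_", seq_len(cfg$n_samples_per_group))
  }))
}

# latent log-scale means in role order: hub on top, satellites mid,
# background taxa a geometric rank-abundance tail
sim_log_means <- function(cfg) {
  n_bg <- cfg$n_taxa - 1 - cfg$n_satellites
  c(
    log(12),
    rep(log(4), cfg$n_satellites),
    log(seq(6, 0.05, length.out = n_bg))
  )
}

#' Simulate a taxa-by-sample count table with a planted keystone hub
#'
#' Latent log abundances are multivariate normal: satellite taxa load on the
#' hub's latent factor at `hub_satellite_rho` (so satellite pairs correlate
#' at rho^2), all other taxa are independent. In the `keystone_vax` group
#' the hub's latent abundance is multiplied by `depletion_factor`, emulating
#' antibody-mediated depletion of the keystone. Fractions are closed
#' (divided by their sum) and counts drawn multinomially at `depth`.
#'
#' @param cfg A [sim_config()].
#' @return A [count_table()] whose metadata has `sample` and `group`.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  samples <- sim_samples(cfg)
  groups <- rep(cfg$groups, each = cfg$n_samples_per_group)
  n_s <- length(samples)
  mu <- sim_log_means(cfg) # role order: hub first
  counts <- with_seed(child_seed(cfg$seed, 1L), {
    z_hub <- rnorm(n_s)
    z <- matrix(rnorm(cfg$n_taxa * n_s), cfg$n_taxa, n_s)
    rho <- cfg$hub_satellite_rho
    z[1, ] <- z_hub
    if (cfg$n_satellites > 0) {
      sat <- 1 + seq_len(cfg$n_satellites)
      z[sat, ] <- rho * matrix(z_hub, cfg$n_satellites, n_s, byrow = TRUE) +
        sqrt(1 - rho^2) * z[sat, , drop = FALSE]
    }
    log_a <- mu + cfg$log_sd * z
    log_a[1, groups == "keystone_vax"] <-
      log_a[1, groups == "keystone_vax"] + log(cfg$depletion_factor)
    a <- exp(log_a)
    frac <- sweep(a, 2, colSums(a), "/")
    m <- vapply(
      seq_len(n_s),
      function(j) rmultinom(1, cfg$depth, frac[, j])[, 1],
      numeric(cfg$n_taxa)
    )
    # permute role order into final row positions (hub at hub_index)
    out <- matrix(0, cfg$n_taxa, n_s)
    out[sim_role_positions(cfg), ] <- m
    dimnames(out) <- list(sim_taxa(cfg), samples)
    out
  })
  count_table(counts, tibble(sample = samples, group = groups))
}

hub_fraction <- function(cfg, ct) {
  # pseudocount guards log/qPCR transforms when the hub drops out of a sample
  (ct$counts[cfg$hub_index, ] + 0.5) / (colSums(ct$counts) + 0.5)
}

#' Simulate antibody OD kinetics coupled to the realized hub abundance
#'
#' For the `mock` and `keystone_vax` groups the terminal OD is a strictly
#' decreasing function of the sample's realized hub relative abundance
#' (`od_max * exp(-10 * fraction)`), so antibody-exposed samples with a
#' depleted hub show high OD; with `od_noise_sd = 0` the pooled Spearman
#' correlation between OD and hub abundance is exactly -1. Groups without
#' hub-specific antibodies get baseline OD plus noise. ODs ramp from day 0
#' to day 30 and are clamped at 0.
#'
#' @param cfg A [sim_config()].
#' @param ct The [simulate_counts()] result for `cfg`.
#' @param days Sampling days. Default `c(0, 14, 30)`.
#' @return Tibble: `sample`, `group`, `day`, `isotype`, `od`.
#' @export
simulate_antibody <- function(cfg, ct, days = c(0, 14, 30)) {
  stopifnot(inherits(cfg, "sim_config"))
  p_hub <- hub_fraction(cfg, ct)
  grid <- tidyr::expand_grid(
    sample = ct$metadata$sample,
    day = days,
    isotype = c("IgM", "IgG")
  )
  grid <- dplyr::left_join(grid, ct$metadata[c("sample", "group")],
    by = "sample"
  )
  od_max <- c(IgM = 2.5, IgG = 3.0)
  coupled <- grid$group %in% c("mock", "keystone_vax")
  signal <- ifelse(
    coupled,
    od_max[grid$isotype] * exp(-10 * p_hub[grid$sample]),
    0
  )
  ramp <- grid$day / max(days)
  with_seed(child_seed(cfg$seed, 2L), {
    od <- 0.05 + ramp * signal + rnorm(nrow(grid), 0, cfg$od_noise_sd)
  })
  grid$od <- pmax(od, 0)
  grid[c("sample", "group", "day", "isotype", "od")]
}

#' Simulate a random coalescent phylogeny over the taxa
#'
#' @param cfg A [sim_config()].
#' @return A rooted [ape::phylo] tree with positive branch lengths whose tip
#'   set equals the taxon set.
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_taxa < 2) abort("need at least 2 tips for a tree")
  with_seed(
    child_seed(cfg$seed, 3L),
    ape::rcoal(cfg$n_taxa, tip.label = sim_taxa(cfg))
  )
}

#' Simulate gene content, pathway map and qPCR Ct values
#'
#' The hub carries two marker genes (`atoB`, `eutD`, copy number 1, no other
#' carrier) assigned to a single marker pathway `P163-PWY`; background genes
#' are scattered over the other taxa and grouped into generic pathways, each
#' gene belonging to exactly one pathway. Ct values are simulated so the
#' marker ddCt fold change tracks the realized hub abundance: the target Ct
#' is the housekeeping Ct minus log2 of the hub fraction (plus noise), hence
#' `2^-ddCt < 1` for the keystone-vaccinated group under depletion.
#'
#' @param cfg A [sim_config()].
#' @param ct The [simulate_counts()] result for `cfg`.
#' @return List with `gene_content` (taxa x genes matrix), `pathway_map`
#'   (tibble `gene`, `pathway`), `rrna_copies` (named vector, all 1) and
#'   `ct_table` (tibble `sample`, `group`, `gene`, `ct`; housekeeping gene
#'   `rsp4` present in every sample).
#' @export
simulate_gene_content <- function(cfg, ct) {
  stopifnot(inherits(cfg, "sim_config"))
  taxa <- rownames(ct$counts)
  markers <- c("atoB", "eutD")
  n_bg <- 8L
  bg <- paste0("KO_", seq_len(n_bg))
  genes <- c(markers, bg)
  gene_content <- matrix(0, length(taxa), length(genes),
    dimnames = list(taxa, genes)
  )
  gene_content[cfg$hub_index, markers] <- 1
  with_seed(child_seed(cfg$seed, 4L), {
    for (g in bg) {
      carriers <- sample(setdiff(seq_along(taxa), cfg$hub_index),
        size = max(2L, rbinom(1, length(taxa) - 1L, 0.3))
      )
      gene_content[carriers, g] <- sample(1:3, length(carriers),
        replace = TRUE
      )
    }
  })
  pathway_map <- tibble(
    gene = genes,
    pathway = c(
      rep("P163-PWY", length(markers)),
      paste0("PWY-", 1 + (seq_len(n_bg) - 1) %% 3)
    )
  )
  p_hub <- hub_fraction(cfg, ct)
  meta <- ct$metadata
  ct_long <- tidyr::expand_grid(
    sample = meta$sample,
    gene = c(markers, "rsp4")
  )
  ct_long <- dplyr::left_join(ct_long, meta[c("sample", "group")],
    by = "sample"
  )
  with_seed(child_seed(cfg$seed, 5L), {
    hk <- 20 + rnorm(nrow(meta), 0, cfg$ct_noise_sd)
    names(hk) <- meta$sample
    ct_long$ct <- ifelse(
      ct_long$gene == "rsp4",
      hk[ct_long$sample],
      hk[ct_long$sample] - log2(p_hub[ct_long$sample]) +
        rnorm(nrow(ct_long), 0, cfg$ct_noise_sd)
    )
  })
  list(
    gene_content = gene_content,
    pathway_map = pathway_map,
    rrna_copies = setNames(rep(1, length(taxa)), taxa),
    ct_table = ct_long[c("sample", "group", "gene", "ct")]
  )
}

#' Simulate a complete synthetic study bundle
#'
#' Runs all sub-generators under child seeds of the master seed.
#'
#' @param cfg A [sim_config()].
#' @return A `microbiome_sim` list: `config`, `counts` ([count_table()]),
#'   `tree`, `antibody`, `gene_content`, `pathway_map`, `rrna_copies`,
#'   `ct_table`.
#' @export
simulate_microbiome <- function(cfg = sim_config()) {
  counts <- simulate_counts(cfg)
  fg <- simulate_gene_content(cfg, counts)
  structure(
    c(
      list(
        config = cfg,
        counts = counts,
        tree = simulate_tree(cfg),
        antibody = simulate_antibody(cfg, counts)
      ),
      fg
    ),
    class = "microbiome_sim"
  )
}

#' @export
print.microbiome_sim <- function(x, ...) {
  cat(sprintf(
    "<microbiome_sim> %d taxa x %d samples, depth %g, hub '%s'\n",
    nrow(x$counts$counts), ncol(x$counts$counts), x$config$depth,
    rownames(x$counts$counts)[x$config$hub_index]
  ))
  invisible(x)
}

#' Write a synthetic bundle to plain-text files
#'
#' Writes counts + metadata TSV, Newick tree, gene content TSV, pathway map
#' TSV and Ct TSV into a directory.
#'
#' @param sim A [simulate_microbiome()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"),
    metadata_path = file.path(dir, "metadata.tsv")
  )
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(sim$antibody, file.path(dir, "antibody.tsv"))
  readr::write_tsv(
    as_tibble(sim$gene_content, rownames = "taxon"),
    file.path(dir, "gene_content.tsv")
  )
  readr::write_tsv(sim$pathway_map, file.path(dir, "pathway_map.tsv"))
  readr::write_tsv(sim$ct_table, file.path(dir, "ct.tsv"))
  invisible(dir)
}
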