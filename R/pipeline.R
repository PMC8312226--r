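#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage with their package
#' defaults. Either a synthetic scenario (`sim`) or paths to input files
#' (`counts_path`, optionally `metadata_path`, `tree_path`,
#' `gene_content_path`, `pathway_map_path`, `ct_path`) must be provided.
#'
#' @param sim A [sim_config()], or `NULL` to read inputs from files.
#' @param counts_path,metadata_path,tree_path,gene_content_path,pathway_map_path,ct_path
#'   Input file paths (TSV / Newick), used when `sim` is `NULL`.
#' @param seed Master seed for all stochastic stages.
#' @param n_inference_iter,n_exclusion_iter,exclusion_threshold SparCC
#'   parameters (see [sparcc()]).
#' @param n_perm_edges Permutations for edge pseudo-p-values.
#' @param r_min,alpha Network edge thresholds (see [build_network()]).
#' @param network_groups Samples used for network inference: a group label
#'   vector, or `NULL` for all samples.
#' @param attack_iterations Random-attack iterations.
#' @param rarefy_depth Rarefaction depth (`NULL` = minimum sample sum).
#' @param n_perm_permanova PERMANOVA permutations.
#' @param contrast Two groups for the differential-abundance stage.
#' @param n_mc_instances Dirichlet Monte-Carlo instances for the covariate
#'   correlation.
#' @param covariate_isotype,covariate_day Antibody measurement correlated
#'   with taxon abundances.
#' @param qpcr_target,qpcr_housekeeping,qpcr_control qPCR fold-change
#'   settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            counts_path = NULL, metadata_path = NULL,
                            tree_path = NULL, gene_content_path = NULL,
                            pathway_map_path = NULL, ct_path = NULL,
                            seed = 1,
                            n_inference_iter = 20, n_exclusion_iter = 10,
                            exclusion_threshold = 0.1,
                            n_perm_edges = 100,
                            r_min = 0.3, alpha = 0.05,
                            network_groups = NULL,
                            attack_iterations = 100,
                            rarefy_depth = NULL,
                            n_perm_permanova = 999,
                            contrast = c("mock", "keystone_vax"),
                            n_mc_instances = 128,
                            covariate_isotype = "IgG",
                            covariate_day = 30,
                            qpcr_target = "atoB",
                            qpcr_housekeeping = "rsp4",
                            qpcr_control = "mock") {
  cfg <- as.list(environment())
  if (is.null(sim) && is.null(counts_path)) {
    abort("either a sim_config or a counts_path is required")
  }
  if (!is.null(counts_path)) {
    paths <- c(
      counts_path, metadata_path, tree_path, gene_content_path,
      pathway_map_path, ct_path
    )
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing) > 0) {
      abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or load) -> SparCC network -> topology /
#' keystones / attack tolerance -> rarefied diversity + PERMANOVA ->
#' NB Wald differential abundance -> covariate (antibody) correlation ->
#' functional prediction -> qPCR fold changes. All result tables are
#' written as TSV under `outdir` together with a JSON manifest recording
#' parameters and seeds; a rerun with the same config and seed reproduces
#' the outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$sim)) {
      sim <- simulate_microbiome(config$sim)
      write_bundle(sim, file.path(outdir, "inputs"))
      sim
    } else {
      list(
        counts = read_counts(config$counts_path,
          metadata = config$metadata_path
        ),
        tree = if (!is.null(config$tree_path)) {
          read_newick(config$tree_path)
        },
        gene_content = if (!is.null(config$gene_content_path)) {
          df <- readr::read_tsv(config$gene_content_path,
            comment = "#", show_col_types = FALSE, progress = FALSE
          )
          m <- as.matrix(df[-1])
          rownames(m) <- df[[1]]
          m
        },
        pathway_map = if (!is.null(config$pathway_map_path)) {
          readr::read_tsv(config$pathway_map_path,
            comment = "#", show_col_types = FALSE, progress = FALSE
          )
        },
        ct_table = if (!is.null(config$ct_path)) {
          readr::read_tsv(config$ct_path,
            comment = "#", show_col_types = FALSE, progress = FALSE
          )
        },
        antibody = NULL,
        rrna_copies = NULL
      )
    }
  })
  counts <- inputs$counts

  net_counts <- if (!is.null(config$network_groups)) {
    subset_samples(
      counts, counts$metadata$group %in% config$network_groups
    )
  } else {
    counts
  }
  fit <- stage("network", {
    f <- sparcc(net_counts,
      n_inference_iter = config$n_inference_iter,
      n_exclusion_iter = config$n_exclusion_iter,
      exclusion_threshold = config$exclusion_threshold,
      seed = child_seed(config$seed, 11L)
    )
    sparcc_pvalues(f,
      n_perm = config$n_perm_edges,
      seed = child_seed(config$seed, 12L)
    )
  })
  net <- build_network(fit, net_counts,
    r_min = config$r_min,
    alpha = config$alpha
  )
  write_matrix_tsv(fit$rho, file.path(outdir, "correlations.tsv"),
    "SparCC basis correlations"
  )
  write_matrix_tsv(fit$pvals, file.path(outdir, "pvalues.tsv"),
    "permutation pseudo-p-values"
  )
  write_edge_list(net, file.path(outdir, "edges.tsv"))
  write_network_gexf(net, file.path(outdir, "network.gexf"))

  topo <- stage("topology", summarize_topology(net))
  readr::write_tsv(topo, file.path(outdir, "topology.tsv"))
  keys <- stage("keystones", keystoneness(net, net_counts))
  readr::write_tsv(keys, file.path(outdir, "keystones.tsv"))
  atk <- stage("attack", {
    attack_tolerance(net,
      n_iterations = config$attack_iterations,
      seed = child_seed(config$seed, 13L)
    )
  })
  readr::write_tsv(atk$curves, file.path(outdir, "attack_curves.tsv"))
  readr::write_tsv(atk$fractions, file.path(outdir, "attack_fractions.tsv"))

  div <- stage("diversity", {
    rar <- rarefy(counts,
      depth = config$rarefy_depth,
      seed = child_seed(config$seed, 14L)
    )
    alpha_div <- alpha_diversity(rar)
    if (!is.null(inputs$tree)) {
      alpha_div <- dplyr::left_join(
        alpha_div, faith_pd(rar, inputs$tree)[c("sample", "faith_pd")],
        by = "sample"
      )
    }
    bc <- bray_curtis(rar)
    perm <- permanova(bc, rar$metadata$group,
      n_perm = config$n_perm_permanova,
      seed = child_seed(config$seed, 15L)
    )
    tests <- list(permanova = as.list(perm))
    for (metric in intersect(
      c("shannon", "pielou", "faith_pd"),
      names(alpha_div)
    )) {
      tests[[paste0("kruskal_", metric)]] <-
        as.list(kruskal_wallis(alpha_div[[metric]], alpha_div$group))
    }
    list(alpha = alpha_div, bray_curtis = bc, tests = tests)
  })
  readr::write_tsv(div$alpha, file.path(outdir, "alpha_diversity.tsv"))
  write_matrix_tsv(
    div$bray_curtis, file.path(outdir, "bray_curtis.tsv"),
    "Bray-Curtis dissimilarities"
  )
  jsonlite::write_json(div$tests, file.path(outdir, "diversity_tests.json"),
    auto_unbox = TRUE, digits = NA
  )

  da <- stage(
    "diffab",
    volcano_table(wald_lfc_test(counts, contrast = config$contrast))
  )
  readr::write_tsv(da, file.path(outdir, "differential_abundance.tsv"))

  ab <- NULL
  if (!is.null(inputs$antibody)) {
    ab <- stage("abcorr", {
      od <- inputs$antibody
      od <- od[od$isotype == config$covariate_isotype &
        od$day == config$covariate_day &
        od$group %in% config$contrast, ]
      sub <- subset_samples(counts, od$sample)
      abundance_correlation(sub, od$od[match(
        colnames(sub$counts),
        od$sample
      )],
      n_instances = config$n_mc_instances,
      seed = child_seed(config$seed, 16L)
      )
    })
    readr::write_tsv(ab, file.path(outdir, "antibody_correlation.tsv"))
  }

  func <- NULL
  if (!is.null(inputs$gene_content)) {
    func <- stage("function", {
      genes <- predict_metagenome(counts, inputs$gene_content,
        rrna_copies = inputs$rrna_copies
      )
      pw <- pathway_abundance(genes, inputs$pathway_map)
      pw_da <- volcano_table(
        wald_lfc_test(round(t(pw)),
          groups = counts$metadata$group,
          contrast = config$contrast
        )
      )
      list(genes = genes, pathways = pw, pathway_diffab = pw_da)
    })
    readr::write_tsv(
      as_tibble(func$genes, rownames = "sample"),
      file.path(outdir, "predicted_genes.tsv")
    )
    readr::write_tsv(
      as_tibble(func$pathways, rownames = "sample"),
      file.path(outdir, "predicted_pathways.tsv")
    )
    readr::write_tsv(
      func$pathway_diffab,
      file.path(outdir, "pathway_differential_abundance.tsv")
    )
  }

  qpcr <- NULL
  if (!is.null(inputs$ct_table)) {
    qpcr <- stage("qpcr", {
      ddct_fold_change(inputs$ct_table,
        target = config$qpcr_target,
        housekeeping = config$qpcr_housekeeping,
        control_group = config$qpcr_control
      )
    })
    readr::write_tsv(
      qpcr$per_sample,
      file.path(outdir, "qpcr_fold_changes.tsv")
    )
  }

  manifest <- list(
    package = "micronet",
    version = as.character(utils::packageVersion("micronet")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "sim")],
    sim = if (!is.null(config$sim)) unclass(config$sim)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(list(
    inputs = inputs, fit = fit, network = net, topology = topo,
    keystones = keys, attack = atk, diversity = div,
    differential_abundance = da, antibody_correlation = ab,
    functional = func, qpcr = qpcr
  ))
}
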