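#' Predict sample-level gene-family abundances from taxon abundances
#'
#' The deterministic copy-number step of 16S-based metagenome prediction:
#' per sample, taxon abundances are divided by the taxon's 16S rRNA copy
#' number and multiplied through the taxon-by-gene copy-number table.
#' Phylogenetic placement and hidden-state prediction are upstream of this
#' package; users of real placement outputs can drop high-uncertainty taxa
#' via `exclude_taxa` (e.g. an NSTI-based exclusion list).
#'
#' @param ct A [count_table()] or count matrix.
#' @param gene_content Taxon-by-gene non-negative copy-number matrix
#'   covering every taxon of `ct`.
#' @param rrna_copies Named per-taxon 16S copy numbers (>= 1); default 1
#'   for every taxon.
#' @param exclude_taxa Optional taxa to drop before prediction.
#' @return Sample-by-gene matrix of predicted abundances.
#' @export
predict_metagenome <- function(ct, gene_content, rrna_copies = NULL,
                               exclude_taxa = NULL) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (!is.null(exclude_taxa)) {
    m <- m[setdiff(rownames(m), exclude_taxa), , drop = FALSE]
  }
  missing <- setdiff(rownames(m), rownames(gene_content))
  if (length(missing) > 0) {
    abort(paste0(
      "taxa missing from gene_content: ", paste(missing, collapse = ", ")
    ))
  }
  gc <- as.matrix(gene_content)[rownames(m), , drop = FALSE]
  if (any(gc < 0)) abort("gene_content must be non-negative")
  if (is.null(rrna_copies)) {
    rrna_copies <- setNames(rep(1, nrow(m)), rownames(m))
  }
  if (!all(rownames(m) %in% names(rrna_copies))) {
    abort("rrna_copies must cover every taxon")
  }
  rr <- rrna_copies[rownames(m)]
  if (any(rr < 1)) abort("rrna_copies must be >= 1")
  t(m / rr) %*% gc
}

#' Aggregate predicted gene abundances into pathway abundances
#'
#' @param predicted_genes Sample-by-gene matrix from
#'   [predict_metagenome()].
#' @param pathway_map Data frame with columns `gene`, `pathway`; every
#'   mapped gene must exist in `predicted_genes` and every pathway must
#'   have at least one member.
#' @param aggregator `"mean"` (default) or `"sum"` over member genes.
#' @return Sample-by-pathway matrix.
#' @export
pathway_abundance <- function(predicted_genes, pathway_map,
                              aggregator = c("mean", "sum")) {
  aggregator <- match.arg(aggregator)
  pathway_map <- as_tibble(pathway_map)
  if (!all(c("gene", "pathway") %in% names(pathway_map))) {
    abort("pathway_map needs columns gene and pathway")
  }
  missing <- setdiff(pathway_map$gene, colnames(predicted_genes))
  if (length(missing) > 0) {
    abort(paste0(
      "mapped gene(s) absent from prediction: ",
      paste(missing, collapse = ", ")
    ))
  }
  pws <- unique(pathway_map$pathway)
  out <- vapply(pws, function(pw) {
    genes <- pathway_map$gene[pathway_map$pathway == pw]
    if (length(genes) == 0) abort(paste0("empty pathway: ", pw))
    sub <- predicted_genes[, genes, drop = FALSE]
    if (aggregator == "mean") rowMeans(sub) else rowSums(sub)
  }, numeric(nrow(predicted_genes)))
  rownames(out) <- rownames(predicted_genes)
  out
}

#' qPCR relative quantification by the 2^-ddCt method
#'
#' Per sample: `dCt = Ct_target - Ct_housekeeping`; `ddCt = dCt -
#' mean(dCt of the control group)`; fold change `2^-ddCt`. The control
#' group's fold changes have geometric mean 1 by construction.
#'
#' @param ct_table Data frame with columns `sample`, `group`, `gene`, `ct`;
#'   the housekeeping gene must be measured in every sample.
#' @param target Target gene name.
#' @param housekeeping Housekeeping gene name.
#' @param control_group Group whose mean dCt is the baseline.
#' @return List with `per_sample` (tibble: `sample`, `group`, `dct`,
#'   `ddct`, `fold_change`) and `group_means` (tibble: `group`,
#'   `mean_fold_change`, `n`).
#' @export
ddct_fold_change <- function(ct_table, target, housekeeping,
                             control_group) {
  ctt <- as_tibble(ct_table)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(ctt))) {
    abort("ct_table needs columns sample, group, gene, ct")
  }
  if (!control_group %in% ctt$group) abort("control group absent")
  tg <- ctt[ctt$gene == target, ]
  hk <- ctt[ctt$gene == housekeeping, ]
  if (nrow(tg) == 0) abort(paste0("no Ct values for target ", target))
  if (!all(tg$sample %in% hk$sample)) {
    abort("housekeeping Ct missing for some samples")
  }
  if (any(!is.finite(tg$ct)) || any(!is.finite(hk$ct))) {
    abort("Ct values must be finite")
  }
  per <- dplyr::mutate(
    tg,
    dct = .data$ct - hk$ct[match(.data$sample, hk$sample)]
  )
  baseline <- mean(per$dct[per$group == control_group])
  per <- dplyr::mutate(
    per,
    ddct = .data$dct - baseline,
    fold_change = 2^-.data$ddct
  )
  list(
    per_sample = per[c("sample", "group", "dct", "ddct", "fold_change")],
    group_means = dplyr::summarise(
      dplyr::group_by(per, .data$group),
      mean_fold_change = mean(.data$fold_change),
      n = dplyr::n(),
      .groups = "drop"
    )
  )
}
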