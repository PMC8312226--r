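#' Rarefy a count table to even depth
#'
#' Subsamples each sample without replacement to exactly `depth` reads.
#' Samples with fewer than `depth` reads are dropped with a warning.
#'
#' @param ct A [count_table()].
#' @param depth Target depth; default the minimum sample sum.
#' @param seed Seed for the subsampling draw (single draw, not averaged).
#' @return A rarefied [count_table()].
#' @export
rarefy <- function(ct, depth = NULL, seed = 1) {
  stopifnot(inherits(ct, "count_table"))
  tot <- colSums(ct$counts)
  depth <- depth %||% min(tot)
  if (depth <= 0) abort("depth must be positive")
  keep <- tot >= depth
  if (!all(keep)) {
    warn(paste0(
      "dropping sample(s) below depth ", depth, ": ",
      paste(colnames(ct$counts)[!keep], collapse = ", ")
    ))
  }
  m <- ct$counts[, keep, drop = FALSE]
  # vegan warns when the smallest positive count exceeds 1 (it suspects
  # scaled data); our inputs are genuine counts, so silence that heuristic
  rar <- with_seed(seed, t(suppressWarnings(vegan::rrarefy(t(m), depth))))
  count_table(rar, ct$metadata[keep, ])
}

#' Faith's phylogenetic diversity
#'
#' Per sample, the total branch length of the minimal rooted subtree
#' spanning the observed taxa (root connection included). Unrooted trees
#' are midpoint-rooted with a warning.
#'
#' @param ct A [count_table()].
#' @param tree An [ape::phylo] tree whose tips cover the table's taxa.
#' @return Tibble: `sample`, `faith_pd`, `richness`.
#' @export
faith_pd <- function(ct, tree) {
  stopifnot(inherits(ct, "count_table"))
  missing <- setdiff(rownames(ct$counts), tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0(
      "taxa missing from tree: ", paste(missing, collapse = ", ")
    ))
  }
  if (!ape::is.rooted(tree)) {
    warn("tree is unrooted; midpoint-rooting")
    tree <- phangorn::midpoint(tree)
  }
  comm <- t(ct$counts) # samples x taxa, as picante expects
  res <- picante::pd(comm, tree, include.root = TRUE)
  tibble(
    sample = rownames(res),
    faith_pd = res$PD,
    richness = res$SR
  )
}

#' Shannon diversity and Pielou evenness
#'
#' Natural-log Shannon entropy over nonzero counts; Pielou's
#' `J = H / ln(S_obs)` with observed richness. `J` is undefined (NA, with
#' `degenerate = TRUE`) for single-taxon samples; both indices are
#' invariant to rescaling counts.
#'
#' @param ct A [count_table()].
#' @return Tibble: `sample`, `richness`, `shannon`, `pielou`, `degenerate`.
#' @export
alpha_diversity <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  m <- ct$counts
  out <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[x > 0]
    if (length(x) == 0) abort(paste0("empty sample: ", colnames(m)[j]))
    p <- x / sum(x)
    h <- -sum(p * log(p))
    s <- length(x)
    tibble(
      sample = colnames(m)[j],
      richness = s,
      shannon = h,
      pielou = if (s > 1) h / log(s) else NA_real_,
      degenerate = s == 1
    )
  })
  dplyr::left_join(out, ct$metadata, by = "sample")
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = 1 - 2 sum(min(u, v)) / (sum(u) + sum(v))` over all sample
#' pairs.
#'
#' @param ct A [count_table()].
#' @return Symmetric sample-by-sample matrix with zero diagonal.
#' @export
bray_curtis <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  if (any(colSums(ct$counts) == 0)) abort("empty sample in count table")
  as.matrix(vegan::vegdist(t(ct$counts), method = "bray"))
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance: pseudo-F from
#' among/within sums of squared dissimilarities, p-value by free label
#' permutation with the `(1 + more extreme) / (1 + n_perm)` convention.
#'
#' @param dist_matrix Symmetric dissimilarity matrix (or `dist`).
#' @param labels Group labels, one per sample; >= 2 groups with >= 2
#'   samples each.
#' @param n_perm Number of permutations. Default 999.
#' @param seed Permutation seed.
#' @return Tibble: `pseudo_f`, `r2`, `df_between`, `df_within`, `p`,
#'   `n_perm`.
#' @export
permanova <- function(dist_matrix, labels, n_perm = 999, seed = 1) {
  d <- stats::as.dist(dist_matrix)
  labels <- as.factor(labels)
  if (length(labels) != attr(d, "Size")) {
    abort("labels must match the dissimilarity matrix size")
  }
  if (nlevels(droplevels(labels)) < 2 || any(table(labels) < 2)) {
    abort("need >= 2 groups with >= 2 samples each")
  }
  fit <- with_seed(seed, {
    vegan::adonis2(d ~ g,
      data = data.frame(g = labels),
      permutations = n_perm
    )
  })
  tibble(
    pseudo_f = fit$F[1],
    r2 = fit$R2[1],
    df_between = fit$Df[1],
    df_within = fit$Df[2],
    p = fit$`Pr(>F)`[1],
    n_perm = n_perm
  )
}

#' Kruskal-Wallis and Mann-Whitney group comparisons
#'
#' Tidy wrappers over the tie-corrected rank tests used for alpha-diversity
#' and fold-change group comparisons. Degenerate inputs (all values equal)
#' are flagged rather than raising.
#'
#' @param values Numeric vector.
#' @param labels Group labels (>= 2 groups).
#' @return Tibble with `statistic`, `df`, `p`, `degenerate`.
#' @export
kruskal_wallis <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) abort("need >= 2 groups")
  if (length(unique(values)) == 1) {
    return(tibble(
      statistic = 0, df = nlevels(droplevels(labels)) - 1,
      p = 1, degenerate = TRUE
    ))
  }
  k <- kruskal.test(values, labels)
  tibble(
    statistic = unname(k$statistic),
    df = unname(k$parameter),
    p = k$p.value,
    degenerate = FALSE
  )
}

#' @rdname kruskal_wallis
#' @param a,b Numeric vectors for the two-sample comparison; the reported
#'   `statistic` is the Mann-Whitney U of `a`.
#' @param exact Use the exact null distribution (default: small samples
#'   without ties, as [stats::wilcox.test()] decides).
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) abort("empty group")
  if (length(unique(c(a, b))) == 1) {
    return(tibble(
      statistic = length(a) * length(b) / 2, p = 1,
      degenerate = TRUE
    ))
  }
  w <- suppressWarnings(wilcox.test(a, b, exact = exact))
  tibble(
    statistic = unname(w$statistic),
    p = w$p.value,
    degenerate = FALSE
  )
}

#' Principal-coordinates (PCoA) ordination of a dissimilarity matrix
#'
#' @param dist_matrix Symmetric dissimilarity matrix (or `dist`).
#' @param k Number of axes. Default 2.
#' @return Tibble: `sample`, `axis_1` ... `axis_k`.
#' @export
pcoa_coordinates <- function(dist_matrix, k = 2) {
  d <- stats::as.dist(dist_matrix)
  co <- stats::cmdscale(d, k = k)
  out <- as_tibble(co, .name_repair = ~ paste0("axis_", seq_len(k)))
  dplyr::mutate(out, sample = labels(d), .before = 1)
}
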