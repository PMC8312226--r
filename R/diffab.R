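#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: each sample's median ratio to the
#' per-feature geometric-mean reference, computed over features positive in
#' every sample. Zero-heavy tables with no all-positive feature fall back
#' to geometric means over positive counts only. Factors are rescaled to
#' geometric mean 1.
#'
#' @param ct A [count_table()] or count matrix.
#' @return Named positive vector, one per sample, geometric mean 1.
#' @export
size_factors <- function(ct) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (any(colSums(m) == 0)) abort("sample with all-zero counts")
  all_pos <- rowSums(m == 0) == 0
  if (any(all_pos)) {
    ref <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
    sf <- apply(m[all_pos, , drop = FALSE], 2, function(x) median(x / ref))
  } else {
    # zero-heavy fallback: per-feature geometric mean over positive counts
    lg <- log(m)
    lg[!is.finite(lg)] <- NA
    ref <- exp(rowMeans(lg, na.rm = TRUE))
    use <- is.finite(ref) & ref > 0
    sf <- apply(m[use, , drop = FALSE], 2, function(x) {
      r <- x[x > 0] / ref[use][x > 0]
      if (length(r) == 0) abort("sample shares no positive feature with reference")
      median(r)
    })
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

#' Negative-binomial Wald test of log2 fold changes between two groups
#'
#' For each feature, counts are normalised by [size_factors()], a
#' per-feature NB dispersion is estimated by the method of moments
#' (`alpha = max((s^2 - mu)/mu^2, 1e-8)` on normalised counts, averaged over
#' the two groups), and the log2 fold change of group means (each offset by
#' a 0.5 pseudocount against zeros) is tested with a Wald z statistic whose
#' standard error comes from the NB variance of the group means via the
#' delta method. P-values are Benjamini-Hochberg adjusted across features.
#' Features with zero counts everywhere in both groups are excluded and
#' reported.
#'
#' @param ct A [count_table()] with group metadata, or a count matrix.
#' @param groups Group label per sample (taken from metadata column `group`
#'   when `ct` is a `count_table` and `groups` is `NULL`).
#' @param contrast Length-2 character vector `c(reference, treatment)`; the
#'   LFC is `log2(treatment / reference)`.
#' @return A `diffab_result` tibble: `feature`, `base_mean`, `lfc`, `se`,
#'   `wald_z`, `p`, `padj`, plus an `excluded` attribute naming all-zero
#'   features.
#' @export
wald_lfc_test <- function(ct, groups = NULL, contrast) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (is.null(groups) && inherits(ct, "count_table")) {
    groups <- ct$metadata$group
  }
  if (is.null(groups)) abort("group labels required")
  if (length(contrast) != 2) abort("contrast must name exactly 2 groups")
  if (!all(contrast %in% groups)) abort("contrast groups absent from labels")
  sel <- groups %in% contrast
  m <- m[, sel, drop = FALSE]
  grp <- groups[sel]
  if (any(table(grp) < 2)) abort("need >= 2 samples per group")
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  ref <- norm[, grp == contrast[1], drop = FALSE]
  trt <- norm[, grp == contrast[2], drop = FALSE]
  nonzero <- rowSums(m) > 0
  excluded <- rownames(m)[!nonzero]
  stats_one <- function(i) {
    x1 <- ref[i, ]
    x2 <- trt[i, ]
    mu1 <- mean(x1)
    mu2 <- mean(x2)
    disp_g <- function(x) {
      mu <- mean(x)
      if (mu <= 0) {
        return(NA_real_)
      }
      (var(x) - mu) / mu^2
    }
    alpha <- mean(c(disp_g(x1), disp_g(x2)), na.rm = TRUE)
    alpha <- max(alpha, 1e-8, na.rm = TRUE)
    lfc <- log2((mu2 + 0.5) / (mu1 + 0.5))
    v1 <- (mu1 + alpha * mu1^2) / length(x1)
    v2 <- (mu2 + alpha * mu2^2) / length(x2)
    se <- sqrt(v1 / (mu1 + 0.5)^2 + v2 / (mu2 + 0.5)^2) / log(2)
    se <- max(se, 1e-12)
    c(
      base_mean = mean(c(x1, x2)), lfc = lfc, se = se,
      wald_z = lfc / se
    )
  }
  res <- t(vapply(which(nonzero), stats_one, numeric(4)))
  p <- unname(2 * pnorm(-abs(res[, "wald_z"])))
  out <- tibble(
    feature = rownames(m)[nonzero],
    base_mean = unname(res[, "base_mean"]),
    lfc = unname(res[, "lfc"]),
    se = unname(res[, "se"]),
    wald_z = unname(res[, "wald_z"]),
    p = p,
    padj = p.adjust(p, method = "BH")
  )
  attr(out, "excluded") <- excluded
  attr(out, "contrast") <- contrast
  class(out) <- c("diffab_result", class(out))
  out
}

#' Centered log-ratio transform
#'
#' Per sample: `log(x + pseudocount)` centered by its mean, so each
#' sample's clr values sum to 0 and the transform is invariant to scaling
#' the sample's counts.
#'
#' @param ct A [count_table()] or count matrix.
#' @param pseudocount Added to every count before the log. Default 0.5.
#' @return Matrix of clr values (taxa x samples).
#' @export
clr_transform <- function(ct, pseudocount = 0.5) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  l <- log(m + pseudocount)
  sweep(l, 2, colMeans(l), "-")
}

#' Flag features for a volcano-style report
#'
#' Features with `|LFC| >= lfc_cutoff` and BH-adjusted `p < alpha` are
#' flagged `"increased"` or `"decreased"`; everything else
#' `"not significant"`.
#'
#' @param result A [wald_lfc_test()] result (any tibble with `lfc` and
#'   `padj`).
#' @param lfc_cutoff Absolute LFC cutoff. Default 1.
#' @param alpha Adjusted-p threshold. Default 0.05.
#' @return The input with a `flag` column.
#' @export
volcano_table <- function(result, lfc_cutoff = 1, alpha = 0.05) {
  if (nrow(result) == 0) {
    return(dplyr::mutate(result, flag = character(0)))
  }
  dplyr::mutate(
    result,
    flag = dplyr::case_when(
      abs(.data$lfc) >= lfc_cutoff & .data$padj < alpha & .data$lfc < 0 ~
        "decreased",
      abs(.data$lfc) >= lfc_cutoff & .data$padj < alpha ~ "increased",
      TRUE ~ "not significant"
    )
  )
}

#' Volcano plot of a differential-abundance result
#'
#' @param object A [wald_lfc_test()] result.
#' @param lfc_cutoff,alpha Passed to [volcano_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diffab_result <- function(object, lfc_cutoff = 1, alpha = 0.05,
                                   ...) {
  df <- volcano_table(object, lfc_cutoff, alpha)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$lfc, y = -log10(.data$padj),
      colour = .data$flag
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(
      xintercept = c(-lfc_cutoff, lfc_cutoff),
      linetype = "dashed"
    ) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      decreased = "#B2182B", increased = "#2166AC",
      `not significant` = "grey60"
    )) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 adjusted p",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
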