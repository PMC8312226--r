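#' Dirichlet Monte-Carlo clr instances
#'
#' Each instance draws, per sample, a composition from
#' `Dirichlet(counts + 0.5)` and applies the centered log-ratio transform;
#' technical (sampling) uncertainty in the composition is propagated by
#' averaging downstream statistics over instances.
#'
#' @param ct A [count_table()] or count matrix.
#' @param n_instances Number of Monte-Carlo instances (>= 2). Default 128.
#' @param seed Seed controlling all draws.
#' @return 3-d array, taxa x samples x instances, of clr values.
#' @export
mc_instances <- function(ct, n_instances = 128, seed = 1) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (n_instances < 2) abort("n_instances must be >= 2")
  out <- array(
    NA_real_, c(nrow(m), ncol(m), n_instances),
    dimnames = list(rownames(m), colnames(m), NULL)
  )
  with_seed(seed, {
    for (k in seq_len(n_instances)) {
      g <- matrix(
        stats::rgamma(length(m), shape = m + 0.5, rate = 1),
        nrow(m), ncol(m)
      )
      f <- sweep(g, 2, colSums(g), "/")
      l <- log(f)
      out[, , k] <- sweep(l, 2, colMeans(l), "-")
    }
  })
  out
}

spearman_by_row <- function(x, y) {
  # x: taxa x samples; returns r and asymptotic two-sided p per row
  n <- ncol(x)
  rx <- t(apply(x, 1, rank))
  ry <- rank(y)
  r <- as.vector(cor(t(rx), ry))
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = pmin(p, 1))
}

#' Expected clr Spearman correlation of taxa with a covariate
#'
#' Per Monte-Carlo instance, each taxon's clr values are Spearman-correlated
#' with the covariate (antibody OD, engorgement weight, ...); within each
#' instance p-values are Benjamini-Hochberg adjusted across taxa, and the
#' reported values are expectations (means) over instances.
#'
#' @param instances An [mc_instances()] array, or a [count_table()] /
#'   count matrix from which instances are generated.
#' @param covariate Numeric vector, one finite value per sample.
#' @param n_instances,seed Used when `instances` is a count table/matrix.
#' @return Tibble: `taxon`, `expected_rs`, `expected_p`, `expected_padj`,
#'   `n_instances`.
#' @export
abundance_correlation <- function(instances, covariate, n_instances = 128,
                                  seed = 1) {
  if (!is.array(instances) || length(dim(instances)) != 3) {
    instances <- mc_instances(instances, n_instances = n_instances,
      seed = seed
    )
  }
  d <- dim(instances)
  if (length(covariate) != d[2]) {
    abort("covariate length must equal the number of samples")
  }
  if (any(!is.finite(covariate))) abort("covariate must be finite")
  if (length(unique(covariate)) == 1) {
    abort("constant covariate: correlation undefined")
  }
  acc_r <- acc_p <- acc_padj <- numeric(d[1])
  for (k in seq_len(d[3])) {
    sp <- spearman_by_row(instances[, , k], covariate)
    acc_r <- acc_r + sp$r
    acc_p <- acc_p + sp$p
    acc_padj <- acc_padj + p.adjust(sp$p, method = "BH")
  }
  tibble(
    taxon = dimnames(instances)[[1]],
    expected_rs = acc_r / d[3],
    expected_p = acc_p / d[3],
    expected_padj = acc_padj / d[3],
    n_instances = d[3]
  )
}
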