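#' Convert counts to compositional fractions
#'
#' @param ct A [count_table()] or a taxa-by-sample count matrix.
#' @param method `"pseudocount"` returns the deterministic
#'   `(counts + 0.5) / colsum`; `"dirichlet_draw"` samples each sample's
#'   fraction vector from `Dirichlet(counts + 1)`, the resampling scheme the
#'   basis-correlation estimator averages over.
#' @param seed Seed for the Dirichlet draw (ignored for `"pseudocount"`).
#' @return Matrix of strictly positive fractions; columns sum to 1.
#' @export
to_fractions <- function(ct, method = c("pseudocount", "dirichlet_draw"),
                         seed = NULL) {
  method <- match.arg(method)
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0(
      "all-zero sample(s): ",
      paste(colnames(m)[tot == 0], collapse = ", ")
    ))
  }
  if (method == "pseudocount") {
    f <- m + 0.5
    return(sweep(f, 2, colSums(f), "/"))
  }
  draw <- function() {
    g <- matrix(
      stats::rgamma(length(m), shape = m + 1, rate = 1),
      nrow(m), ncol(m), dimnames = dimnames(m)
    )
    sweep(g, 2, colSums(g), "/")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Pairwise log-ratio variances
#'
#' `t[i, j] = Var over samples of log(x_i / x_j)`, the compositionally
#' invariant dispersion the basis decomposition starts from.
#'
#' @param fractions Strictly positive taxa-by-sample fraction matrix.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
log_ratio_variance <- function(fractions) {
  if (ncol(fractions) < 2) abort("need at least 2 samples")
  if (any(fractions <= 0)) abort("fractions must be strictly positive")
  l <- log(fractions)
  cv <- cov(t(l)) # taxon x taxon covariance of log fractions
  v <- diag(cv)
  t_mat <- outer(v, v, "+") - 2 * cv
  t_mat[t_mat < 0] <- 0 # numerical negatives
  diag(t_mat) <- 0
  dimnames(t_mat) <- list(rownames(fractions), rownames(fractions))
  t_mat
}

#' Basis variances and correlations from log-ratio variances
#'
#' Solves the sparsity approximation for the basis variances omega: with
#' `t[i,j] ~ omega_i + omega_j - 2*rho_ij*sqrt(omega_i omega_j)` and most
#' rho near 0, row sums of `t` give the linear system
#' `((D-2) I + J) omega = rowSums(t)`; correlations follow as
#' `rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))`,
#' clamped to `[-1, 1]`. Pairs flagged in `excluded` (a logical matrix) are
#' left out of the row sums and the system, implementing the
#' strong-correlation exclusion rounds of [sparcc()].
#'
#' @param t_mat Symmetric log-ratio variance matrix (>= 4 taxa).
#' @param excluded Optional logical matrix marking excluded pairs.
#' @return List with `omega` (named vector) and `rho` (matrix, unit
#'   diagonal). Non-positive omega solutions are clamped to the smallest
#'   positive estimate with a warning.
#' @export
basis_correlation <- function(t_mat, excluded = NULL) {
  d <- nrow(t_mat)
  if (d < 4) abort("basis estimation needs at least 4 taxa")
  include <- matrix(TRUE, d, d)
  diag(include) <- FALSE
  if (!is.null(excluded)) include <- include & !excluded
  # M omega = rowSums over included pairs; M[i,i] = n_included(i),
  # M[i,j] = 1 for included pairs (reduces to (D-2)I + J with none excluded)
  m_mat <- matrix(0, d, d)
  m_mat[include] <- 1
  diag(m_mat) <- rowSums(include)
  t_sum <- rowSums(t_mat * include)
  omega <- tryCatch(solve(m_mat, t_sum), error = function(e) {
    abort("basis variance system is singular; too many excluded pairs")
  })
  if (any(omega <= 0)) {
    pos <- omega[omega > 0]
    if (length(pos) == 0) abort("all basis variances non-positive")
    warn(sprintf(
      "%d non-positive basis variance(s) clamped to %.3g",
      sum(omega <= 0), min(pos)
    ))
    omega[omega <= 0] <- min(pos)
  }
  denom <- 2 * sqrt(outer(omega, omega))
  rho <- (outer(omega, omega, "+") - t_mat) / denom
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  dimnames(rho) <- dimnames(t_mat)
  list(omega = setNames(omega, rownames(t_mat)), rho = rho)
}

# one exclusion round: flag the most strongly correlated off-diagonal pair
# above the threshold; ties broken by lexicographically smallest taxon pair
strongest_pair <- function(rho, excluded, threshold) {
  a <- abs(rho)
  diag(a) <- 0
  a[excluded] <- 0
  mx <- max(a)
  if (mx <= threshold) {
    return(NULL)
  }
  hits <- which(a == mx, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  taxa <- rownames(rho)
  keys <- paste(
    pmin(taxa[hits[, 1]], taxa[hits[, 2]]),
    pmax(taxa[hits[, 1]], taxa[hits[, 2]])
  )
  hits[order(keys)[1], ]
}

sparcc_single <- function(fractions, n_exclusion_iter, exclusion_threshold) {
  t_mat <- log_ratio_variance(fractions)
  d <- nrow(t_mat)
  excluded <- matrix(FALSE, d, d)
  bc <- basis_correlation(t_mat, excluded)
  pairs <- list()
  iter <- 0
  while (iter < n_exclusion_iter) {
    hit <- strongest_pair(bc$rho, excluded, exclusion_threshold)
    if (is.null(hit)) break
    # dropping a taxon's last informative pairs makes the solve singular;
    # stop excluding once any taxon would fall below 3 partners
    tmp <- excluded
    tmp[hit[1], hit[2]] <- tmp[hit[2], hit[1]] <- TRUE
    if (min(rowSums(!tmp) - 1) < 3) break
    excluded <- tmp
    pairs[[length(pairs) + 1]] <- sort(rownames(t_mat)[hit])
    bc <- basis_correlation(t_mat, excluded)
    iter <- iter + 1
  }
  list(t = t_mat, omega = bc$omega, rho = bc$rho, excluded_pairs = pairs)
}

#' SparCC basis correlations for a count table
#'
#' Runs `n_inference_iter` Dirichlet resampling iterations; each iteration
#' draws fractions from `Dirichlet(counts + 1)`, computes log-ratio
#' variances, and solves for basis correlations with up to
#' `n_exclusion_iter` rounds of strong-pair exclusion (the single pair with
#' the largest `|rho| > exclusion_threshold` is removed from the sparsity
#' system each round). Iterations are aggregated element-wise by the median.
#'
#' @param ct A [count_table()] or count matrix (>= 4 taxa).
#' @param n_inference_iter Dirichlet resampling iterations. Default 20.
#' @param n_exclusion_iter Maximum exclusion rounds per iteration. Default 10.
#' @param exclusion_threshold Exclude pairs with `|rho|` above this; 1
#'   disables exclusion. Default 0.1.
#' @param seed Seed controlling all Dirichlet draws.
#' @return A `sparcc_fit`: `rho` (median basis correlations), `omega`
#'   (median basis variances), `t` (median log-ratio variances),
#'   `excluded_pairs` (unique pairs excluded in any iteration), `pvals`
#'   (`NULL` until [sparcc_pvalues()] is run), plus the call parameters.
#' @seealso [sparcc_pvalues()], [build_network()]
#' @export
sparcc <- function(ct, n_inference_iter = 20, n_exclusion_iter = 10,
                   exclusion_threshold = 0.1, seed = 1) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  if (nrow(m) < 4) abort("basis estimation needs at least 4 taxa")
  if (n_inference_iter < 1) abort("n_inference_iter must be >= 1")
  n_clamped <- 0L
  runs <- withCallingHandlers(
    with_seed(seed, {
      lapply(seq_len(n_inference_iter), function(i) {
        f <- to_fractions(m, "dirichlet_draw")
        sparcc_single(f, n_exclusion_iter, exclusion_threshold)
      })
    }),
    warning = function(w) {
      if (grepl("basis variance", conditionMessage(w))) {
        n_clamped <<- n_clamped + 1L
        invokeRestart("muffleWarning")
      }
    }
  )
  if (n_clamped > 0) {
    warn(sprintf(
      "non-positive basis variances clamped in %d solve(s) across %d iterations",
      n_clamped, n_inference_iter
    ))
  }
  agg <- function(field) {
    arr <- vapply(runs, `[[`, runs[[1]][[field]], field)
    if (is.matrix(runs[[1]][[field]])) {
      apply(arr, c(1, 2), median)
    } else {
      apply(arr, 1, median)
    }
  }
  rho <- agg("rho")
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(m), rownames(m))
  pairs <- unique(unlist(
    lapply(runs, function(r) {
      vapply(r$excluded_pairs, paste, character(1), collapse = "|")
    })
  ))
  structure(
    list(
      rho = rho,
      omega = setNames(agg("omega"), rownames(m)),
      t = agg("t"),
      excluded_pairs = lapply(strsplit(pairs, "|", fixed = TRUE), identity),
      pvals = NULL,
      counts = m,
      params = list(
        n_inference_iter = n_inference_iter,
        n_exclusion_iter = n_exclusion_iter,
        exclusion_threshold = exclusion_threshold,
        seed = seed
      )
    ),
    class = "sparcc_fit"
  )
}

#' @export
print.sparcc_fit <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf(
    "<sparcc_fit> %d taxa; median |rho| = %.3f; %d pair(s) excluded; %s\n",
    nrow(x$rho), median(abs(off)), length(x$excluded_pairs),
    if (is.null(x$pvals)) "no p-values yet" else "permutation p-values attached"
  ))
  invisible(x)
}

#' Permutation pseudo-p-values for SparCC correlations
#'
#' Each taxon's counts are shuffled independently across samples, the full
#' estimator is re-run on the permuted table, and the two-sided
#' pseudo-p-value for each pair is `(1 + #{|rho_perm| >= |rho_obs|}) /
#' (1 + n_perm)`, bounded below by `1/(n_perm + 1)`.
#'
#' @param fit A [sparcc()] fit.
#' @param n_perm Number of permutations (>= 1). Default 100.
#' @param seed Seed for the permutations and their Dirichlet draws.
#' @param ... Overrides for the sparcc parameters used on permuted tables
#'   (defaults to the observed fit's parameters).
#' @return The fit with `pvals` filled in (symmetric, unit diagonal-free:
#'   diagonal set to 1).
#' @export
sparcc_pvalues <- function(fit, n_perm = 100, seed = 1, ...) {
  stopifnot(inherits(fit, "sparcc_fit"))
  if (n_perm < 1) abort("n_perm must be >= 1")
  m <- fit$counts
  pars <- modifyList(fit$params, list(...))
  obs <- abs(fit$rho)
  exceed <- matrix(0, nrow(m), nrow(m))
  for (b in seq_len(n_perm)) {
    sh <- with_seed(child_seed(seed, b), {
      t(apply(m, 1, sample))
    })
    dimnames(sh) <- dimnames(m)
    perm_fit <- sparcc(sh,
      n_inference_iter = pars$n_inference_iter,
      n_exclusion_iter = pars$n_exclusion_iter,
      exclusion_threshold = pars$exclusion_threshold,
      seed = child_seed(seed, n_perm + b)
    )
    exceed <- exceed + (abs(perm_fit$rho) >= obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  p[p > 1] <- 1
  diag(p) <- 1
  dimnames(p) <- dimnames(fit$rho)
  fit$pvals <- p
  fit$params$n_perm <- n_perm
  fit
}

#' @rdname sparcc
#' @param x A `sparcc_fit`.
#' @param ... Unused.
#' @return `tidy()` returns one row per taxon pair: `taxon_a`, `taxon_b`,
#'   `rho`, and `p` when permutation p-values have been computed.
#' @export
tidy.sparcc_fit <- function(x, ...) {
  ut <- which(upper.tri(x$rho), arr.ind = TRUE)
  taxa <- rownames(x$rho)
  out <- tibble(
    taxon_a = taxa[ut[, 1]],
    taxon_b = taxa[ut[, 2]],
    rho = x$rho[ut]
  )
  if (!is.null(x$pvals)) out$p <- x$pvals[ut]
  dplyr::arrange(out, dplyr::desc(abs(.data$rho)))
}

#' @rdname sparcc
#' @export
glance.sparcc_fit <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  tibble(
    n_taxa = nrow(x$rho),
    n_samples = ncol(x$counts),
    mean_abs_rho = mean(abs(off)),
    max_abs_rho = max(abs(off)),
    n_excluded_pairs = length(x$excluded_pairs),
    n_inference_iter = x$params$n_inference_iter
  )
}
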