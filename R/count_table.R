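#' Build a taxa-by-sample count table
#'
#' The universal input of the pipeline: a non-negative integer matrix with
#' taxa as rows and samples as columns, plus a per-sample metadata table
#' (group labels, antibody titres, collection day, ...).
#'
#' @param counts Numeric matrix (taxa x samples) of non-negative integers,
#'   with unique rownames (taxon IDs) and colnames (sample IDs). A long-format
#'   data frame with columns `taxon`, `sample`, `count` is also accepted.
#' @param metadata Optional data frame with a `sample` column matching the
#'   count table's sample IDs; typically also a `group` column.
#' @return An object of class `count_table` with elements `counts`
#'   (integer matrix) and `metadata` (tibble, one row per sample).
#' @examples
#' m <- matrix(c(5, 0, 2, 7, 1, 3), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' ct <- count_table(m)
#' ct
#' @export
count_table <- function(counts, metadata = NULL) {
  if (is.data.frame(counts)) {
    need <- c("taxon", "sample", "count")
    if (!all(need %in% names(counts))) {
      abort("long-format input needs columns taxon, sample and count")
    }
    wide <- tidyr::pivot_wider(counts[need],
      names_from = "sample", values_from = "count", values_fill = 0
    )
    counts <- as.matrix(wide[-1])
    rownames(counts) <- wide$taxon
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("taxon_", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  }
  validate_counts_matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(metadata)) {
    metadata <- tibble(sample = colnames(counts))
  } else {
    metadata <- as_tibble(metadata)
    if (!"sample" %in% names(metadata)) {
      abort("metadata must contain a `sample` column")
    }
    missing <- setdiff(colnames(counts), metadata$sample)
    if (length(missing) > 0) {
      abort(paste0(
        "metadata is missing samples: ", paste(missing, collapse = ", ")
      ))
    }
    metadata <- metadata[match(colnames(counts), metadata$sample), ]
  }
  structure(list(counts = counts, metadata = metadata),
    class = "count_table"
  )
}

validate_counts_matrix <- function(counts) {
  if (any(!is.finite(counts))) abort("counts must be finite")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "negative count at taxon '%s', sample '%s'",
      rownames(counts)[bad[1]], colnames(counts)[bad[2]]
    ))
  }
  if (max(abs(counts - round(counts))) > 1e-6) {
    abort("counts must be integers (tolerance 1e-6)")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate taxon IDs")
  if (anyDuplicated(colnames(counts))) abort("duplicate sample IDs")
  invisible(counts)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "<count_table> %d taxa x %d samples\n",
    nrow(x$counts), ncol(x$counts)
  ))
  if ("group" %in% names(x$metadata)) {
    tab <- table(x$metadata$group)
    cat("groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' @rdname count_table
#' @param x A `count_table`.
#' @param ... Unused.
#' @export
tidy.count_table <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "taxon")
  long <- tidyr::pivot_longer(long, -"taxon",
    names_to = "sample", values_to = "count"
  )
  dplyr::left_join(long, x$metadata, by = "sample")
}

#' Per-sample relative abundances
#'
#' @param ct A [count_table()].
#' @return Numeric matrix of column-normalised fractions (columns sum to 1).
#' @export
relative_abundance <- function(ct) {
  m <- ct$counts
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0(
      "all-zero sample(s): ",
      paste(colnames(m)[tot == 0], collapse = ", ")
    ))
  }
  sweep(m, 2, tot, "/")
}

#' Collapse counts to a coarser taxonomic level
#'
#' Sums rows sharing a label (e.g. ASVs of the same genus) before network
#' inference.
#'
#' @param ct A [count_table()].
#' @param labels Character vector, one label per row of `ct`.
#' @return A `count_table` with one row per unique label.
#' @export
collapse_taxa <- function(ct, labels) {
  if (length(labels) != nrow(ct$counts)) {
    abort("labels must have one entry per taxon")
  }
  agg <- rowsum(ct$counts, group = labels)
  count_table(agg, ct$metadata)
}

#' Subset a count table to a set of samples
#'
#' @param ct A [count_table()].
#' @param samples Character vector of sample IDs, or a logical/integer index
#'   over samples.
#' @return A `count_table`.
#' @export
subset_samples <- function(ct, samples) {
  if (is.character(samples)) {
    missing <- setdiff(samples, colnames(ct$counts))
    if (length(missing) > 0) {
      abort(paste0("unknown samples: ", paste(missing, collapse = ", ")))
    }
    idx <- match(samples, colnames(ct$counts))
  } else {
    idx <- seq_len(ncol(ct$counts))[samples]
  }
  count_table(
    ct$counts[, idx, drop = FALSE],
    ct$metadata[match(colnames(ct$counts)[idx], ct$metadata$sample), ]
  )
}
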