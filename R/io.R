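#' Read a count table from TSV or BIOM-style JSON
#'
#' The TSV layout is taxa as rows and samples as columns, first column
#' `taxon`, header row of sample IDs; lines starting with `#` are comments.
#' The BIOM-style JSON dialect is the minimal dense/sparse triplet form:
#' top-level `rows` (list of `{id}`), `columns` (list of `{id}`), and `data`
#' as either a dense matrix or `[row, column, value]` triplets (0-based).
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom_json"`.
#' @param metadata Optional metadata data frame or TSV path (must contain a
#'   `sample` column).
#' @return A [count_table()].
#' @export
read_counts <- function(path, format = c("tsv", "biom_json"),
                        metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "tsv") {
    df <- readr::read_tsv(path,
      comment = "#", show_col_types = FALSE,
      progress = FALSE
    )
    if (ncol(df) < 2) abort("malformed counts TSV: need taxon + >=1 sample")
    m <- as.matrix(df[-1])
    if (!is.numeric(m)) abort("malformed counts TSV: non-numeric entries")
    rownames(m) <- as.character(df[[1]])
  } else {
    b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(b$rows) || is.null(b$columns) || is.null(b$data)) {
      abort("malformed BIOM JSON: need rows, columns, data")
    }
    taxa <- vapply(b$rows, function(r) as.character(r$id), character(1))
    samples <- vapply(b$columns, function(r) as.character(r$id), character(1))
    m <- matrix(0, length(taxa), length(samples),
      dimnames = list(taxa, samples)
    )
    dense <- identical(b$matrix_type, "dense") ||
      (length(b$data) == length(taxa) &&
        length(b$data[[1]]) == length(samples) && is.null(b$matrix_type))
    if (dense) {
      for (i in seq_along(b$data)) m[i, ] <- unlist(b$data[[i]])
    } else {
      for (trip in b$data) {
        m[trip[[1]] + 1L, trip[[2]] + 1L] <- trip[[3]]
      }
    }
  }
  if (is.character(metadata)) {
    metadata <- readr::read_tsv(metadata,
      comment = "#", show_col_types = FALSE, progress = FALSE
    )
  }
  count_table(m, metadata)
}

#' Write a count table (and its metadata) to TSV
#'
#' @param ct A [count_table()].
#' @param path Output TSV path for the counts.
#' @param metadata_path Optional path for the sample metadata TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(ct, path, metadata_path = NULL) {
  df <- as_tibble(ct$counts, rownames = "taxon")
  writeLines("# taxa x samples count table; columns: taxon, <sample IDs>",
    con = path
  )
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  if (!is.null(metadata_path)) {
    writeLines("# per-sample metadata; one row per sample", metadata_path)
    readr::write_tsv(ct$metadata, metadata_path,
      append = TRUE,
      col_names = TRUE
    )
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] with
#' error reporting; branch lengths and quoted labels are supported.
#'
#' @param path Newick file path.
#' @return `read_newick()` returns an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
    error = function(e) NULL
  )
  if (is.null(tr)) {
    abort(paste0("unparseable Newick in ", path))
  }
  tr
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a signed network as GEXF
#'
#' Writes nodes with abundance, ubiquity and eigenvector-centrality
#' attributes and signed weighted edges, readable by Gephi or any generic
#' GEXF parser.
#'
#' @param net A [build_network()] result.
#' @param path Output `.gexf` path.
#' @return `path`, invisibly.
#' @export
write_network_gexf <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  nodes <- net$nodes
  cent <- tryCatch(eigenvector_centrality(net), error = function(e) {
    setNames(rep(NA_real_, nrow(nodes)), nodes$taxon)
  })
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2"
  )
  graph <- xml2::xml_add_child(doc, "graph",
    mode = "static",
    defaultedgetype = "undirected"
  )
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  specs <- list(
    c("0", "mean_relative_abundance", "double"),
    c("1", "ubiquity", "double"),
    c("2", "eigenvector_centrality", "double")
  )
  for (s in specs) {
    xml2::xml_add_child(attrs, "attribute",
      id = s[1], title = s[2],
      type = s[3]
    )
  }
  xnodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(xnodes, "node",
      id = nodes$taxon[i], label = nodes$taxon[i]
    )
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue",
      `for` = "0",
      value = format(nodes$mean_relative_abundance[i], digits = 10)
    )
    xml2::xml_add_child(av, "attvalue",
      `for` = "1",
      value = format(nodes$ubiquity[i], digits = 10)
    )
    xml2::xml_add_child(av, "attvalue",
      `for` = "2",
      value = format(unname(cent[nodes$taxon[i]]), digits = 10)
    )
  }
  xedges <- xml2::xml_add_child(graph, "edges")
  ed <- net$edges
  for (i in seq_len(nrow(ed))) {
    xml2::xml_add_child(xedges, "edge",
      id = as.character(i - 1L),
      source = ed$taxon_a[i], target = ed$taxon_b[i],
      weight = format(abs(ed$weight[i]), digits = 10),
      label = ed$sign[i]
    )
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write / read a signed-network edge list TSV
#'
#' Columns: `taxon_a`, `taxon_b`, `weight`, `sign`, `p`.
#'
#' @param net A [build_network()] result.
#' @param path TSV path.
#' @export
write_edge_list <- function(net, path) {
  writeLines("# signed network edges; columns: taxon_a, taxon_b, weight, sign, p",
    con = path
  )
  readr::write_tsv(net$edges, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
}

#' Write a symmetric taxon-by-taxon matrix (correlations, p-values) to TSV
#'
#' @param m Matrix with dimnames.
#' @param path TSV path.
#' @param what One-word description used in the header comment.
#' @export
write_matrix_tsv <- function(m, path, what = "matrix") {
  writeLines(sprintf("# taxa x taxa %s; columns: taxon, <taxon IDs>", what),
    con = path
  )
  readr::write_tsv(as_tibble(m, rownames = "taxon"), path,
    append = TRUE, col_names = TRUE
  )
  invisible(path)
}
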