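#' Published network summary (worked-example fixture)
#'
#' Printed summary values, transcribed from a published anti-tick-microbiota
#' vaccination study, for the three co-occurrence networks it reports:
#' control (mock-immunized), keystone-vaccinated and
#' non-keystone-vaccinated. Used to demonstrate and check the arithmetic of
#' [topology_arithmetic()] (signed-edge percentages, average degree) and the
#' keystone centrality fold change; the networks themselves derive from
#' sequencing data and unstated edge thresholds and are not reproducible
#' from these counts.
#'
#' @return Tibble with columns `network`, `nodes`, `edges`,
#'   `positive_edges`, `negative_edges`, `keystone_eigenvector`,
#'   `random_removal_fraction`, `directed_removal_fraction`.
#' @export
published_network_summary <- function() {
  readr::read_tsv(
    system.file("extdata", "published_network_summary.tsv",
      package = "micronet", mustWork = TRUE
    ),
    comment = "#", show_col_types = FALSE, progress = FALSE,
    na = "NA"
  )
}
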