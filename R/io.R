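# Tab-delimited readers for the standard input tables and Cytoscape-ready
# network exports (SIF, GraphML).

read_checked_tsv <- function(path, needed, what) {
  x <- readr::read_tsv(path, col_types = readr::cols(), show_col_types = FALSE)
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      what, " file ", path, " is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x
}

#' Read the standard input tables
#'
#' Tab-delimited, header required, UTF-8. Expected columns:
#' * component catalog: `id`, `name`, `formula`, `herb_class`, optional
#'   `structure` (validated against the catalog invariants);
#' * dock table: `component_id`, `protein_id`, `engine`, `score`,
#'   `positive_control_score`;
#' * text-mining edges: `component_id`, `protein_id`;
#' * PPI edge list: `protein_a`, `protein_b`, `combined_score` (either in
#'   (0, 1] or STRING-style 0-1000; see [filter_ppi()]);
#' * metabolite pathway enrichment: `metabolite`, `pathway`, `p`;
#' * pathway membership: `pathway`, `protein`;
#' * annotations: `gene`, `term_id`, `term_name`, `namespace`.
#'
#' @param path Path to a TSV file.
#' @return A tibble (the catalog reader validates invariants too).
#' @export
read_components <- function(path) {
  validate_catalog(read_checked_tsv(path, c("id", "name", "formula", "herb_class"), "Component catalog"))
}

#' @rdname read_components
#' @export
read_dock_table <- function(path) {
  read_checked_tsv(
    path,
    c("component_id", "protein_id", "engine", "score", "positive_control_score"),
    "Dock table"
  )
}

#' @rdname read_components
#' @export
read_text_edges <- function(path) {
  read_checked_tsv(path, c("component_id", "protein_id"), "Text-mining edge")
}

#' @rdname read_components
#' @export
read_ppi_table <- function(path) {
  read_checked_tsv(path, c("protein_a", "protein_b", "combined_score"), "PPI")
}

#' @rdname read_components
#' @export
read_enrichment_table <- function(path) {
  read_checked_tsv(path, c("metabolite", "pathway", "p"), "Enrichment")
}

#' @rdname read_components
#' @export
read_membership_table <- function(path) {
  read_checked_tsv(path, c("pathway", "protein"), "Membership")
}

#' @rdname read_components
#' @export
read_annotation_table <- function(path) {
  read_checked_tsv(path, c("gene", "term_id", "term_name", "namespace"), "Annotation")
}

#' Export a layered network for Cytoscape
#'
#' `write_sif()` writes the simple interaction format
#' (`source<TAB>edge_type<TAB>target`); `write_graphml()` writes GraphML
#' with the node roles and edge attributes preserved.
#'
#' @param x A `cpmi_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path) {
  stopifnot(inherits(x, "cpmi_network"))
  lines <- paste(x$edges$from, x$edges$edge_type, x$edges$to, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(x, path) {
  stopifnot(inherits(x, "cpmi_network"))
  igraph::write_graph(as.igraph(x), path, format = "graphml")
  invisible(path)
}
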