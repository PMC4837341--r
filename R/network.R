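# Layered network container shared by all evidence layers (CTPI, PPI, MPPI,
# NATPI, CPMI). Undirected; layer semantics are imposed at traversal time.

NODE_ROLES <- c("component", "target", "pathway_protein", "metabolite")
EDGE_TYPES <- c("component-target", "protein-protein", "pathway-metabolite")

#' Construct a layered interaction network
#'
#' A `cpmi_network` holds role-annotated nodes and typed, provenance-tagged
#' undirected edges. The same container represents every evidence layer:
#' the component-target interaction network (CTPI), the confidence-filtered
#' protein-protein interaction network (PPI), the metabolite-pathway-protein
#' network (MPPI), and their unions (NATPI, CPMI). A node may hold several
#' roles at once (e.g. a protein that is both a predicted target and a member
#' of an enriched pathway).
#'
#' @param nodes A data frame with columns `node` (character, unique,
#'   case-sensitive) and `roles` (list column of character vectors, each a
#'   subset of `component`, `target`, `pathway_protein`, `metabolite`; a
#'   plain character column is accepted and wrapped).
#' @param edges A data frame with columns `from`, `to` (node ids),
#'   `edge_type` (one of `component-target`, `protein-protein`,
#'   `pathway-metabolite`), and optionally `provenance` (list column of
#'   character vectors drawn from `text`, `dock`, `curated`) and
#'   `confidence` (numeric in (0, 1], required for protein-protein edges).
#' @param validate Check the container invariants (default `TRUE`).
#'
#' @return An object of class `cpmi_network`: a list with tibbles `nodes`
#'   and `edges`.
#'
#' @examples
#' net <- cpmi_network(
#'   nodes = tibble::tibble(
#'     node = c("S25", "TNF", "M1"),
#'     roles = list("component", "target", "metabolite")
#'   ),
#'   edges = tibble::tibble(
#'     from = c("S25", "TNF"),
#'     to = c("TNF", "M1"),
#'     edge_type = c("component-target", "pathway-metabolite"),
#'     provenance = list("dock", character()),
#'     confidence = NA_real_
#'   )
#' )
#' network_stats(net)
#' @export
cpmi_network <- function(nodes = NULL, edges = NULL, validate = TRUE) {
  nodes <- normalize_nodes(nodes)
  edges <- normalize_edges(edges)
  x <- structure(list(nodes = nodes, edges = edges), class = "cpmi_network")
  if (validate) validate_network(x)
  x
}

#' @rdname cpmi_network
#' @export
empty_network <- function() cpmi_network()

normalize_nodes <- function(nodes) {
  if (is.null(nodes) || nrow(as_tibble(nodes)) == 0) {
    return(tibble(node = character(), roles = list()))
  }
  nodes <- as_tibble(nodes)
  if (!all(c("node", "roles") %in% names(nodes))) {
    abort("`nodes` must have columns `node` and `roles`.")
  }
  if (!is.list(nodes$roles)) nodes$roles <- as.list(nodes$roles)
  nodes$node <- as.character(nodes$node)
  nodes$roles <- map(nodes$roles, function(r) sort(unique(as.character(r))))
  # collapse duplicate node rows by role union
  nodes |>
    summarise(roles = list(sort(unique(unlist(roles)))), .by = node) |>
    arrange(node)
}

normalize_edges <- function(edges) {
  if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    return(tibble(
      from = character(), to = character(), edge_type = character(),
      provenance = list(), confidence = double()
    ))
  }
  edges <- as_tibble(edges)
  if (!all(c("from", "to", "edge_type") %in% names(edges))) {
    abort("`edges` must have columns `from`, `to` and `edge_type`.")
  }
  if (!"provenance" %in% names(edges)) edges$provenance <- rep(list(character()), nrow(edges))
  if (!is.list(edges$provenance)) edges$provenance <- as.list(edges$provenance)
  if (!"confidence" %in% names(edges)) edges$confidence <- NA_real_
  edges <- edges |>
    mutate(
      from = as.character(from), to = as.character(to),
      edge_type = as.character(edge_type),
      provenance = map(provenance, function(p) sort(unique(as.character(p)))),
      confidence = as.double(confidence)
    )
  dedupe_edges(edges)
}

# Undirected dedup on (unordered endpoints, edge_type); provenance is
# unioned, confidence keeps the maximum observed value.
dedupe_edges <- function(edges) {
  edges |>
    mutate(
      .a = pmin(from, to), .b = pmax(from, to)
    ) |>
    summarise(
      from = from[1], to = to[1],
      provenance = list(sort(unique(unlist(provenance)))),
      confidence = if (all(is.na(confidence))) NA_real_ else max(confidence, na.rm = TRUE),
      .by = c(.a, .b, edge_type)
    ) |>
    select(from, to, edge_type, provenance, confidence) |>
    arrange(edge_type, pmin(from, to), pmax(from, to))
}

#' Validate the invariants of a layered network
#'
#' Checks that node ids are unique and non-missing, roles are drawn from the
#' four-role vocabulary, every edge endpoint is a node, there are no
#' self-edges, edge types are known, protein-protein edges carry a
#' confidence in (0, 1], and component-target edges carry a non-empty
#' provenance.
#'
#' @param x A `cpmi_network`.
#' @return `x`, invisibly, if valid; otherwise an error describing every
#'   violated invariant.
#' @export
validate_network <- function(x) {
  stopifnot(inherits(x, "cpmi_network"))
  nodes <- x$nodes
  edges <- x$edges
  problems <- character()

  if (anyNA(nodes$node) || any(!nzchar(nodes$node))) {
    problems <- c(problems, "node ids must be non-missing, non-empty strings")
  }
  if (anyDuplicated(nodes$node)) {
    problems <- c(problems, paste0(
      "duplicate node ids: ",
      paste(unique(nodes$node[duplicated(nodes$node)]), collapse = ", ")
    ))
  }
  bad_roles <- setdiff(unique(unlist(nodes$roles)), NODE_ROLES)
  if (length(bad_roles) > 0) {
    problems <- c(problems, paste0("unknown roles: ", paste(bad_roles, collapse = ", ")))
  }
  if (nrow(edges) > 0) {
    missing_ep <- setdiff(unique(c(edges$from, edges$to)), nodes$node)
    if (length(missing_ep) > 0) {
      problems <- c(problems, paste0(
        "edge endpoints absent from nodes: ", paste(missing_ep, collapse = ", ")
      ))
    }
    if (any(edges$from == edges$to)) {
      problems <- c(problems, "self-edges are not allowed")
    }
    bad_type <- setdiff(unique(edges$edge_type), EDGE_TYPES)
    if (length(bad_type) > 0) {
      problems <- c(problems, paste0("unknown edge types: ", paste(bad_type, collapse = ", ")))
    }
    pp <- edges$edge_type == "protein-protein"
    if (any(pp & (is.na(edges$confidence) | edges$confidence <= 0 | edges$confidence > 1))) {
      problems <- c(problems, "protein-protein edges must carry a confidence in (0, 1]")
    }
    ct <- edges$edge_type == "component-target"
    if (any(ct & map_int(edges$provenance, length) == 0)) {
      problems <- c(problems, "component-target edges must carry a non-empty provenance")
    }
  }
  if (length(problems) > 0) {
    abort(c("Invalid cpmi_network:", problems))
  }
  invisible(x)
}

#' @export
print.cpmi_network <- function(x, ...) {
  st <- network_stats(x)
  cat("<cpmi_network> ", st$n_nodes, " nodes, ", st$n_edges, " edges\n", sep = "")
  rc <- st$role_counts
  if (nrow(rc) > 0) {
    cat("  roles: ", paste0(rc$role, "=", rc$n, collapse = ", "), "\n", sep = "")
  }
  tc <- st$edge_type_counts
  if (nrow(tc) > 0) {
    cat("  edges: ", paste0(tc$edge_type, "=", tc$n, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Node and edge counts of a layered network
#'
#' @param x A `cpmi_network`.
#' @return A list with `n_nodes`, `n_edges`, a `role_counts` tibble (a node
#'   with several roles counts once per role), and an `edge_type_counts`
#'   tibble.
#' @export
network_stats <- function(x) {
  stopifnot(inherits(x, "cpmi_network"))
  role_counts <- tibble(role = unlist(x$nodes$roles)) |> count(role, name = "n")
  edge_type_counts <- x$edges |> count(edge_type, name = "n")
  list(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    role_counts = role_counts,
    edge_type_counts = edge_type_counts
  )
}

#' Node ids holding a given role
#'
#' @param x A `cpmi_network`.
#' @param role One of `component`, `target`, `pathway_protein`, `metabolite`.
#' @return Character vector of node ids, sorted.
#' @export
nodes_with_role <- function(x, role) {
  stopifnot(inherits(x, "cpmi_network"))
  role <- match.arg(role, NODE_ROLES)
  sort(x$nodes$node[map_lgl(x$nodes$roles, function(r) role %in% r)])
}

#' Union of two layered networks
#'
#' Node sets are unioned with role sets merged; the edge multiset is
#' deduplicated on (unordered endpoints, edge type) with provenance unioned
#' across duplicates. Combining the CTPI with the PPI yields the NATPI;
#' combining the NATPI with the MPPI yields the CPMI on which target
#' prioritization runs. The operation is associative and commutative and has
#' the empty network as identity.
#'
#' @param a,b `cpmi_network` objects.
#' @return A `cpmi_network`.
#' @export
union_networks <- function(a, b) {
  stopifnot(inherits(a, "cpmi_network"), inherits(b, "cpmi_network"))
  cpmi_network(
    nodes = bind_rows(a$nodes, b$nodes),
    edges = bind_rows(a$edges, b$edges)
  )
}

#' Convert a layered network to an igraph graph
#'
#' Roles and provenance are collapsed to comma-separated vertex/edge
#' attributes so the graph survives GraphML round trips.
#'
#' @param x A `cpmi_network`.
#' @param ... Unused.
#' @return An undirected `igraph` graph with vertex attribute `roles` and
#'   edge attributes `edge_type`, `provenance`, `confidence`.
#' @method as.igraph cpmi_network
#' @importFrom igraph as.igraph
#' @export as.igraph.cpmi_network
#' @export
as.igraph.cpmi_network <- function(x, ...) {
  vertices <- tibble(
    name = x$nodes$node,
    roles = map_chr(x$nodes$roles, paste, collapse = ",")
  )
  edges <- x$edges |>
    transmute(
      from, to, edge_type,
      provenance = map_chr(provenance, paste, collapse = ","),
      confidence = if_else(is.na(confidence), -1, confidence)
    )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}
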