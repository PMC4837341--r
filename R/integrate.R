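# Layer integration (NATPI, CPMI) and path-reachability target
# prioritization: a candidate target survives only if it connects an active
# component to a metabolite biomarker through the integrated network.

#' Assemble the NATPI and CPMI
#'
#' `build_natpi()` unions the component-target network (CTPI) with the
#' confidence-filtered PPI; `build_cpmi()` unions the result with the
#' metabolite-pathway-protein network (MPPI), yielding the fully integrated
#' component-protein-metabolite interaction network on which
#' [prioritize_targets()] runs. Both are thin, named wrappers over
#' [union_networks()].
#'
#' @param ctpi,ppi,natpi,mppi `cpmi_network` layers.
#' @return A `cpmi_network`.
#' @export
build_natpi <- function(ctpi, ppi) union_networks(ctpi, ppi)

#' @rdname build_natpi
#' @export
build_cpmi <- function(natpi, mppi) union_networks(natpi, mppi)

#' Prioritize targets by component-to-metabolite reachability
#'
#' Components are the initial nodes and metabolite biomarkers the terminal
#' nodes. A candidate target is retained if and only if (i) at least one
#' component-target edge touches it and (ii) it can reach a metabolite by
#' traversing protein-protein edges among nodes holding the `target` or
#' `pathway_protein` role, followed by a single pathway-metabolite edge.
#' A target that itself holds the `pathway_protein` role and has a direct
#' pathway-metabolite edge satisfies (ii) with a length-1 path. Components
#' never appear as intermediate path nodes: paths run component, target,
#' proteins, metabolite.
#'
#' One witness path per retained target is recorded via breadth-first search
#' with lexicographically ordered neighbor expansion, so results are
#' deterministic and explainable without enumerating all simple paths.
#'
#' @param cpmi A `cpmi_network` containing at least one node of each role
#'   (`component`, `target`, `pathway_protein`, `metabolite`).
#' @return A `target_prioritization` object with elements:
#'   * `retained`: tibble of retained targets ordered by descending
#'     component-degree (ties broken lexicographically), with columns
#'     `target`, `component_degree`, `witness_path` (list of node id
#'     vectors ending at a metabolite), `path_via_target` (logical: does the
#'     witness path pass through another target-role node).
#'   * `evidence`: named list, one entry per retained target with its linked
#'     components and witness path.
#'   * `stats`: [network_stats()] of the input CPMI.
#' @export
prioritize_targets <- function(cpmi) {
  stopifnot(inherits(cpmi, "cpmi_network"))
  validate_network(cpmi)
  missing_roles <- NODE_ROLES[map_int(NODE_ROLES, function(r) length(nodes_with_role(cpmi, r))) == 0]
  if (length(missing_roles) > 0) {
    abort(paste0(
      "CPMI lacks nodes with role(s): ", paste(missing_roles, collapse = ", "),
      "; all four roles are required for prioritization."
    ))
  }

  targets <- nodes_with_role(cpmi, "target")
  metabolites <- nodes_with_role(cpmi, "metabolite")
  proteins <- sort(union(targets, nodes_with_role(cpmi, "pathway_protein")))

  ct <- cpmi$edges |> filter(edge_type == "component-target")
  linked_components <- ct |>
    mutate(
      target = if_else(to %in% targets, to, from),
      comp = if_else(to %in% targets, from, to)
    ) |>
    filter(target %in% targets) |>
    summarise(components = list(sort(unique(comp))), .by = target)

  # protein-protein adjacency restricted to target/pathway_protein nodes
  pp <- cpmi$edges |>
    filter(edge_type == "protein-protein", from %in% proteins, to %in% proteins)
  adj <- ppi_adjacency(pp)

  # proteins anchored to a metabolite by a direct pathway-metabolite edge
  pm <- cpmi$edges |>
    filter(edge_type == "pathway-metabolite") |>
    mutate(
      prot = if_else(from %in% metabolites, to, from),
      met = if_else(from %in% metabolites, from, to)
    ) |>
    filter(prot %in% proteins, met %in% metabolites)
  anchor_mets <- split(pm$met, pm$prot) |> map(function(v) sort(unique(v)))

  evidence <- list()
  for (t in intersect(targets, linked_components$target)) {
    res <- bfs_witness(t, adj, anchor_mets)
    if (is.null(res)) next
    comps <- linked_components$components[[match(t, linked_components$target)]]
    evidence[[t]] <- list(
      target = t,
      components = comps,
      witness_path = res$path,
      path_via_target = any(res$path[-1] %in% setdiff(targets, t))
    )
  }

  retained <- if (length(evidence) == 0) {
    tibble(
      target = character(), component_degree = integer(),
      witness_path = list(), path_via_target = logical()
    )
  } else {
    tibble(
      target = unname(map_chr(evidence, "target")),
      component_degree = unname(map_int(evidence, function(e) length(e$components))),
      witness_path = unname(map(evidence, "witness_path")),
      path_via_target = unname(map_lgl(evidence, "path_via_target"))
    ) |>
      arrange(desc(component_degree), target)
  }
  evidence <- evidence[retained$target]

  structure(
    list(retained = retained, evidence = evidence, stats = network_stats(cpmi)),
    class = "target_prioritization"
  )
}

# BFS from `start` over adjacency `adj` (lexicographically sorted neighbor
# lists) until a node with an entry in `anchor_mets` is found; returns the
# witness path start -> ... -> anchor -> metabolite, or NULL.
bfs_witness <- function(start, adj, anchor_mets) {
  parent <- setNames(NA_character_, start)
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    if (!is.null(anchor_mets[[v]])) {
      path <- v
      while (!is.na(parent[[path[1]]])) path <- c(parent[[path[1]]], path)
      return(list(path = c(path, anchor_mets[[v]][1])))
    }
    for (w in adj[[v]] %||% character()) {
      if (!w %in% names(parent)) {
        parent[[w]] <- v
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

#' @export
print.target_prioritization <- function(x, ...) {
  cat("<target_prioritization> ", nrow(x$retained), " retained target(s)\n", sep = "")
  if (nrow(x$retained) > 0) {
    print(tidy(x), n = 10)
  }
  invisible(x)
}

#' @describeIn prioritize_targets Tidy the retained-target table: one row per
#'   retained target with its component degree, witness path (collapsed to a
#'   `" -> "` string), and whether the path runs through another target.
#' @param x A `target_prioritization`.
#' @param ... Unused.
#' @export
tidy.target_prioritization <- function(x, ...) {
  x$retained |>
    mutate(witness_path = map_chr(witness_path, paste, collapse = " -> "))
}

#' @describeIn prioritize_targets One-row summary: retained-target count and
#'   CPMI node/edge/role counts.
#' @export
glance.target_prioritization <- function(x, ...) {
  rc <- x$stats$role_counts
  counts <- setNames(as.list(rc$n), paste0("n_", rc$role))
  as_tibble(c(
    list(
      n_retained = nrow(x$retained),
      n_nodes = x$stats$n_nodes,
      n_edges = x$stats$n_edges
    ),
    counts
  ))
}

#' Stratify CTPI targets by component degree
#'
#' Classifies each target by its number of distinct interacting components
#' in the component-target network: degree 1-9 is `low`, 10-19 `middle`,
#' and 20 or more `high` (the upper stratum is open-ended; the observed
#' maximum in any given study does not cap it). Targets with degree 0 are
#' excluded with a warning.
#'
#' @param ctpi A `cpmi_network` containing component-target edges.
#' @return A tibble with columns `target`, `degree`, `stratum` (factor with
#'   levels `low`, `middle`, `high`), sorted by descending degree then
#'   target id.
#' @export
degree_stratify <- function(ctpi) {
  stopifnot(inherits(ctpi, "cpmi_network"))
  targets <- nodes_with_role(ctpi, "target")
  ct <- ctpi$edges |> filter(edge_type == "component-target")
  deg <- ct |>
    mutate(
      target = if_else(to %in% targets, to, from),
      comp = if_else(to %in% targets, from, to)
    ) |>
    filter(target %in% targets) |>
    summarise(degree = n_distinct(comp), .by = target)
  isolated <- setdiff(targets, deg$target)
  if (length(isolated) > 0) {
    warn(paste0(
      "Excluding isolated target(s) with component degree 0: ",
      paste(isolated, collapse = ", ")
    ))
  }
  deg |>
    mutate(
      stratum = factor(
        case_when(degree >= 20 ~ "high", degree >= 10 ~ "middle", .default = "low"),
        levels = c("low", "middle", "high")
      )
    ) |>
    arrange(desc(degree), target)
}
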