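# Evidence-layer construction: dock-score filtering against positive-control
# cutoffs, CTPI assembly from dock + text-mining edges, confidence filtering
# of the PPI, and MPPI construction from metabolite pathway enrichment.

#' Filter docking records against per-protein positive-control cutoffs
#'
#' Each docked protein carries the score of its co-crystallized ligand
#' (the positive control). A component-target edge is emitted if and only if
#' the component's dock score strictly beats that cutoff in the engine's
#' favorable direction. Some engines score higher-is-better (e.g. LibDock),
#' others lower-is-better (e.g. AutoDock Vina), so an orientation must be
#' declared for every engine tag present; no default is guessed.
#'
#' @param records A data frame with columns `component_id`, `protein_id`,
#'   `engine`, `score`, `positive_control_score`.
#' @param orientation Named character vector mapping each engine tag to
#'   `"greater_better"` or `"lesser_better"`.
#' @param tolerance Non-negative slack subtracted from the margin before the
#'   strict comparison, for engines with coarse score grids. The default 0
#'   keeps the comparison strict: a score equal to the cutoff emits no edge.
#' @return A tibble of component-target edges (`from` = component, `to` =
#'   protein, `edge_type = "component-target"`, `provenance = "dock"`),
#'   suitable for [merge_ctpi()].
#' @examples
#' recs <- tibble::tibble(
#'   component_id = c("S25", "S26"), protein_id = "TNF",
#'   engine = "libdock", score = c(62, 55), positive_control_score = 55
#' )
#' apply_dock_cutoff(recs, c(libdock = "greater_better"))
#' @export
apply_dock_cutoff <- function(records, orientation, tolerance = 0) {
  records <- as_tibble(records)
  needed <- c("component_id", "protein_id", "engine", "score", "positive_control_score")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  stopifnot(is.numeric(tolerance), tolerance >= 0)

  engines <- unique(records$engine)
  unknown <- setdiff(engines, names(orientation))
  if (length(unknown) > 0) {
    abort(paste0(
      "No score orientation declared for engine(s): ",
      paste(unknown, collapse = ", ")
    ))
  }
  bad_orient <- setdiff(unname(orientation[engines]), c("greater_better", "lesser_better"))
  if (length(bad_orient) > 0) {
    abort("Orientations must be \"greater_better\" or \"lesser_better\".")
  }
  no_control <- records$protein_id[is.na(records$positive_control_score)]
  if (length(no_control) > 0) {
    abort(paste0(
      "Missing positive-control score for protein(s): ",
      paste(sort(unique(no_control)), collapse = ", ")
    ))
  }

  records |>
    mutate(
      margin = if_else(
        orientation[engine] == "greater_better",
        score - positive_control_score,
        positive_control_score - score
      )
    ) |>
    filter(margin > tolerance) |>
    distinct(component_id, protein_id) |>
    transmute(
      from = component_id, to = protein_id,
      edge_type = "component-target",
      provenance = rep(list("dock"), n()),
      confidence = NA_real_
    )
}

#' Curated text-mining edges in CTPI edge form
#'
#' @param pairs A data frame with columns `component_id`, `protein_id`
#'   (additional columns are ignored).
#' @return A tibble of component-target edges with provenance `"text"`.
#' @export
text_mining_edges <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("component_id", "protein_id") %in% names(pairs))) {
    abort("`pairs` must have columns `component_id` and `protein_id`.")
  }
  pairs |>
    distinct(component_id, protein_id) |>
    transmute(
      from = component_id, to = protein_id,
      edge_type = "component-target",
      provenance = rep(list("text"), n()),
      confidence = NA_real_
    )
}

#' Merge dock and text-mining evidence into the CTPI
#'
#' Duplicate (component, protein) pairs collapse to a single edge whose
#' provenance is the union of sources, so a pair supported by both docking
#' and text mining carries provenance `{dock, text}`. Nodes are assigned the
#' `component` / `target` roles from their side of the edges.
#'
#' @param dock_edges,text_edges Component-target edge tibbles, e.g. from
#'   [apply_dock_cutoff()] and [text_mining_edges()]. Either may be empty.
#' @param components Optional component catalog (data frame with an `id`
#'   column). Edges referencing a component absent from the catalog are kept
#'   (ids are authoritative) but reported with a warning.
#' @return A `cpmi_network` — the component-target protein interaction
#'   network (CTPI).
#' @export
merge_ctpi <- function(dock_edges, text_edges, components = NULL) {
  edges <- bind_rows(as_tibble(dock_edges), as_tibble(text_edges))
  if (nrow(edges) > 0 && !all(edges$edge_type == "component-target")) {
    abort("All CTPI input edges must have edge_type \"component-target\".")
  }
  if (!is.null(components) && nrow(edges) > 0) {
    unknown <- setdiff(unique(edges$from), as_tibble(components)$id)
    if (length(unknown) > 0) {
      warn(paste0(
        "CTPI edges reference component(s) absent from the catalog ",
        "(kept, ids are authoritative): ", paste(sort(unknown), collapse = ", ")
      ))
    }
  }
  nodes <- bind_rows(
    tibble(node = unique(edges$from), roles = list("component")),
    tibble(node = unique(edges$to), roles = list("target"))
  )
  cpmi_network(nodes = nodes, edges = edges)
}

#' Filter a protein-protein interaction edge list by confidence
#'
#' Retains exactly the edges whose confidence is strictly greater than
#' `min_conf` (default 0.8, the conventional "high confidence" STRING
#' threshold). Scores may be given in (0, 1] or STRING-export style 0-1000;
#' if any score exceeds 1 the whole column is divided by 1000 (reported via
#' a message).
#'
#' @param edges A data frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (aliases `from`, `to`, `confidence` are accepted).
#' @param min_conf Confidence threshold; edges must strictly exceed it.
#' @return A `cpmi_network` containing only the retained edges and their
#'   endpoints. Nodes carry no roles yet; roles are acquired when the PPI is
#'   unioned with role-bearing layers.
#' @export
filter_ppi <- function(edges, min_conf = 0.8) {
  edges <- as_tibble(edges)
  if (all(c("protein_a", "protein_b", "combined_score") %in% names(edges))) {
    edges <- edges |> rename(from = protein_a, to = protein_b, confidence = combined_score)
  }
  if (!all(c("from", "to", "confidence") %in% names(edges))) {
    abort("`edges` must have columns `protein_a`, `protein_b`, `combined_score`.")
  }
  stopifnot(is.numeric(min_conf), length(min_conf) == 1, min_conf >= 0, min_conf <= 1)
  if (nrow(edges) == 0) {
    return(empty_network())
  }
  if (any(edges$confidence > 1, na.rm = TRUE)) {
    inform("PPI scores exceed 1; interpreting as STRING-style 0-1000 and dividing by 1000.")
    edges$confidence <- edges$confidence / 1000
  }
  bad <- is.na(edges$confidence) | edges$confidence <= 0 | edges$confidence > 1
  if (any(bad)) {
    abort(c(
      "PPI confidences must lie in (0, 1]:",
      paste0(
        "record ", which(bad), ": ", edges$from[bad], " - ", edges$to[bad],
        " (", edges$confidence[bad], ")"
      )[seq_len(min(5, sum(bad)))]
    ))
  }
  kept <- edges |>
    filter(confidence > min_conf) |>
    transmute(
      from, to, edge_type = "protein-protein",
      provenance = rep(list("curated"), n()), confidence
    )
  nodes <- tibble(node = unique(c(kept$from, kept$to)), roles = rep(list(character()), length(unique(c(kept$from, kept$to)))))
  cpmi_network(nodes = nodes, edges = kept)
}

#' Build the metabolite-pathway-protein interaction network (MPPI)
#'
#' For every pathway enriched below `alpha` (strict `p < alpha`), the
#' pathway's member proteins become `pathway_protein` nodes linked directly
#' to the metabolite whose enrichment implicated the pathway. Each member
#' protein is then extended by its neighbors in the confidence-filtered PPI
#' (1 hop by default, matching the "add interactors" convention), which join
#' as `pathway_protein` nodes linked by the corresponding protein-protein
#' edges. Metabolites with no surviving pathway are absent from the result.
#'
#' @param metabolite_pathways A data frame with columns `metabolite`,
#'   `pathway`, `p` (enrichment p-values in \[0, 1\]).
#' @param memberships A data frame with columns `pathway`, `protein`.
#' @param ppi A confidence-filtered PPI as returned by [filter_ppi()], used
#'   for the neighbor extension. May be an empty network.
#' @param alpha Pathway significance threshold (default 0.05, strict).
#' @param neighbor_depth How many PPI hops to extend member proteins by
#'   (default 1; 0 disables the extension).
#' @return A `cpmi_network` with `metabolite` and `pathway_protein` nodes.
#' @export
build_mppi <- function(metabolite_pathways, memberships, ppi = empty_network(),
                       alpha = 0.05, neighbor_depth = 1) {
  mp <- as_tibble(metabolite_pathways)
  mem <- as_tibble(memberships)
  if (!all(c("metabolite", "pathway", "p") %in% names(mp))) {
    abort("`metabolite_pathways` must have columns `metabolite`, `pathway`, `p`.")
  }
  if (!all(c("pathway", "protein") %in% names(mem))) {
    abort("`memberships` must have columns `pathway`, `protein`.")
  }
  if (any(is.na(mp$p) | mp$p < 0 | mp$p > 1)) {
    abort("Enrichment p-values must lie in [0, 1].")
  }
  stopifnot(inherits(ppi, "cpmi_network"), neighbor_depth >= 0)

  sig <- mp |> filter(p < alpha)
  no_members <- setdiff(unique(sig$pathway), unique(mem$pathway))
  if (length(no_members) > 0) {
    warn(paste0(
      "Enriched pathway(s) without membership rows skipped: ",
      paste(sort(no_members), collapse = ", ")
    ))
    sig <- sig |> filter(!pathway %in% no_members)
  }
  if (nrow(sig) == 0) {
    return(empty_network())
  }

  direct <- sig |>
    inner_join(mem, by = "pathway", relationship = "many-to-many") |>
    distinct(metabolite, protein)
  pm_edges <- direct |>
    transmute(
      from = protein, to = metabolite, edge_type = "pathway-metabolite",
      provenance = rep(list("curated"), n()), confidence = NA_real_
    )

  # breadth-limited PPI extension of the member proteins
  members <- unique(direct$protein)
  ext_edges <- tibble()
  ext_nodes <- character()
  if (neighbor_depth > 0 && nrow(ppi$edges) > 0) {
    adj <- ppi_adjacency(ppi$edges)
    frontier <- intersect(members, names(adj))
    seen <- members
    for (d in seq_len(neighbor_depth)) {
      if (length(frontier) == 0) break
      hop <- ppi$edges |>
        filter(from %in% frontier | to %in% frontier)
      ext_edges <- bind_rows(ext_edges, hop)
      nbrs <- setdiff(unique(c(hop$from, hop$to)), seen)
      ext_nodes <- union(ext_nodes, nbrs)
      seen <- union(seen, nbrs)
      frontier <- intersect(nbrs, names(adj))
    }
  }

  nodes <- bind_rows(
    tibble(node = unique(sig$metabolite), roles = list("metabolite")),
    tibble(node = members, roles = list("pathway_protein")),
    tibble(node = ext_nodes, roles = rep(list("pathway_protein"), length(ext_nodes)))
  )
  cpmi_network(nodes = nodes, edges = bind_rows(pm_edges, ext_edges))
}

# adjacency list (sorted neighbors) from a protein-protein edge tibble
ppi_adjacency <- function(edges) {
  if (nrow(edges) == 0) {
    return(list())
  }
  long <- bind_rows(
    tibble(a = edges$from, b = edges$to),
    tibble(a = edges$to, b = edges$from)
  )
  split(long$b, long$a) |> map(function(v) sort(unique(v)))
}
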