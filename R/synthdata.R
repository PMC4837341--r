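# Fixture layer: the packaged 48-component catalog and a seeded generator of
# complete synthetic input bundles with planted ground truth, so every
# pipeline stage can be exercised without any database access.

#' Parse a molecular formula into atom counts
#'
#' @param formula A molecular formula string such as `"C34H47NO11"`.
#' @return Named integer vector of atom counts (elements in order of
#'   appearance); an error for anything that does not parse completely.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (!nzchar(formula)) abort("Empty molecular formula.")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    abort(paste0("Invalid molecular formula: \"", formula, "\""))
  }
  el <- sub("[0-9]*$", "", tokens)
  ct <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(nzchar(ct), suppressWarnings(as.integer(ct)), 1L)
  if (anyNA(counts) || any(counts < 1)) {
    abort(paste0("Invalid atom counts in formula: \"", formula, "\""))
  }
  out <- integer(0)
  for (i in seq_along(el)) {
    prev <- if (el[i] %in% names(out)) out[[el[i]]] else 0L
    out[el[i]] <- prev + counts[i]
  }
  out
}

#' Load the packaged 48-component catalog
#'
#' The catalog of potential active anti-heart-failure components of Sini
#' decoction (SND), a three-herb formula of *Aconitum carmichaelii*,
#' *Zingiber officinale* and *Glycyrrhiza uralensis*. Serial-number prefixes
#' encode the compound family: `S` alkaloids, `J` gingerols, `H` flavones,
#' `Z` saponins. Structures are not part of the published catalog, so the
#' `structure` column is empty; network modules do not need it and
#' descriptor computations skip such rows.
#'
#' @return A tibble with 48 rows and columns `id`, `name`, `formula`,
#'   `herb_class`, `structure`, validated against the catalog invariants
#'   (unique ids, herb class from the serial prefix, parseable formulas).
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_components.tsv", package = "cpminet", mustWork = TRUE)
  cat <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  validate_catalog(cat)
}

validate_catalog <- function(cat) {
  cat <- as_tibble(cat)
  needed <- c("id", "name", "formula", "herb_class")
  if (!all(needed %in% names(cat))) {
    abort(paste0("Component catalog must have columns: ", paste(needed, collapse = ", ")))
  }
  if (!"structure" %in% names(cat)) cat$structure <- NA_character_
  if (anyDuplicated(cat$id)) abort("Component ids must be unique.")
  bad_class <- !cat$herb_class %in% c("S", "J", "H", "Z")
  if (any(bad_class)) {
    abort(paste0(
      "herb_class must be one of S, J, H, Z; offending ids: ",
      paste(cat$id[bad_class], collapse = ", ")
    ))
  }
  mismatch <- substr(cat$id, 1, 1) != cat$herb_class
  if (any(mismatch)) {
    abort(paste0(
      "Serial-number prefix and herb_class disagree for: ",
      paste(cat$id[mismatch], collapse = ", ")
    ))
  }
  walk_ok <- map(cat$formula, parse_formula) # errors on bad formulas
  stopifnot(length(walk_ok) == nrow(cat))
  cat
}

# small pool of real, parseable structures used for synthetic catalogs so
# that descriptor/fingerprint code paths stay exercisable
SYNTH_STRUCTURE_POOL <- data.frame(
  structure = c(
    "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12", # quercetin
    "CC(=O)Oc1ccccc1C(=O)O", # aspirin
    "Cn1c(=O)c2c(ncn2C)n(C)c1=O", # caffeine
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O", # ibuprofen
    "CC(=O)Nc1ccc(O)cc1", # paracetamol
    "OC(=O)c1ccccc1", # benzoic acid
    "CN1CCCC1c1cccnc1", # nicotine
    "O=Cc1ccc(O)c(OC)c1", # vanillin
    "Oc1ccccc1O", # catechol
    "c1ccc2ccccc2c1" # naphthalene
  ),
  formula = c(
    "C15H10O7", "C9H8O4", "C8H10N4O2", "C13H18O2", "C8H9NO2",
    "C7H6O2", "C10H14N2", "C8H8O3", "C6H6O2", "C10H8"
  )
)

#' Configuration for the synthetic fixture generator
#'
#' Defaults mirror the layer sizes of the motivating SND study: 48
#' components, 61 candidate targets of which 25 are genuinely connected,
#' 44 pathway proteins and 13 metabolite biomarkers.
#'
#' @param n_components,n_targets,n_pathway_proteins,n_metabolites Layer
#'   sizes.
#' @param n_connected_targets How many targets are planted as true positives
#'   (component edge *and* metabolite path); the remaining targets are
#'   decoys with only one of the two.
#' @param dock_hit_rate,text_hit_rate Probability of an extra dock/text edge
#'   for each (component, connectable target) pair beyond the coverage
#'   backbone.
#' @param ppi_density Probability of a noise protein-protein edge per
#'   eligible pair.
#' @param confidence_range Range of the planted high-confidence PPI scores;
#'   must reach above 0.8 when connected targets are requested, since the
#'   planted paths have to survive the conventional confidence filter.
#' @param seed Integer seed; the bundle is a pure function of the config.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_components = 48, n_targets = 61,
                           n_pathway_proteins = 44, n_metabolites = 13,
                           n_connected_targets = 25,
                           dock_hit_rate = 0.08, text_hit_rate = 0.06,
                           ppi_density = 0.03,
                           confidence_range = c(0.85, 0.99),
                           seed = 1) {
  cfg <- list(
    n_components = as.integer(n_components),
    n_targets = as.integer(n_targets),
    n_pathway_proteins = as.integer(n_pathway_proteins),
    n_metabolites = as.integer(n_metabolites),
    n_connected_targets = as.integer(n_connected_targets),
    dock_hit_rate = dock_hit_rate,
    text_hit_rate = text_hit_rate,
    ppi_density = ppi_density,
    confidence_range = as.double(confidence_range),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_components < 1 || n_targets < 1) {
      abort("Need at least one component and one target.")
    }
    if (n_connected_targets < 0 || n_connected_targets > n_targets) {
      abort("n_connected_targets must lie in [0, n_targets].")
    }
    if (dock_hit_rate < 0 || dock_hit_rate > 1 || text_hit_rate < 0 || text_hit_rate > 1) {
      abort("Hit rates must lie in [0, 1].")
    }
    if (ppi_density <= 0 || ppi_density > 1) abort("ppi_density must lie in (0, 1].")
    if (length(confidence_range) != 2 || confidence_range[1] <= 0 ||
      confidence_range[2] > 1 || confidence_range[1] > confidence_range[2]) {
      abort("confidence_range must be an interval within (0, 1].")
    }
    if (n_connected_targets > 0) {
      if (n_metabolites == 0 || n_pathway_proteins == 0) {
        abort(paste0(
          "Infeasible config: connected targets require at least one ",
          "metabolite and one pathway protein."
        ))
      }
      if (confidence_range[2] <= 0.8) {
        abort(paste0(
          "Infeasible config: planted paths must survive the 0.8 confidence ",
          "filter, so confidence_range must reach above 0.8."
        ))
      }
    }
  })
  structure(cfg, class = "fixture_config")
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Builds every input table the pipeline consumes — component catalog, dock
#' score table (with per-protein positive-control scores), curated
#' text-mining edges, PPI edge list, metabolite-pathway enrichment table,
#' pathway membership table and a gene-term annotation table — such that
#' exactly `n_connected_targets` targets satisfy the prioritization
#' semantics (a component edge *and* a metabolite path through
#' high-confidence protein interactions). The remaining targets are decoys:
#' either they interact with components but cannot reach a metabolite, or
#' they sit on metabolite paths but no component touches them. Ground truth
#' is enforced constructively — decoy targets are only ever wired to other
#' decoys at high confidence, while sub-threshold "temptation" edges toward
#' the connected backbone exercise the confidence filter — and re-verified
#' by an internal reachability check before the bundle is returned.
#'
#' The bundle is deterministic for a fixed config (seed included): calling
#' the generator twice yields identical tables.
#'
#' @param config A [fixture_config()].
#' @return A `cpmi_fixture` list with elements `components`, `dock`,
#'   `text_edges`, `ppi`, `metabolite_pathways`, `memberships`,
#'   `annotations`, `truth` (the planted connected target ids) and
#'   `config`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(
    config$seed,
    generate_fixture_impl(config),
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

generate_fixture_impl <- function(cfg) {
  n_cmp <- cfg$n_components
  n_tgt <- cfg$n_targets
  n_pp <- cfg$n_pathway_proteins
  n_met <- cfg$n_metabolites

  # --- component catalog ------------------------------------------------
  classes <- sample(c("S", "J", "H", "Z"), n_cmp, replace = TRUE)
  serial <- stats::ave(seq_len(n_cmp), classes, FUN = seq_along)
  pool_idx <- sample(nrow(SYNTH_STRUCTURE_POOL), n_cmp, replace = TRUE)
  components <- tibble(
    id = paste0(classes, serial),
    name = paste0("Synthetic compound ", classes, serial),
    formula = SYNTH_STRUCTURE_POOL$formula[pool_idx],
    herb_class = classes,
    structure = SYNTH_STRUCTURE_POOL$structure[pool_idx]
  )

  targets <- sprintf("T%02d", seq_len(n_tgt))
  pathway_proteins <- if (n_pp > 0) sprintf("P%02d", seq_len(n_pp)) else character()
  metabolites <- if (n_met > 0) sprintf("M%02d", seq_len(n_met)) else character()

  connected <- sort(sample(targets, cfg$n_connected_targets))
  decoys <- setdiff(targets, connected)
  # decoy type A: component edge but no metabolite path; type B: the reverse
  decoy_a <- decoys[seq_along(decoys) %% 2 == 1]
  decoy_b <- setdiff(decoys, decoy_a)
  connectable <- sort(c(connected, decoy_a)) # targets that get component edges

  # --- component-target evidence ---------------------------------------
  # coverage backbone: every component touches some connectable target and
  # every connectable target is touched by some component
  base_pairs <- tibble(
    component_id = components$id,
    protein_id = sample(connectable, n_cmp, replace = TRUE)
  )
  base_pairs <- bind_rows(
    base_pairs,
    tibble(
      component_id = sample(components$id, length(connectable), replace = TRUE),
      protein_id = connectable
    )
  )
  all_pairs <- tidyr::expand_grid(
    component_id = components$id, protein_id = connectable
  )
  extra_dock <- all_pairs |> filter(runif(n()) < cfg$dock_hit_rate)
  extra_text <- all_pairs |> filter(runif(n()) < cfg$text_hit_rate)
  base_src <- sample(c("dock", "text"), nrow(base_pairs), replace = TRUE)
  dock_pairs <- distinct(bind_rows(base_pairs[base_src == "dock", ], extra_dock))
  text_pairs <- distinct(bind_rows(base_pairs[base_src == "text", ], extra_text))

  control <- tibble(
    protein_id = targets,
    positive_control_score = runif(n_tgt, 40, 60)
  )
  dock_hits <- dock_pairs |>
    left_join(control, by = "protein_id") |>
    mutate(score = positive_control_score + runif(n(), 1, 10))
  # failing records: docked but below the positive-control cutoff, drawn
  # from non-hit pairs over every target (decoy-B targets appear only here)
  miss_pool <- tidyr::expand_grid(
    component_id = components$id, protein_id = targets
  ) |>
    anti_join(dock_pairs, by = c("component_id", "protein_id"))
  dock_miss <- miss_pool |>
    slice_sample(n = min(nrow(dock_hits) * 2 + n_tgt, nrow(miss_pool))) |>
    left_join(control, by = "protein_id") |>
    mutate(score = positive_control_score - runif(n(), 1, 10))
  dock <- bind_rows(dock_hits, dock_miss) |>
    mutate(engine = "libdock") |>
    select(component_id, protein_id, engine, score, positive_control_score) |>
    arrange(component_id, protein_id)

  # --- metabolite pathway enrichment and membership ---------------------
  sig_pathways <- if (n_met > 0) sprintf("PW%02d", seq_len(n_met)) else character()
  metabolite_pathways <- tibble(
    metabolite = metabolites, pathway = sig_pathways,
    p = runif(n_met, 0.001, 0.049)
  )
  if (n_met > 0) {
    noise_pw <- tibble(
      metabolite = sample(metabolites, max(2, n_met %/% 3), replace = TRUE),
      pathway = sprintf("PW%02d", n_met + seq_len(max(2, n_met %/% 3))),
      p = runif(max(2, n_met %/% 3), 0.06, 0.9)
    )
    metabolite_pathways <- bind_rows(metabolite_pathways, noise_pw)
  }
  memberships <- tibble(pathway = character(), protein = character())
  if (n_met > 0 && n_pp > 0) {
    # round-robin so every pathway protein belongs to a significant pathway
    # and every significant pathway has at least one member
    memberships <- tibble(
      pathway = sig_pathways[(seq_len(n_pp) - 1L) %% n_met + 1L],
      protein = pathway_proteins
    )
    extra_mem <- tidyr::expand_grid(pathway = sig_pathways, protein = pathway_proteins) |>
      filter(runif(n()) < 0.05)
    noise_mem <- tibble(
      pathway = sample(setdiff(metabolite_pathways$pathway, sig_pathways), 2, replace = TRUE),
      protein = sample(pathway_proteins, 2, replace = TRUE)
    )
    memberships <- distinct(bind_rows(memberships, extra_mem, noise_mem)) |>
      arrange(pathway, protein)
  }

  # --- PPI --------------------------------------------------------------
  lo <- max(cfg$confidence_range[1], 0.801)
  hi <- cfg$confidence_range[2]
  hconf <- function(n) runif(n, lo, hi)
  ppi <- tibble(protein_a = character(), protein_b = character(), combined_score = double())
  if (n_pp > 0) {
    anchored_pool <- memberships$protein
    backbone_for <- function(tg) {
      tibble(
        protein_a = tg,
        protein_b = sample(anchored_pool, length(tg), replace = TRUE),
        combined_score = hconf(length(tg))
      )
    }
    ppi <- bind_rows(
      if (length(connected) > 0 && length(anchored_pool) > 0) backbone_for(connected),
      if (length(decoy_b) > 0 && length(anchored_pool) > 0) backbone_for(decoy_b)
    )
    # high-confidence noise only among nodes that may legitimately reach the
    # anchored set (connected/decoy-B targets and pathway proteins) ...
    safe <- c(connected, decoy_b, pathway_proteins)
    noise_pairs <- function(nodes) {
      if (length(nodes) < 2) {
        return(tibble(protein_a = character(), protein_b = character()))
      }
      tidyr::expand_grid(protein_a = nodes, protein_b = nodes) |>
        filter(protein_a < protein_b) |>
        filter(runif(n()) < cfg$ppi_density)
    }
    ppi <- bind_rows(
      ppi,
      noise_pairs(safe) |> mutate(combined_score = hconf(n())),
      # ... decoy-A targets may be wired, at high confidence, only to each
      # other, so they can never reach a metabolite
      noise_pairs(decoy_a) |> mutate(combined_score = hconf(n())),
      # sub-threshold temptation edges anywhere, including decoy-A to the
      # anchored backbone; the confidence filter must remove them
      noise_pairs(c(targets, pathway_proteins)) |>
        mutate(combined_score = runif(n(), 0.1, 0.8))
    ) |>
      filter(protein_a != protein_b) |>
      distinct(protein_a, protein_b, .keep_all = TRUE) |>
      arrange(protein_a, protein_b)
  }

  # --- annotations ------------------------------------------------------
  genes <- c(targets, pathway_proteins)
  terms <- tibble(
    term_id = sprintf("TERM%02d", 1:8),
    term_name = paste0("synthetic term ", 1:8),
    namespace = rep(c("process", "pathway", "function", "disease"), 2)
  )
  annotations <- terms |>
    mutate(gene = map(term_id, function(t) {
      sample(genes, min(length(genes), sample(3:max(3, length(genes) %/% 2), 1)))
    })) |>
    tidyr::unnest(gene) |>
    select(gene, term_id, term_name, namespace) |>
    arrange(term_id, gene)

  bundle <- structure(
    list(
      components = components,
      dock = dock,
      text_edges = text_pairs |> arrange(component_id, protein_id),
      ppi = ppi,
      metabolite_pathways = metabolite_pathways,
      memberships = memberships,
      annotations = annotations,
      truth = connected,
      config = cfg
    ),
    class = "cpmi_fixture"
  )
  check_fixture_truth(bundle)
  bundle
}

# Internal reachability check, independent of prioritize_targets(): verify
# that the planted truth is exactly the set of targets with a component edge
# that reach an anchored protein through >0.8 PPI edges.
check_fixture_truth <- function(bundle) {
  cfg <- bundle$config
  comp_targets <- unique(c(
    bundle$text_edges$protein_id,
    bundle$dock$protein_id[bundle$dock$score > bundle$dock$positive_control_score]
  ))
  sig <- bundle$metabolite_pathways$pathway[bundle$metabolite_pathways$p < 0.05]
  anchored <- unique(bundle$memberships$protein[bundle$memberships$pathway %in% sig])
  strong <- bundle$ppi |> filter(combined_score > 0.8)
  adj <- ppi_adjacency(strong |> rename(from = protein_a, to = protein_b))
  reaches <- function(v) {
    seen <- v
    queue <- v
    while (length(queue) > 0) {
      x <- queue[1]
      queue <- queue[-1]
      if (x %in% anchored) {
        return(TRUE)
      }
      nxt <- setdiff(adj[[x]] %||% character(), seen)
      seen <- c(seen, nxt)
      queue <- c(queue, nxt)
    }
    FALSE
  }
  realized <- sort(comp_targets[map_lgl(comp_targets, reaches)])
  if (!identical(realized, bundle$truth)) {
    abort(c(
      "Fixture self-consistency failure: realized connected set differs from planted truth.",
      paste0("planted: ", paste(bundle$truth, collapse = ", ")),
      paste0("realized: ", paste(realized, collapse = ", "))
    ))
  }
  invisible(bundle)
}

#' @export
print.cpmi_fixture <- function(x, ...) {
  cfg <- x$config
  cat(
    "<cpmi_fixture> ", cfg$n_components, " components, ", cfg$n_targets,
    " targets (", length(x$truth), " connected), ", cfg$n_pathway_proteins,
    " pathway proteins, ", cfg$n_metabolites, " metabolites (seed ",
    cfg$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Run the full network-analysis pipeline on an input bundle
#'
#' Convenience wrapper chaining the individual steps: dock-score cutoff
#' filtering and CTPI assembly, PPI confidence filtering, MPPI construction,
#' NATPI/CPMI integration and target prioritization.
#'
#' @param fixture A `cpmi_fixture` (or any list with the same table
#'   elements: `components`, `dock`, `text_edges`, `ppi`,
#'   `metabolite_pathways`, `memberships`).
#' @param orientation Engine score orientations for [apply_dock_cutoff()].
#' @param min_conf PPI confidence threshold (strict; default 0.8).
#' @param alpha Pathway enrichment threshold (strict; default 0.05).
#' @param neighbor_depth PPI hops for the MPPI extension (default 1).
#' @return A list with the intermediate layers (`ctpi`, `ppi`, `mppi`,
#'   `natpi`, `cpmi`) and the `prioritization` result.
#' @examples
#' \donttest{
#' fx <- generate_fixture(fixture_config(
#'   n_components = 6, n_targets = 5, n_pathway_proteins = 4,
#'   n_metabolites = 2, n_connected_targets = 2, seed = 42
#' ))
#' res <- run_network_analysis(fx)
#' tidy(res$prioritization)
#' }
#' @export
run_network_analysis <- function(fixture,
                                 orientation = c(libdock = "greater_better"),
                                 min_conf = 0.8, alpha = 0.05,
                                 neighbor_depth = 1) {
  dock_edges <- apply_dock_cutoff(fixture$dock, orientation)
  text_edges <- text_mining_edges(fixture$text_edges)
  ctpi <- merge_ctpi(dock_edges, text_edges, components = fixture$components)
  ppi <- filter_ppi(fixture$ppi, min_conf = min_conf)
  mppi <- build_mppi(
    fixture$metabolite_pathways, fixture$memberships, ppi,
    alpha = alpha, neighbor_depth = neighbor_depth
  )
  natpi <- build_natpi(ctpi, ppi)
  cpmi <- build_cpmi(natpi, mppi)
  list(
    ctpi = ctpi, ppi = ppi, mppi = mppi, natpi = natpi, cpmi = cpmi,
    prioritization = prioritize_targets(cpmi)
  )
}

#' Write a fixture bundle to a directory of TSV files
#'
#' Writes `components.tsv`, `dock.tsv`, `text_edges.tsv`, `ppi.tsv`,
#' `metabolite_pathways.tsv`, `memberships.tsv`, `annotations.tsv` and
#' `truth.txt` in the dialects the readers expect.
#'
#' @param fixture A `cpmi_fixture`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "cpmi_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c(
    "components", "dock", "text_edges", "ppi",
    "metabolite_pathways", "memberships", "annotations"
  )
  for (tb in tables) {
    readr::write_tsv(fixture[[tb]], file.path(dir, paste0(tb, ".tsv")))
  }
  writeLines(fixture$truth, file.path(dir, "truth.txt"))
  invisible(dir)
}
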