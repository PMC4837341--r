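test_that("dock cutoff is strict and orientation-aware", {
  recs <- tibble::tibble(
    component_id = c("c1", "c1", "c2"),
    protein_id = c("t1", "t2", "t3"),
    engine = c("libdock", "libdock", "vina"),
    score = c(62, 55, -9.1),
    positive_control_score = c(55, 55, -8.0)
  )
  edges <- apply_dock_cutoff(
    recs,
    orientation = c(libdock = "greater_better", vina = "lesser_better")
  )
  # 62 > 55 passes; 55 == 55 fails the strict comparison; -9.1 beats -8.0
  # for a minimizing engine
  expect_setequal(edges$to, c("t1", "t3"))
  expect_false("t2" %in% edges$to)
  expect_true(all(purrr::map_lgl(edges$provenance, identical, "dock")))

  # a tolerance for coarse score grids shrinks the accepted margin
  edges_tol <- apply_dock_cutoff(
    recs,
    orientation = c(libdock = "greater_better", vina = "lesser_better"),
    tolerance = 2
  )
  expect_setequal(edges_tol$to, "t1")
})

test_that("dock cutoff validates controls and engine orientations", {
  recs <- tibble::tibble(
    component_id = "c1", protein_id = "t1", engine = "libdock",
    score = 50, positive_control_score = NA_real_
  )
  expect_error(
    apply_dock_cutoff(recs, c(libdock = "greater_better")),
    "t1"
  )
  recs$positive_control_score <- 40
  expect_error(apply_dock_cutoff(recs, c(vina = "lesser_better")), "libdock")
})

test_that("dock cutoff output is invariant under order-preserving rescaling", {
  set.seed(11)
  recs <- tibble::tibble(
    component_id = paste0("c", 1:20),
    protein_id = sample(paste0("t", 1:5), 20, replace = TRUE),
    engine = "libdock",
    score = runif(20, 30, 70),
    positive_control_score = 50
  )
  orient <- c(libdock = "greater_better")
  base <- apply_dock_cutoff(recs, orient)
  rescaled <- recs |>
    dplyr::mutate(
      score = 3.7 * score + 12,
      positive_control_score = 3.7 * positive_control_score + 12
    )
  expect_equal(apply_dock_cutoff(rescaled, orient), base)
})

test_that("CTPI merge unions provenance and assigns roles", {
  dock <- apply_dock_cutoff(
    tibble::tibble(
      component_id = c("c1", "c2"), protein_id = c("t1", "t2"),
      engine = "libdock", score = 60, positive_control_score = 50
    ),
    c(libdock = "greater_better")
  )
  text <- text_mining_edges(tibble::tibble(
    component_id = c("c1", "c1", "c3"), protein_id = c("t1", "t1", "t3")
  ))
  ctpi <- merge_ctpi(dock, text)
  validate_network(ctpi)
  # c1-t1 supported by both sources collapses to one edge
  e11 <- ctpi$edges |> dplyr::filter(from == "c1", to == "t1")
  expect_equal(nrow(e11), 1)
  expect_equal(e11$provenance[[1]], c("dock", "text"))
  # within-source duplicates deduplicate
  expect_equal(nrow(ctpi$edges), 3)
  # disjoint layers: node count is the sum of the distinct id counts
  expect_equal(nrow(ctpi$nodes), 3 + 3)
  expect_setequal(nodes_with_role(ctpi, "component"), c("c1", "c2", "c3"))
  expect_setequal(nodes_with_role(ctpi, "target"), c("t1", "t2", "t3"))

  # merge is commutative and idempotent in its edge lists
  expect_equal(merge_ctpi(text, dock), ctpi)
  expect_equal(merge_ctpi(dplyr::bind_rows(dock, dock), text), ctpi)

  # unknown component ids are kept but flagged
  expect_warning(
    merge_ctpi(dock, text, components = tibble::tibble(id = c("c1", "c2"))),
    "c3"
  )
})

test_that("PPI filtering is strict at the threshold and auto-detects scale", {
  edges <- tibble::tibble(
    protein_a = c("a", "b", "c"), protein_b = c("b", "c", "d"),
    combined_score = c(0.9, 0.8, 0.2)
  )
  net <- filter_ppi(edges)
  expect_equal(nrow(net$edges), 1) # 0.9 kept; 0.8 dropped (strict); 0.2 dropped
  expect_setequal(net$nodes$node, c("a", "b"))

  # STRING-style 0-1000 scores are detected and rescaled
  expect_message(
    net1000 <- filter_ppi(edges |> dplyr::mutate(combined_score = combined_score * 1000)),
    "1000"
  )
  expect_equal(net1000$edges$confidence, 0.9)

  expect_equal(filter_ppi(edges[0, ]), empty_network())
  expect_error(
    filter_ppi(tibble::tibble(protein_a = "a", protein_b = "b", combined_score = 0)),
    "\\(0, 1\\]"
  )
})

test_that("MPPI keeps strictly significant pathways and extends by one hop", {
  mp <- tibble::tibble(
    metabolite = c("m1", "m2", "m3"),
    pathway = c("pw1", "pw2", "pw3"),
    p = c(0.04, 0.05, 0.2)
  )
  mem <- tibble::tibble(
    pathway = c("pw1", "pw2", "pw3"),
    protein = c("A", "B", "C")
  )
  ppi <- filter_ppi(tibble::tibble(
    protein_a = c("A", "E"), protein_b = c("E", "F"),
    combined_score = c(0.95, 0.9)
  ))
  mppi <- build_mppi(mp, mem, ppi)
  validate_network(mppi)
  # p = 0.04 survives; p = 0.05 and 0.2 are excluded (strict)
  expect_setequal(nodes_with_role(mppi, "metabolite"), "m1")
  # direct member edge m1-A plus the 1-hop neighbor E of A
  expect_true(nrow(dplyr::filter(mppi$edges, from == "A", to == "m1")) == 1)
  expect_true("E" %in% nodes_with_role(mppi, "pathway_protein"))
  # F is 2 hops from the member A and must not enter at depth 1
  expect_false("F" %in% mppi$nodes$node)
  # depth 2 pulls it in
  mppi2 <- build_mppi(mp, mem, ppi, neighbor_depth = 2)
  expect_true("F" %in% mppi2$nodes$node)

  # enriched pathway without membership rows: warn and skip
  expect_warning(
    skipped <- build_mppi(
      tibble::tibble(metabolite = "m9", pathway = "pwX", p = 0.01),
      mem, ppi
    ),
    "pwX"
  )
  expect_equal(skipped, empty_network())
  expect_error(
    build_mppi(dplyr::mutate(mp, p = c(0.04, 1.2, 0.2)), mem, ppi),
    "\\[0, 1\\]"
  )
})

test_that("threshold filters are monotone in their thresholds", {
  set.seed(21)
  edges <- tibble::tibble(
    protein_a = sample(paste0("p", 1:15), 60, replace = TRUE),
    protein_b = sample(paste0("p", 1:15), 60, replace = TRUE),
    combined_score = runif(60, 0.01, 1)
  ) |> dplyr::filter(protein_a != protein_b)
  confs <- c(0.2, 0.5, 0.8, 0.95)
  sizes <- purrr::map_int(confs, function(mc) nrow(filter_ppi(edges, min_conf = mc)$edges))
  expect_true(all(diff(sizes) <= 0))

  mp <- tibble::tibble(
    metabolite = sample(paste0("m", 1:4), 12, replace = TRUE),
    pathway = paste0("pw", 1:12),
    p = runif(12)
  )
  mem <- tibble::tibble(
    pathway = sample(paste0("pw", 1:12), 30, replace = TRUE),
    protein = sample(paste0("p", 1:15), 30, replace = TRUE)
  ) |> dplyr::distinct()
  ppi <- filter_ppi(edges, min_conf = 0.8)
  alphas <- c(0.8, 0.4, 0.1, 0.02)
  nodes_n <- purrr::map_int(alphas, function(a) {
    nrow(suppressWarnings(build_mppi(mp, mem, ppi, alpha = a))$nodes)
  })
  expect_true(all(diff(nodes_n) <= 0))
})
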