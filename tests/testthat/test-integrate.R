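test_that("disjoint four-layer union has additive node counts", {
  comps <- setNames(rep("component", 48), paste0("c", 1:48))
  tgts <- setNames(rep("target", 25), paste0("t", 1:25))
  pps <- setNames(rep("pathway_protein", 44), paste0("p", 1:44))
  mets <- setNames(rep("metabolite", 13), paste0("m", 1:13))
  a <- quick_net(c(comps, tgts), ct = list("c1", "t1"))
  b <- quick_net(c(pps, mets), pm = list("p1", "m1"))
  u <- union_networks(a, b)
  expect_equal(network_stats(u)$n_nodes, 130)
})

test_that("prioritization retains exactly the component-to-metabolite connectors", {
  # c1 - t1 - p1 - m1 chain retains t1; t2 touches c1 but dead-ends
  net <- quick_net(
    c(
      c1 = "component", t1 = "target", t2 = "target",
      p1 = "pathway_protein", m1 = "metabolite"
    ),
    ct = list(c("c1", "c1"), c("t1", "t2")),
    pp = list("t1", "p1"),
    pm = list("p1", "m1")
  )
  pr <- prioritize_targets(net)
  expect_equal(pr$retained$target, "t1")
  expect_equal(pr$evidence$t1$components, "c1")
  expect_equal(pr$evidence$t1$witness_path, c("t1", "p1", "m1"))

  # no pathway-metabolite edges anywhere: nothing is retained
  net2 <- quick_net(
    c(
      c1 = "component", t1 = "target", p1 = "pathway_protein",
      m1 = "metabolite"
    ),
    ct = list("c1", "t1"), pp = list("t1", "p1")
  )
  expect_equal(nrow(prioritize_targets(net2)$retained), 0)

  # dual-role target with a direct metabolite edge: length-1 witness path
  net3 <- quick_net(
    c(
      c1 = "component", t3 = "target+pathway_protein",
      p0 = "pathway_protein", m1 = "metabolite"
    ),
    ct = list("c1", "t3"), pm = list("t3", "m1")
  )
  pr3 <- prioritize_targets(net3)
  expect_equal(pr3$retained$target, "t3")
  expect_equal(pr3$evidence$t3$witness_path, c("t3", "m1"))
})

test_that("prioritization requires all four roles and orders deterministically", {
  net <- quick_net(
    c(c1 = "component", t1 = "target", p1 = "pathway_protein"),
    ct = list("c1", "t1")
  )
  expect_error(prioritize_targets(net), "metabolite")

  # ordering: descending component degree, ties lexicographic
  net2 <- quick_net(
    c(
      c1 = "component", c2 = "component",
      tb = "target", ta = "target", tz = "target",
      p1 = "pathway_protein", m1 = "metabolite"
    ),
    ct = list(c("c1", "c2", "c1", "c1"), c("tb", "tb", "ta", "tz")),
    pp = list(c("tb", "ta", "tz"), c("p1", "p1", "p1")),
    pm = list("p1", "m1")
  )
  pr <- prioritize_targets(net2)
  expect_equal(pr$retained$target, c("tb", "ta", "tz"))
  expect_equal(pr$retained$component_degree, c(2L, 1L, 1L))
  td <- tidy(pr)
  expect_equal(td$witness_path[1], "tb -> p1 -> m1")
  gl <- glance(pr)
  expect_equal(gl$n_retained, 3L)
  expect_equal(gl$n_component, 2L)
})

test_that("prioritization agrees with the brute-force simple-path oracle", {
  set.seed(77)
  for (i in 1:60) {
    net <- random_layered_net(
      n_comp = sample(2:4, 1), n_tgt = sample(3:8, 1),
      n_pp = sample(3:8, 1), n_met = sample(1:3, 1)
    )
    pr <- prioritize_targets(net)
    expect_equal(sort(pr$retained$target), oracle_retained(net))
  }
})

test_that("prioritization is monotone in evidence and relabel-invariant", {
  set.seed(88)
  for (i in 1:20) {
    net <- random_layered_net()
    base <- sort(prioritize_targets(net)$retained$target)

    # adding a protein-protein edge never removes a retained target
    prot <- sort(union(
      nodes_with_role(net, "target"), nodes_with_role(net, "pathway_protein")
    ))
    pair <- sample(prot, 2)
    aug <- cpmi_network(
      nodes = net$nodes,
      edges = dplyr::bind_rows(net$edges, tibble::tibble(
        from = pair[1], to = pair[2], edge_type = "protein-protein",
        provenance = list("curated"), confidence = 0.95
      ))
    )
    expect_true(all(base %in% prioritize_targets(aug)$retained$target))

    # relabeling nodes relabels the retained set and nothing else
    perm <- setNames(paste0("N", sample(nrow(net$nodes))), net$nodes$node)
    relab <- cpmi_network(
      nodes = dplyr::mutate(net$nodes, node = unname(perm[node])),
      edges = dplyr::mutate(net$edges,
        from = unname(perm[from]), to = unname(perm[to])
      )
    )
    expect_equal(
      sort(unname(perm[base])),
      sort(prioritize_targets(relab)$retained$target)
    )
  }
})

test_that("deleting a metabolite node never adds a retained target", {
  set.seed(99)
  for (i in 1:10) {
    net <- random_layered_net(n_met = 2)
    base <- prioritize_targets(net)$retained$target
    drop <- nodes_with_role(net, "metabolite")[1]
    smaller <- cpmi_network(
      nodes = dplyr::filter(net$nodes, node != drop),
      edges = dplyr::filter(net$edges, from != drop, to != drop)
    )
    res <- tryCatch(
      prioritize_targets(smaller)$retained$target,
      error = function(e) character() # all metabolites gone
    )
    expect_true(all(res %in% base))
  }
})

test_that("degree stratification maps the documented boundaries", {
  mk_ct <- function(deg, tgt) {
    list(paste0("c", seq_len(deg)), rep(tgt, deg))
  }
  comps <- setNames(rep("component", 41), paste0("c", 1:41))
  net <- quick_net(
    c(comps,
      t_high = "target", t_mid = "target", t_low = "target",
      t_iso = "target"
    ),
    ct = list(
      c(paste0("c", 1:20), paste0("c", 1:19), "c1"),
      c(rep("t_high", 20), rep("t_mid", 19), "t_low")
    )
  )
  expect_warning(strata <- degree_stratify(net), "t_iso")
  got <- setNames(as.character(strata$stratum), strata$target)
  expect_equal(got[["t_high"]], "high") # degree 20
  expect_equal(got[["t_mid"]], "middle") # degree 19
  expect_equal(got[["t_low"]], "low") # degree 1
  expect_false("t_iso" %in% strata$target)

  # partition: every non-isolated target lands in exactly one stratum
  set.seed(31)
  for (i in 1:10) {
    rnet <- random_layered_net(n_comp = 25, n_tgt = 6, p_ct = 0.6)
    st <- suppressWarnings(degree_stratify(rnet))
    expect_equal(anyDuplicated(st$target), 0)
    expect_true(all(!is.na(st$stratum)))
    expect_true(all(st$degree >= 1))
  }

  # degrees above the observed 20-41 range still map to "high"
  big <- quick_net(
    c(
      setNames(rep("component", 50), paste0("c", 1:50)),
      tx = "target"
    ),
    ct = list(paste0("c", 1:50), rep("tx", 50))
  )
  expect_equal(as.character(degree_stratify(big)$stratum), "high")
})
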