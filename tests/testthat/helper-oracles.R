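# Shared fixtures and independent oracles used across the test files.

# compact builder for small layered networks:
#   roles: named character vector, e.g. c(c1 = "component", t1 = "target");
#   multi-role nodes use "+" separators ("target+pathway_protein")
quick_net <- function(roles, ct = NULL, pp = NULL, pm = NULL) {
  nodes <- tibble::tibble(
    node = names(roles),
    roles = strsplit(unname(roles), "+", fixed = TRUE)
  )
  edges <- dplyr::bind_rows(
    if (!is.null(ct)) {
      tibble::tibble(
        from = ct[[1]], to = ct[[2]], edge_type = "component-target",
        provenance = rep(list("text"), length(ct[[1]])), confidence = NA_real_
      )
    },
    if (!is.null(pp)) {
      tibble::tibble(
        from = pp[[1]], to = pp[[2]], edge_type = "protein-protein",
        provenance = rep(list("curated"), length(pp[[1]])),
        confidence = if (length(pp) >= 3) pp[[3]] else 0.9
      )
    },
    if (!is.null(pm)) {
      tibble::tibble(
        from = pm[[1]], to = pm[[2]], edge_type = "pathway-metabolite",
        provenance = rep(list("curated"), length(pm[[1]])), confidence = NA_real_
      )
    }
  )
  cpmi_network(nodes = nodes, edges = edges)
}

# Brute-force prioritization oracle: enumerate ALL simple paths from each
# component-linked target over protein-protein edges among target /
# pathway_protein nodes, and retain the target iff some enumerated path ends
# at a protein with a pathway-metabolite edge. Deliberately independent of
# the BFS-reachability implementation.
oracle_retained <- function(net) {
  role_of <- setNames(net$nodes$roles, net$nodes$node)
  has_role <- function(v, r) r %in% role_of[[v]]
  all_nodes <- net$nodes$node
  targets <- all_nodes[vapply(all_nodes, has_role, TRUE, r = "target")]
  proteins <- all_nodes[vapply(
    all_nodes,
    function(v) has_role(v, "target") || has_role(v, "pathway_protein"), TRUE
  )]
  mets <- all_nodes[vapply(all_nodes, has_role, TRUE, r = "metabolite")]

  e <- net$edges
  ct <- e[e$edge_type == "component-target", ]
  touched <- unique(c(
    ct$to[ct$to %in% targets], ct$from[ct$from %in% targets]
  ))
  pp <- e[e$edge_type == "protein-protein" & e$from %in% proteins & e$to %in% proteins, ]
  nbr <- function(v) unique(c(pp$to[pp$from == v], pp$from[pp$to == v]))
  pm <- e[e$edge_type == "pathway-metabolite", ]
  anchored <- unique(c(
    pm$from[pm$from %in% proteins & pm$to %in% mets],
    pm$to[pm$to %in% proteins & pm$from %in% mets]
  ))

  reaches_by_path <- function(t0) {
    found <- FALSE
    dfs <- function(v, visited) {
      if (found) {
        return(invisible(NULL))
      }
      if (v %in% anchored) {
        found <<- TRUE
        return(invisible(NULL))
      }
      for (w in setdiff(nbr(v), visited)) dfs(w, c(visited, w))
    }
    dfs(t0, t0)
    found
  }
  sort(touched[vapply(touched, reaches_by_path, TRUE)])
}

# Random layered network generator for property tests (valid by
# construction; sizes kept small so path enumeration stays cheap).
random_layered_net <- function(n_comp = 3, n_tgt = 6, n_pp = 6, n_met = 2,
                               p_ct = 0.3, p_pp = 0.15, p_pm = 0.25) {
  comps <- paste0("c", seq_len(n_comp))
  tgts <- paste0("t", seq_len(n_tgt))
  pps <- paste0("p", seq_len(n_pp))
  mets <- paste0("m", seq_len(n_met))
  roles <- c(
    setNames(rep("component", n_comp), comps),
    setNames(rep("target", n_tgt), tgts),
    setNames(rep("pathway_protein", n_pp), pps),
    setNames(rep("metabolite", n_met), mets)
  )
  # occasionally give a target the dual target+pathway_protein role
  if (stats::runif(1) < 0.3) {
    dual <- sample(tgts, 1)
    roles[dual] <- "target+pathway_protein"
  }
  pick_pairs <- function(a, b, p) {
    g <- expand.grid(x = a, y = b, stringsAsFactors = FALSE)
    g <- g[g$x != g$y, , drop = FALSE]
    g[stats::runif(nrow(g)) < p, , drop = FALSE]
  }
  ct <- pick_pairs(comps, tgts, p_ct)
  prot <- c(tgts, pps)
  pp <- pick_pairs(prot, prot, p_pp / 2)
  pp <- pp[pp$x < pp$y, , drop = FALSE]
  pm <- pick_pairs(c(pps, tgts), mets, p_pm)
  quick_net(
    roles,
    ct = if (nrow(ct) > 0) list(ct$x, ct$y),
    pp = if (nrow(pp) > 0) list(pp$x, pp$y, stats::runif(nrow(pp), 0.81, 0.99)),
    pm = if (nrow(pm) > 0) list(pm$x, pm$y)
  )
}

# Exact upper-tail hypergeometric probability by direct combinatorial
# summation (oracle for phyper-based enrichment).
oracle_hyper_p <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (k > min(K, n)) {
    return(0)
  }
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# KS statistic by direct ECDF enumeration on the pooled support.
oracle_ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x), 0)))
}
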