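# Chemical-space computations: physicochemical descriptors, descriptor-space
# PCA, drug-likeness distribution comparison, and Tanimoto similarity
# screening. Structure handling is delegated to ChemmineR/Open Babel.

DESCRIPTOR_COLS <- c(
  "mw", "n_aromatic_rings", "n_hbd", "n_hba", "psa", "n_rotatable", "alogp"
)

# Parse SMILES one at a time so failures can be attributed to a record.
# Returns list(mols = named list of Open Babel molecule handles, ok = ids,
# problems = tibble(id, structure, error)).
parse_structures <- function(structures) {
  ids <- names(structures) %||% as.character(seq_along(structures))
  if (anyDuplicated(ids)) abort("Structure ids must be unique.")
  problems <- list()
  mols <- list()
  for (i in seq_along(structures)) {
    smi <- structures[[i]]
    res <- tryCatch(
      ChemmineOB::forEachMol("SMILES", smi, identity),
      error = function(e) structure(conditionMessage(e), class = "parse_failure")
    )
    if (inherits(res, "parse_failure")) {
      problems[[length(problems) + 1]] <- tibble(
        id = ids[i], structure = smi, error = unclass(res)
      )
    } else {
      mols[[ids[i]]] <- res
    }
  }
  list(
    mols = mols,
    ok = names(mols),
    problems = if (length(problems) == 0) {
      tibble(id = character(), structure = character(), error = character())
    } else {
      bind_rows(problems)
    }
  )
}

# Aromatic ring count via ChemmineR ring perception; molecules without bonds
# (e.g. water) cannot be represented as SDF blocks and trivially have none.
aromatic_ring_count <- function(smi, id) {
  tryCatch(
    {
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smi, id)))
      rc <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
      as.integer(if (is.matrix(rc)) rc[1, "AROMATIC"] else rc[["AROMATIC"]])
    },
    error = function(e) 0L
  )
}

ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

# accept a catalog data frame (id, structure) or a (named) character vector
as_structure_vector <- function(x, what = "structures") {
  if (is.data.frame(x)) {
    x <- as_tibble(x)
    if (!all(c("id", "structure") %in% names(x))) {
      abort(paste0("`", what, "` must have columns `id` and `structure`."))
    }
    setNames(as.character(x$structure), as.character(x$id))
  } else {
    setNames(as.character(x), names(x) %||% as.character(seq_along(x)))
  }
}

#' Physicochemical descriptors from line-notation structures
#'
#' Computes the seven descriptors conventionally used for drug-likeness and
#' chemical-space analysis: molecular weight, number of aromatic rings,
#' hydrogen bond donors and acceptors (N + O definition), topological polar
#' surface area, rotatable bonds (non-terminal, non-ring single bonds
#' excluding triple-bond neighbors), and the Open Babel logP (reported in
#' the `alogp` column; octanol-water partition parameterizations differ
#' across toolkits, so the toolkit of record is part of the result's
#' meaning). Computation is pure: identical input gives bit-identical
#' output.
#'
#' Components with a missing/empty structure are skipped with a warning and
#' absent from the result; an unparseable structure is an error naming the
#' offending input.
#'
#' @param structures A (named) character vector of SMILES, or a component
#'   catalog data frame with columns `id` and `structure`.
#' @return A tibble with columns `id`, `mw`, `n_aromatic_rings`, `n_hbd`,
#'   `n_hba`, `psa`, `n_rotatable`, `alogp`, one row per structure in input
#'   order (minus skipped blanks).
#' @examples
#' \donttest{
#' compute_descriptors(c(benzene = "c1ccccc1", ethanol = "CCO"))
#' }
#' @export
compute_descriptors <- function(structures) {
  structures <- as_structure_vector(structures)
  blank <- is.na(structures) | !nzchar(trimws(structures))
  if (any(blank)) {
    warn(paste0(
      "Skipping ", sum(blank), " component(s) without a structure: ",
      paste(names(structures)[blank], collapse = ", ")
    ))
    structures <- structures[!blank]
  }
  if (length(structures) == 0) {
    return(tibble(id = character()) |>
      bind_cols(as_tibble(setNames(rep(list(double()), 7), DESCRIPTOR_COLS))))
  }
  parsed <- parse_structures(structures)
  if (nrow(parsed$problems) > 0) {
    abort(c(
      "Unparseable structure(s):",
      paste0(parsed$problems$id, ": \"", parsed$problems$structure, "\"")
    ))
  }
  rows <- map2(parsed$mols, names(parsed$mols), function(mol, id) {
    props <- ChemmineOB::prop_OB(mol)
    # rotatable bonds: acyclic single bonds between non-terminal heavy
    # atoms, excluding bonds adjacent to a triple bond
    rotors <- ChemmineOB::smartsSearch_OB(mol, ROTATABLE_SMARTS, uniqueMatches = TRUE)
    tibble(
      id = id,
      mw = as.double(props$MW),
      n_aromatic_rings = aromatic_ring_count(structures[[id]], id),
      n_hbd = as.integer(props$HBD),
      n_hba = as.integer(props$HBA2),
      psa = as.double(props$TPSA),
      n_rotatable = as.integer(rotors),
      alogp = as.double(props$logP)
    )
  })
  bind_rows(rows)
}

#' Chemical-space principal component analysis
#'
#' PCA of a descriptor table for chemical-space visualization. Columns are
#' centered and (by default) scaled to unit variance, since the descriptors
#' have incommensurate units; zero-variance columns are centered but left
#' unscaled. Missing values are rejected with a row/column report rather
#' than silently imputed. Each loading vector is oriented so that its
#' largest-magnitude entry is positive, making signs reproducible across
#' platforms.
#'
#' @param data A data frame containing the descriptor columns; non-numeric
#'   columns (e.g. `id`, a set label) are carried through to the scores
#'   table unchanged.
#' @param scale Scale columns to unit variance (default `TRUE`).
#' @return A `chemspace_pca` object with `scores` (tibble: metadata columns
#'   plus `PC1..PCk`), `loadings` (tibble: `descriptor` plus `PC1..PCk`),
#'   and `explained_variance` (fractions summing to 1, non-increasing).
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
pca_chemspace <- function(data, scale = TRUE) {
  data <- as_tibble(data)
  numeric_cols <- names(data)[map_lgl(data, is.numeric)]
  if (length(numeric_cols) < 2) abort("Need at least 2 numeric descriptor columns.")
  meta <- data[setdiff(names(data), numeric_cols)]
  x <- as.matrix(data[numeric_cols])
  if (nrow(x) < 2) abort("Need at least 2 observations.")
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)
    abort(c(
      "Missing values are not allowed (no silent imputation):",
      paste0("row ", idx[, 1], ", column ", numeric_cols[idx[, 2]])[seq_len(min(10, nrow(idx)))]
    ))
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sds <- apply(xc, 2, stats::sd)
  scl <- rep(1, ncol(x))
  if (scale) scl <- ifelse(sds > 0, sds, 1)
  xs <- sweep(xc, 2, scl, "/")

  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)

  structure(
    list(
      scores = bind_cols(meta, as_tibble(scores)),
      loadings = bind_cols(tibble(descriptor = numeric_cols), as_tibble(rot)),
      explained_variance = ev,
      sdev = pc$sdev,
      center = ctr,
      scale = scl,
      scaled = scale
    ),
    class = "chemspace_pca"
  )
}

#' @export
print.chemspace_pca <- function(x, ...) {
  cat(
    "<chemspace_pca> ", nrow(x$scores), " observations, ",
    nrow(x$loadings), " descriptors\n", sep = ""
  )
  cat(
    "  explained variance: ",
    paste0(sprintf("PC%d %.1f%%", seq_along(x$explained_variance), 100 * x$explained_variance),
      collapse = ", "
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn pca_chemspace Eigenvalue table: one row per component with
#'   its standard deviation, explained-variance fraction and cumulative
#'   fraction.
#' @param x A `chemspace_pca`.
#' @param ... Unused.
#' @export
tidy.chemspace_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$explained_variance),
    std_dev = x$sdev,
    variance_fraction = x$explained_variance,
    cumulative = cumsum(x$explained_variance)
  )
}

#' @describeIn pca_chemspace One-row summary: observation/descriptor counts
#'   and variance captured by the first two components.
#' @export
glance.chemspace_pca <- function(x, ...) {
  tibble(
    n_obs = nrow(x$scores),
    n_descriptors = nrow(x$loadings),
    var_pc1 = x$explained_variance[1],
    var_pc12 = sum(x$explained_variance[seq_len(min(2, length(x$explained_variance)))])
  )
}

#' @describeIn pca_chemspace Score plot on the first two components,
#'   colored by `group` when given.
#' @param object A `chemspace_pca`.
#' @param group Optional name of a metadata column of the scores table to
#'   color points by.
#' @export
autoplot.chemspace_pca <- function(object, group = NULL, ...) {
  pct <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * object$explained_variance[i])
  p <- ggplot2::ggplot(
    object$scores,
    ggplot2::aes(PC1, PC2, color = if (is.null(group)) NULL else .data[[group]])
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = pct(1), y = pct(2), color = group, title = "Chemical space")
  p
}

#' Compare drug-likeness descriptor distributions between two compound sets
#'
#' For every shared numeric descriptor column, runs the two-sided two-sample
#' Kolmogorov-Smirnov test (difference in distribution shape) and the
#' two-sided Wilcoxon rank-sum (Mann-Whitney) test (difference in location).
#' The rank-sum variant is used because the two sets (e.g. herbal components
#' vs approved oral drugs) are independent samples, not pairs. Exact
#' p-values are used for small samples without ties, the standard asymptotic
#' approximations otherwise.
#'
#' @param set_a,set_b Descriptor tables (data frames with shared numeric
#'   columns, e.g. from [compute_descriptors()]); each needs at least 3
#'   rows.
#' @return A tibble with one row per descriptor: `descriptor`,
#'   `ks_statistic`, `ks_p`, `ranksum_statistic`, `ranksum_p`.
#' @export
compare_druglikeness <- function(set_a, set_b) {
  set_a <- as_tibble(set_a)
  set_b <- as_tibble(set_b)
  if (nrow(set_a) < 3 || nrow(set_b) < 3) {
    abort("Insufficient data: each set needs at least 3 observations.")
  }
  shared <- intersect(
    names(set_a)[map_lgl(set_a, is.numeric)],
    names(set_b)[map_lgl(set_b, is.numeric)]
  )
  if (length(shared) == 0) abort("No shared numeric descriptor columns.")
  map(shared, function(col) {
    a <- set_a[[col]]
    b <- set_b[[col]]
    ks <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
    w <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    tibble(
      descriptor = col,
      ks_statistic = unname(ks$statistic),
      ks_p = ks$p.value,
      ranksum_statistic = unname(w$statistic),
      ranksum_p = w$p.value
    )
  }) |> bind_rows()
}

#' Tanimoto similarity of bit fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} between fingerprint rows of `a` and `b`.
#' Symmetric, 1 for identical non-empty fingerprints, 0 for disjoint ones;
#' the degenerate case of two all-zero fingerprints is defined as 0.
#'
#' @param a,b Logical (or 0/1) matrices with one fingerprint per row and a
#'   common number of bit columns; vectors are treated as single rows.
#' @return A `nrow(a)` by `nrow(b)` matrix of similarities.
#' @export
tanimoto_similarity <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  if (is.vector(b)) b <- matrix(b, nrow = 1)
  storage.mode(a) <- "double"
  storage.mode(b) <- "double"
  if (ncol(a) != ncol(b)) abort("Fingerprints must have the same number of bits.")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    abort("Fingerprints must be binary.")
  }
  inter <- a %*% t(b)
  uni <- outer(rowSums(a), rowSums(b), "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  dimnames(out) <- list(rownames(a), rownames(b))
  out
}

#' Screen a compound catalog against a structure library by similarity
#'
#' Computes fingerprint Tanimoto similarity between every query and every
#' library structure and retains the pairs at or above the threshold
#' (inclusive: a similarity of exactly the threshold is kept). The default
#' fingerprint is the circular ECFP4 (radius 2); pre-computed binary
#' fingerprint matrices can be supplied instead, which also allows other
#' fingerprint families.
#'
#' Unparseable structures do not abort the screen: each failure is collected
#' into a report (attribute `"problems"`, also raised as a warning) and the
#' remaining records are processed.
#'
#' @param queries Component catalog (data frame with `id`, `structure`) or
#'   named character vector of SMILES.
#' @param library Structure library in the same forms.
#' @param threshold Minimum Tanimoto similarity to retain, in (0, 1];
#'   default 0.85.
#' @param fp_type Open Babel fingerprint name (default `"ECFP4"`).
#' @param query_fps,library_fps Optional pre-computed binary fingerprint
#'   matrices (rows named by id) overriding structure parsing.
#' @return A tibble of matches `query_id`, `library_id`, `tanimoto`, sorted
#'   by descending similarity, ties broken by (query_id, library_id);
#'   attribute `"problems"` holds the per-record parse failures.
#' @export
tanimoto_screen <- function(queries, library, threshold = 0.85,
                            fp_type = "ECFP4",
                            query_fps = NULL, library_fps = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0, threshold <= 1)
  problems <- tibble(id = character(), structure = character(), error = character())
  fps_for <- function(x, precomputed, what) {
    if (!is.null(precomputed)) {
      if (is.null(rownames(precomputed))) abort("Pre-computed fingerprints need rownames.")
      return(precomputed)
    }
    smi <- as_structure_vector(x, what)
    blank <- is.na(smi) | !nzchar(trimws(smi))
    if (any(blank)) {
      problems <<- bind_rows(problems, tibble(
        id = names(smi)[blank], structure = smi[blank], error = "missing structure"
      ))
      smi <- smi[!blank]
    }
    parsed <- parse_structures(smi)
    problems <<- bind_rows(problems, parsed$problems)
    if (length(parsed$ok) == 0) {
      return(NULL)
    }
    fpm <- do.call(rbind, map(parsed$mols, function(m) {
      as.numeric(ChemmineOB::fingerprint_OB(m, fp_type))
    }))
    rownames(fpm) <- parsed$ok
    fpm
  }
  qf <- fps_for(queries, query_fps, "queries")
  lf <- fps_for(library, library_fps, "library")
  if (nrow(problems) > 0) {
    warn(paste0(
      nrow(problems), " structure(s) could not be screened: ",
      paste(problems$id, collapse = ", ")
    ))
  }
  if (is.null(qf) || is.null(lf)) {
    out <- tibble(query_id = character(), library_id = character(), tanimoto = double())
    attr(out, "problems") <- problems
    return(out)
  }
  sim <- tanimoto_similarity(qf, lf)
  out <- as_tibble(sim, rownames = "query_id") |>
    tidyr::pivot_longer(-query_id, names_to = "library_id", values_to = "tanimoto") |>
    filter(tanimoto >= threshold) |>
    arrange(desc(tanimoto), query_id, library_id)
  attr(out, "problems") <- problems
  out
}
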