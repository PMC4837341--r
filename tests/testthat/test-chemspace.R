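# standard atomic weights, used as an independent molar-mass oracle
ATOMIC_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)

formula_mw <- function(formula) {
  counts <- parse_formula(formula)
  sum(ATOMIC_WEIGHTS[names(counts)] * counts)
}

test_that("descriptors match definitional and atomic-weight oracles", {
  d <- compute_descriptors(c(
    benzene = "c1ccccc1", ethanol = "CCO", water = "O"
  ))
  expect_equal(d$id, c("benzene", "ethanol", "water"))
  # benzene: forced by the definitions
  expect_equal(d$n_aromatic_rings[1], 1L)
  expect_equal(d$n_hbd[1], 0L)
  expect_equal(d$n_rotatable[1], 0L)
  # molar masses against atomic-weight summation
  expect_equal(d$mw[2], formula_mw("C2H6O"), tolerance = 1e-3)
  expect_equal(d$n_hbd[2], 1L)
  expect_equal(d$mw[3], formula_mw("H2O"), tolerance = 1e-3)
  expect_equal(d$n_aromatic_rings[3], 0L)
  expect_true(all(d$mw > 0) && all(d$psa >= 0))

  # purity: identical input, identical output
  expect_identical(d, compute_descriptors(c(
    benzene = "c1ccccc1", ethanol = "CCO", water = "O"
  )))
})

test_that("descriptor computation reports unparseable and missing structures", {
  expect_error(
    compute_descriptors(c(ok = "CCO", broken = "XX(")),
    "broken"
  )
  expect_warning(
    d <- compute_descriptors(c(ok = "CCO", noinfo = NA)),
    "noinfo"
  )
  expect_equal(d$id, "ok")
})

test_that("chemical-space PCA satisfies variance accounting and orthonormality", {
  set.seed(101)
  # rank-1 case: only one descriptor varies
  x1 <- tibble::tibble(a = rnorm(10), b = 1, c = 2)
  p1 <- pca_chemspace(x1)
  expect_equal(p1$explained_variance[1], 1.0)

  # general case on random 7-descriptor data
  x <- as.data.frame(matrix(rnorm(30 * 7), 30, 7))
  p <- pca_chemspace(x)
  L <- as.matrix(p$loadings[, -1])
  expect_equal(t(L) %*% L, diag(7), ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # sign convention: the largest-magnitude loading entry is positive
  for (j in seq_len(ncol(L))) expect_gt(L[which.max(abs(L[, j])), j], 0)
  # full reconstruction of the centered-scaled matrix
  S <- as.matrix(p$scores)
  xs <- scale(as.matrix(x))
  expect_equal(S %*% t(L), xs, ignore_attr = TRUE, tolerance = 1e-10)

  # planted 2-D plane in 7-D plus tiny noise: two PCs capture >= 99%
  basis <- qr.Q(qr(matrix(rnorm(14), 7, 2)))
  plane <- matrix(rnorm(100), 50, 2) %*% t(basis) + matrix(rnorm(350, sd = 1e-3), 50, 7)
  pp <- pca_chemspace(as.data.frame(plane), scale = FALSE)
  expect_gte(sum(pp$explained_variance[1:2]), 0.99)

  # eigendecomposition of the sample covariance as an independent oracle
  ev_oracle <- sort(eigen(stats::cov(scale(as.matrix(x))), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(p$explained_variance, ev_oracle / sum(ev_oracle), tolerance = 1e-10)
})

test_that("PCA rejects missing values with a row/column report", {
  x <- tibble::tibble(a = c(1, NA, 3), b = c(4, 5, 6))
  expect_error(pca_chemspace(x), "row 2, column a")
})

test_that("broom and autoplot methods for chemspace PCA work", {
  set.seed(7)
  x <- tibble::tibble(
    set = rep(c("herb", "drug"), each = 10),
    a = rnorm(20), b = rnorm(20), c = rnorm(20)
  )
  p <- pca_chemspace(x)
  td <- tidy(p)
  expect_equal(td$cumulative[nrow(td)], 1, tolerance = 1e-10)
  expect_equal(glance(p)$n_obs, 20)
  expect_s3_class(autoplot(p, group = "set"), "ggplot")
})

test_that("drug-likeness comparison behaves at the distributional extremes", {
  same <- tibble::tibble(x = c(1, 2, 3, 4, 5))
  res <- compare_druglikeness(same, same)
  expect_equal(res$ks_statistic, 0)
  expect_equal(res$ks_p, 1)

  sep <- compare_druglikeness(
    tibble::tibble(x = c(1, 2, 3)), tibble::tibble(x = c(4, 5, 6))
  )
  expect_equal(sep$ks_statistic, 1)

  expect_error(
    compare_druglikeness(tibble::tibble(x = 1:2), same),
    "at least 3"
  )
})

test_that("rank-sum p equals exhaustive permutation enumeration", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  res <- compare_druglikeness(tibble::tibble(x = a), tibble::tibble(x = b))
  # enumerate all C(6,3) = 20 assignments of pooled ranks to group a
  pooled <- c(a, b)
  combos <- utils::combn(6, 3)
  w_obs <- sum(rank(pooled)[1:3]) - 3 * 4 / 2 # Mann-Whitney U of group a
  w_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]) - 6)
  p_exact <- mean(abs(w_all - 4.5) >= abs(w_obs - 4.5)) # two-sided around U mean
  expect_equal(res$ranksum_p, p_exact)
  expect_equal(res$ranksum_statistic, w_obs)
})

test_that("KS statistic equals direct ECDF enumeration for small samples", {
  set.seed(202)
  for (i in 1:25) {
    a <- sample(1:10, sample(3:6, 1), replace = TRUE)
    b <- sample(1:10, sample(3:6, 1), replace = TRUE)
    res <- compare_druglikeness(tibble::tibble(x = a), tibble::tibble(x = b))
    expect_equal(res$ks_statistic, oracle_ks_stat(a, b))
  }
})

test_that("tanimoto similarity matches a brute-force bit-set oracle", {
  set.seed(303)
  for (i in 1:50) {
    a <- as.integer(runif(64) < 0.4)
    b <- as.integer(runif(64) < 0.4)
    if (sum(a) == 0) a[1] <- 1L
    if (sum(b) == 0) b[2] <- 1L
    inter <- sum(a & b)
    uni <- sum(a | b)
    expect_equal(as.numeric(tanimoto_similarity(a, b)), inter / uni)
    # symmetry and the identity criterion
    expect_equal(tanimoto_similarity(a, b), t(tanimoto_similarity(b, a)))
    expect_equal(as.numeric(tanimoto_similarity(a, a)), 1)
    if (!identical(a, b)) expect_lt(as.numeric(tanimoto_similarity(a, b)), 1)
  }
})

test_that("similarity screen keeps the threshold inclusive and sorts matches", {
  # bit-exact fingerprints: |A n B| = 17, |A u B| = 20 gives exactly 0.85
  qf <- matrix(0L, 2, 64, dimnames = list(c("q_at", "q_below"), NULL))
  lf <- matrix(0L, 2, 64, dimnames = list(c("lib1", "lib_empty"), NULL))
  qf["q_at", 1:20] <- 1L
  lf["lib1", 1:17] <- 1L
  qf["q_below", 1:25] <- 1L # 17/28 with lib1 ~ 0.607
  lf["lib_empty", 40:45] <- 1L # disjoint from both queries
  res <- tanimoto_screen(
    queries = c(q_at = "CC"), library = c(lib1 = "CC"),
    query_fps = qf, library_fps = lf
  )
  expect_equal(res$query_id, "q_at")
  expect_equal(res$library_id, "lib1")
  expect_equal(res$tanimoto, 0.85)

  # identity retained at 1.0; structurally unrelated pair excluded
  res2 <- tanimoto_screen(
    queries = c(q = "CC(=O)Oc1ccccc1C(=O)O"),
    library = c(
      same = "CC(=O)Oc1ccccc1C(=O)O",
      other = "CCCCCCCC"
    )
  )
  expect_equal(res2$library_id, "same")
  expect_equal(res2$tanimoto, 1.0)

  # descending sort with lexicographic tie-break
  qf3 <- matrix(1L, 2, 8, dimnames = list(c("qB", "qA"), NULL))
  res3 <- tanimoto_screen(
    queries = "x", library = "x",
    query_fps = qf3,
    library_fps = matrix(1L, 1, 8, dimnames = list("L", NULL)),
    threshold = 0.5
  )
  expect_equal(res3$query_id, c("qA", "qB"))
})

test_that("unparseable screen records are reported, not fatal", {
  expect_warning(
    res <- tanimoto_screen(
      queries = c(good = "CCO", bad = "XX("),
      library = c(l1 = "CCO")
    ),
    "bad"
  )
  expect_equal(res$query_id, "good")
  probs <- attr(res, "problems")
  expect_equal(probs$id, "bad")
})
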