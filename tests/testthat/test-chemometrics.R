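test_that("correlation matrix reproduces published cells at 4 decimals", {
  r <- correlation_matrix(gliflozin_logp_all())
  expect_equal(round(r["HPLC.CN.ACN", "TLC.CN.ACN"], 4), 0.9706)
  expect_equal(round(r["MLOGP", "TLC.RP18.MeOH"], 4), 0.9934)
  expect_equal(round(r["MLOGP", "TLC.CN.ACN"], 4), 0.9904)
  expect_equal(round(r["HPLC.RP8.ACN", "TLC.CN.MeOH"], 4), 0.7398)
})

test_that("correlation matrix is symmetric, unit-diagonal and PSD", {
  r <- correlation_matrix(gliflozin_logp_all())
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, ncol(r)))
  expect_true(all(eigen(r, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("correlations are invariant under positive affine column transforms", {
  tbl <- gliflozin_logp_all()
  r0 <- correlation_matrix(tbl)
  tbl2 <- tbl
  tbl2$MLOGP <- 3.2 * tbl2$MLOGP + 11
  tbl2$TLC.CN.ACN <- 0.5 * tbl2$TLC.CN.ACN - 4
  expect_equal(correlation_matrix(tbl2), r0, tolerance = 1e-12)
})

test_that("zero-variance columns are flagged, not fatal", {
  tbl <- gliflozin_logp_exp()
  tbl$FLAT <- 2.0
  expect_warning(r <- correlation_matrix(tbl), "FLAT")
  expect_true(all(is.na(r["FLAT", setdiff(colnames(r), "FLAT")])))
  expect_equal(r["FLAT", "FLAT"], 1)
})

test_that("pairwise statistics reproduce the published WLOGP~MLOGP cell", {
  ps <- pairwise_stats_table(gliflozin_logp_all(),
                             pairs = cbind("MLOGP", "WLOGP"))
  expect_equal(round(ps$r, 4), 0.9872)
  expect_equal(ps$n, 5L)
})

test_that("pairwise statistics: exact fit, symmetry of r, ANOVA-F oracle", {
  x <- c(1, 2, 3, 4, 5)
  exact <- pairwise_stats(x, 2 * x + 3)
  expect_equal(exact$r, 1, tolerance = 1e-12)
  expect_equal(exact$s, 0, tolerance = 1e-10)

  set.seed(41)
  for (i in 1:20) {
    inst <- random_instance()
    xy <- pairwise_stats(inst$x, inst$y)
    yx <- pairwise_stats(inst$y, inst$x)
    expect_equal(xy$r, yx$r, tolerance = 1e-12)
    expect_equal(xy$F, anova_f_oracle(inst$x, inst$y), tolerance = 1e-6)
    # s follows the documented y-on-x direction
    expect_equal(xy$s, ols_oracle(inst$x, inst$y)$residual_se,
                 tolerance = 1e-10)
  }
})

test_that("clustering merges identical columns first, at height zero", {
  tbl <- tibble::tibble(
    drug = paste0("d", 1:5),
    A = c(1, 2, 3, 4, 5),
    B = c(1, 2, 3, 4, 5),
    C = c(5, 1, 4, 2, 3)
  )
  cl <- cluster_methods(tbl)
  hc <- cl$hclust
  expect_equal(hc$height[1], 0)
  first_pair <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first_pair, c("A", "B"))
})

test_that("three-method clustering agrees with an exhaustive distance oracle", {
  tbl <- tibble::tibble(
    drug = paste0("d", 1:5),
    M1 = c(3.7, 2.3, 2.3, 2.5, 3.6),
    M2 = c(3.3, 2.0, 1.4, 2.2, 3.4),
    M3 = c(1.9, 1.1, 0.7, 0.9, 1.9)
  )
  m <- as_logp_matrix(tbl)
  # brute-force pairwise Euclidean distances
  d12 <- sqrt(sum((m[, 1] - m[, 2])^2))
  d13 <- sqrt(sum((m[, 1] - m[, 3])^2))
  d23 <- sqrt(sum((m[, 2] - m[, 3])^2))
  dists <- c(M1.M2 = d12, M1.M3 = d13, M2.M3 = d23)
  closest <- strsplit(names(which.min(dists)), ".", fixed = TRUE)[[1]]
  cl <- cluster_methods(tbl)
  hc <- cl$hclust
  expect_identical(sort(hc$labels[-hc$merge[1, ]]), sort(closest))
  expect_equal(hc$height[1], min(dists), tolerance = 1e-12)
  expect_true(all(diff(hc$height) >= 0))
})

test_that("clustering is deterministic and invariant to column order", {
  tbl <- gliflozin_logp_all()
  n1 <- newick_tree(cluster_methods(tbl))
  shuffled <- tbl[c("drug", sample(setdiff(names(tbl), "drug")))]
  n2 <- newick_tree(cluster_methods(shuffled))
  expect_identical(n1, n2)

  path <- withr::local_tempfile(fileext = ".nwk")
  newick_tree(cluster_methods(tbl), path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, setdiff(names(tbl), "drug"))
})

test_that("single-method clustering degrades to a single-leaf tree", {
  tbl <- gliflozin_logp_exp()[c("drug", "HPLC.CN.ACN")]
  cl <- cluster_methods(tbl)
  expect_null(cl$hclust)
  expect_match(newick_tree(cl), "HPLC.CN.ACN", fixed = TRUE)
})

test_that("PCA of two perfectly correlated variables puts all variance on PC1", {
  tbl <- tibble::tibble(drug = paste0("d", 1:6),
                        A = c(1, 3, 2, 5, 4, 6))
  tbl$B <- 2 * tbl$A - 1
  p <- pca_methods(tbl, scale = TRUE)
  expect_equal(p$proportion[1], 1, tolerance = 1e-12)
})

test_that("PCA proportions sum to 1, scores are orthogonal, signs canonical", {
  p <- pca_methods(gliflozin_logp_all(), scale = TRUE)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-12)
  cross <- crossprod(p$scores)
  expect_equal(cross[upper.tri(cross)], rep(0, sum(upper.tri(cross))),
               tolerance = 1e-8)
  for (j in seq_len(ncol(p$loadings))) {
    v <- p$loadings[, j]
    expect_gte(v[which.max(abs(v))], 0)
  }
  expect_error(pca_methods(dplyr::mutate(gliflozin_logp_exp(), FLAT = 1)),
               "FLAT")
})

test_that("scaled PCA eigenvalues match a characteristic-polynomial oracle", {
  set.seed(42)
  tbl <- tibble::tibble(
    drug = paste0("d", 1:30),
    A = rnorm(30), B = rnorm(30), C = rnorm(30)
  )
  tbl$B <- tbl$B + 0.8 * tbl$A
  tbl$C <- tbl$C - 0.4 * tbl$A
  R <- cor(as_logp_matrix(tbl))
  # characteristic polynomial of a 3x3 matrix via trace / 2nd invariant / det
  tr <- sum(diag(R))
  m2 <- sum(vapply(1:3, function(i) det(R[-i, -i, drop = FALSE]), numeric(1)))
  coefs <- c(-det(R), m2, -tr, 1)  # -det + m2*x - tr*x^2 + x^3
  roots <- sort(Re(polyroot(coefs)), decreasing = TRUE)
  p <- pca_methods(tbl, scale = TRUE)
  expect_equal(p$eigenvalues, roots, tolerance = 1e-8)
})

test_that("sampling check: isotropic data spreads variance evenly", {
  set.seed(43)
  tbl <- tibble::as_tibble(matrix(rnorm(4000 * 4), ncol = 4,
                                  dimnames = list(NULL, paste0("V", 1:4))))
  tbl <- dplyr::bind_cols(tibble::tibble(drug = paste0("d", 1:4000)), tbl)
  p <- pca_methods(tbl, scale = TRUE)
  expect_equal(p$proportion, rep(0.25, 4), tolerance = 0.05)
})
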