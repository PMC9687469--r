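test_that("standardizer uses the population convention and is idempotent", {
  tab <- labeled_table(cbind(f1 = c(0, 2), f2 = c(1, 1.5)), c("a", "b"))
  std <- fit_standardizer(tab)
  expect_equal(unname(std$means[1]), 1)
  expect_equal(unname(std$sds[1]), 1)  # population sd of {0, 2}

  out <- apply_standardizer(tab, std)
  expect_equal(unname(colMeans(out$features)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(out$features, 2, function(x)
    sqrt(mean((x - mean(x))^2)))), c(1, 1), tolerance = 1e-9)

  # already-standardized data: refitting gives the identity transform
  std2 <- fit_standardizer(out)
  expect_equal(unname(std2$means), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(std2$sds), c(1, 1), tolerance = 1e-12)
  expect_identical(out$labels, tab$labels)
})

test_that("held-out rows are transformed with training statistics only", {
  train <- labeled_table(cbind(f1 = c(1, 3), f2 = c(10, 14)), c("a", "b"))
  std <- fit_standardizer(train)
  test <- labeled_table(cbind(f1 = 5, f2 = 10), "a")
  out <- apply_standardizer(test, std)
  # hand transform: (5 - 2)/1 = 3; (10 - 12)/2 = -1
  expect_equal(unname(out$features[1, ]), c(3, -1))

  # leakage guard: fitted parameters do not depend on held-out rows
  expect_identical(std, fit_standardizer(train))
  expect_error(apply_standardizer(
    labeled_table(matrix(1:3, 1, 3), "a"), std), "dimension mismatch")
})

test_that("constant features are flagged, warned about and passed through", {
  tab <- labeled_table(cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5)),
                       c("a", "a", "b"))
  expect_warning(std <- fit_standardizer(tab), "constant")
  expect_true(std$constant[["f2"]])
  out <- apply_standardizer(tab, std)
  expect_equal(unname(out$features[, "f2"]), c(0, 0, 0))
})

test_that("PCA matches an independent eigendecomposition", {
  set.seed(21)
  tab <- labeled_table(matrix(rnorm(60), 10, 6), rep(c("a", "b"), 5))
  pca <- fit_pca(tab, 6)

  # orthonormal loadings, descending variances
  expect_equal(t(pca$loadings) %*% pca$loadings, diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))

  # dense eigensolver oracle (same covariance, independent route)
  eig <- eigen(cov(tab$features), symmetric = TRUE)
  for (j in 1:6) {
    expect_equal(abs(sum(pca$loadings[, j] * eig$vectors[, j])), 1,
                 tolerance = 1e-8)
    expect_equal(pca$explained_variance[j], eig$values[j], tolerance = 1e-10)
  }

  # sign convention: largest-magnitude entry non-negative
  for (j in 1:6) {
    expect_gte(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }

  # completeness: k = n preserves total variance
  expect_equal(sum(pca$explained_variance),
               sum(apply(tab$features, 2, var)), tolerance = 1e-10)

  # projected training scores match the oracle scores up to column sign
  scores <- project_pca(tab, pca)
  expect_identical(colnames(scores$features), paste0("PC", 1:6))
  oracle <- scale(tab$features, scale = FALSE) %*% eig$vectors
  for (j in 1:6) {
    expect_equal(abs(scores$features[, j]), abs(oracle[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("rank-1 data yields one dominant component", {
  set.seed(22)
  u <- rnorm(5)
  tab <- labeled_table(outer(rnorm(12), u) +
                         matrix(1, 12, 5), rep(c("a", "b"), 6))
  pca <- fit_pca(tab, 4)
  expect_gt(pca$explained_variance[1], 1e-6)
  expect_lt(pca$explained_variance[2] / pca$explained_variance[1], 1e-10)
})

test_that("PCA validates k and feature dimensions", {
  set.seed(23)
  tab <- labeled_table(matrix(rnorm(40), 8, 5), rep(c("a", "b"), 4))
  expect_error(fit_pca(tab, 6), "k")
  expect_error(fit_pca(tab, 0), "k")
  pca <- fit_pca(tab, 2)
  expect_error(project_pca(labeled_table(matrix(1:4, 2, 2), c("a", "b")),
                           pca), "dimension mismatch")
})

test_that("fitted preprocessing parameters survive a JSON round-trip", {
  set.seed(24)
  tab <- labeled_table(matrix(rnorm(40), 8, 5), rep(c("a", "b"), 4))
  std <- fit_standardizer(tab)
  pca <- fit_pca(apply_standardizer(tab, std), 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_preproc(std, pca, path)
  back <- read_preproc(path)
  expect_equal(unname(back$standardizer$means), unname(std$means))
  expect_equal(unname(back$standardizer$sds), unname(std$sds))
  expect_equal(back$pca$loadings, pca$loadings, tolerance = 1e-12)
  expect_equal(back$pca$explained_variance, pca$explained_variance)
  expect_equal(back$pca$k, pca$k)
  # reloaded parameters reproduce the projection exactly
  expect_equal(project_pca(apply_standardizer(tab, back$standardizer),
                           back$pca)$features,
               project_pca(apply_standardizer(tab, std), pca)$features,
               tolerance = 1e-12)
})
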