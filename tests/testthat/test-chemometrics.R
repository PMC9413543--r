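test_that("PCA reproduces the centered truncated SVD", {
  # collinear 2-D points: one component carries all variance
  line <- cbind(1:5, 1:5)
  pm <- pca_fit(line, 2)
  expect_equal(pm$explained_variance[1], 100)
  expect_equal(pm$explained_variance[2], 0, tolerance = 1e-12)

  set.seed(8)
  x <- matrix(rnorm(60), 10, 6)
  full <- pca_fit(x, 6)
  recon <- full$scores %*% t(full$loadings)
  expect_equal(recon + rep(full$center, each = 10), x, tolerance = 1e-8)
  expect_equal(full$tev, 100, tolerance = 1e-8)

  # loadings orthonormal, scores orthogonal, variance non-increasing
  expect_equal(crossprod(full$loadings), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  g <- crossprod(full$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_true(all(diff(full$explained_variance) <= 1e-10))
})

test_that("PCA agrees with an independent eigendecomposition oracle", {
  set.seed(13)
  x <- matrix(rnorm(80), 10, 8)
  pm <- pca_fit(x, 4)
  xc <- sweep(x, 2, colMeans(x), `-`)
  eig <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  oracle_scores <- xc %*% eig$vectors[, 1:4]
  expect_equal(abs(unclass(pm$scores)), abs(oracle_scores),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pm$explained_variance[1:4],
               100 * eig$values[1:4] / sum(eig$values), tolerance = 1e-8)
  expect_error(pca_fit(x[1, , drop = FALSE], 1), "at least 2")
  expect_error(pca_fit(x, 10), "n_components")
})

test_that("CPCA-W super scores equal PCA of the concatenated weighted blocks", {
  for (seed in c(21, 22, 23)) {
    set.seed(seed)
    b1 <- matrix(rnorm(36 * 40), 36, 40)
    b2 <- matrix(rnorm(36 * 25), 36, 25)
    mb <- mbpca_fit(list(p = b1, n = b2), n_components = 3)
    w1 <- unclass_scaled(autoscale(b1)) / sqrt(40)
    w2 <- unclass_scaled(autoscale(b2)) / sqrt(25)
    oracle <- pca_fit(cbind(w1, w2), 3)
    expect_equal(abs(unclass(mb$super_scores)),
                 abs(unclass(oracle$scores)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("CPCA-W degenerates to PCA for one block and is symmetric for two", {
  set.seed(31)
  b <- matrix(rnorm(20 * 12), 20, 12)
  mb <- mbpca_fit(list(b), n_components = 2)
  # the single block still carries its 1/sqrt(n) weight
  pm <- pca_fit(unclass_scaled(autoscale(b)) / sqrt(ncol(b)), 2)
  expect_equal(abs(unclass(mb$super_scores)), abs(unclass(pm$scores)),
               tolerance = 1e-6, ignore_attr = TRUE)

  mb2 <- mbpca_fit(list(a = b, b = b), n_components = 2)
  expect_equal(abs(mb2$super_weights[1, ]), abs(mb2$super_weights[2, ]),
               tolerance = 1e-6)

  expect_error(mbpca_fit(list(b, matrix(0, 5, 3))), "same samples")
})

test_that("1/sqrt(n) weighting cancels column duplication", {
  set.seed(41)
  b1 <- matrix(rnorm(18 * 10), 18, 10)
  b2 <- matrix(rnorm(18 * 6), 18, 6)
  mb <- mbpca_fit(list(b1, b2), n_components = 2)
  mb_dup <- mbpca_fit(list(b1, cbind(b2, b2, b2, b2)), n_components = 2)
  expect_equal(abs(unclass(mb$super_scores)),
               abs(unclass(mb_dup$super_scores)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("scores are invariant to feature order", {
  set.seed(51)
  x <- matrix(rnorm(200), 10, 20)
  perm <- sample(20)
  expect_equal(abs(unclass(pca_fit(x, 3)$scores)),
               abs(unclass(pca_fit(x[, perm], 3)$scores)),
               tolerance = 1e-8, ignore_attr = TRUE)
  cls <- factor(rep(c("A", "B"), each = 5))
  f1 <- plsda_fit(x, cls, 2); f2 <- plsda_fit(x[, perm], cls, 2)
  expect_equal(abs(f1$scores), abs(f2$scores), tolerance = 1e-8)
})

test_that("PLS-DA separates separable clouds and matches its latent-space oracle", {
  g <- gaussian_classes(n_per = 8, p = 20, shift = 4, seed = 61)
  # two perfectly separated clouds need a single latent variable
  two <- g$classes != "B"
  fit <- plsda_fit(g$x[two, ], g$classes[two], n_lv = 1)
  expect_equal(mean(predict(fit, g$x[two, ]) == droplevels(g$classes[two])),
               1)

  fit2 <- plsda_fit(g$x, g$classes, n_lv = 2)
  # coefficient route (X B) must equal the latent route (T Q')
  Xs <- sweep(sweep(g$x, 2, fit2$x_center, `-`), 2, fit2$x_scale, `/`)
  expect_equal(Xs %*% fit2$coefficients,
               fit2$scores %*% t(fit2$y_loadings), tolerance = 1e-8)
  # latent scores orthogonal
  g2 <- crossprod(fit2$scores)
  expect_lt(abs(g2[1, 2]), 1e-8)

  expect_error(plsda_fit(g$x, rep("A", 24)), "at least 2 classes")
})

test_that("PLS-DA overfits random labels, which out-of-bag validation exposes", {
  set.seed(71)
  x <- matrix(rnorm(36 * 200), 36, 200)
  cls <- factor(rep(c("A", "B", "C"), each = 12))
  fit <- plsda_fit(x, cls, n_lv = 2)
  resub <- mean(predict(fit, x) == cls)
  expect_gte(resub, 0.8)                    # apparent separation from noise
  set.seed(72)
  oob <- bootstrap_validate(x, cls, n_boot = 100)$ccr
  expect_lt(oob, resub - 0.3)               # honest estimate collapses
})

test_that("prediction assigns centroids to their class and flags ties", {
  g <- gaussian_classes(n_per = 6, p = 10, shift = 5, seed = 81)
  fit <- plsda_fit(g$x, g$classes, n_lv = 2)
  for (k in levels(g$classes)) {
    centroid <- colMeans(g$x[g$classes == k, , drop = FALSE])
    expect_equal(as.character(predict(fit, rbind(centroid))), k)
  }
  # symmetric two-class sample: exact tie goes to the first class, flagged
  x2 <- matrix(c(-1, -1.5, 1, 1.5), 4, 1)
  fit2 <- plsda_fit(x2, factor(c("A", "A", "B", "B")), n_lv = 1)
  pr <- predict(fit2, matrix(0, 1, 1))
  expect_equal(as.character(pr), "A")
  expect_true(attr(pr, "tie"))
  expect_error(predict(fit2, matrix(0, 1, 3)), "features")
})
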