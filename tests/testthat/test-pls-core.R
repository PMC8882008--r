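test_that("self-correlation of a single column yields one full latent variable", {
  x <- matrix(c(1, 3, 2, 5, 4), ncol = 1)
  fit <- fit_pls(x, x)
  expect_length(fit$singular_values, 1L)
  expect_equal(fit$singular_values[1], 1, tolerance = 1e-12)
  expect_equal(fit$covariance_explained, 100, tolerance = 1e-12)
  expect_equal(abs(fit$behaviour_correlations[1, 1]), 1, tolerance = 1e-12)
})

test_that("singular structure matches an independent eigendecomposition", {
  X <- matrix(c(2, 5, 1, 4, 7, 3,
                9, 1, 6, 2, 8, 4,
                3, 3, 7, 1, 5, 9), 6, 3)
  Y <- matrix(c(1, 4, 2, 6, 3, 5,
                7, 2, 8, 1, 9, 4), 6, 2)
  fit <- fit_pls(X, Y)

  R <- crossprod(scale(Y), scale(X)) / (nrow(X) - 1)
  ev <- eigen(tcrossprod(R), symmetric = TRUE)  # R R^T: b x b
  expect_equal(fit$singular_values, sqrt(pmax(0, ev$values)),
               tolerance = 1e-8)
  for (l in seq_along(fit$singular_values)) {
    u_oracle <- ev$vectors[, l]
    expect_equal(abs(sum(fit$behaviour_saliences[, l] * u_oracle)), 1,
                 tolerance = 1e-8)
    v_oracle <- drop(t(R) %*% u_oracle) / sqrt(ev$values[l])
    expect_equal(abs(sum(fit$voxel_saliences[, l] * v_oracle)), 1,
                 tolerance = 1e-8)
  }
})

test_that("constant columns are rejected", {
  X <- matrix(rnorm(20), 5, 4)
  Ybad <- cbind(a = rnorm(5), b = rep(2, 5))
  expect_error(fit_pls(X, Ybad), "constant.*b")
  Xbad <- X; Xbad[, 2] <- 0
  expect_error(fit_pls(Xbad, cbind(a = rnorm(5))), "constant")
  expect_error(fit_pls(X, matrix(rnorm(8), 4, 2)), "subject counts")
})

test_that("PLS satisfies its algebraic identities", {
  set.seed(10)
  blocks <- planted_blocks(n = 25, v = 12, b = 4, effect = 0.8)
  fit <- fit_pls(blocks$X, blocks$Y)
  U <- fit$behaviour_saliences
  V <- fit$voxel_saliences
  s <- fit$singular_values
  R <- crossprod(scale(blocks$Y), scale(blocks$X)) / (nrow(blocks$X) - 1)

  expect_equal(crossprod(U), diag(ncol(U)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(fit$covariance_explained), 100, tolerance = 1e-6)
  expect_equal(sum(s^2), sum(R^2), tolerance = 1e-8)
  expect_equal(U %*% diag(s) %*% t(V), R, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(abs(fit$behaviour_correlations) <= 1 + 1e-12))
  expect_true(all(diff(s) <= 1e-12))
  # sign convention: the largest-|u| element of each column is positive
  for (l in seq_along(s))
    expect_gt(U[which.max(abs(U[, l])), l], 0)
})

test_that("fit is invariant to affine rescaling of input columns", {
  blocks <- planted_blocks(n = 20, v = 8, b = 3, seed = 4)
  fit1 <- fit_pls(blocks$X, blocks$Y)
  X2 <- blocks$X
  X2[, 3] <- 100 * X2[, 3] - 7
  Y2 <- blocks$Y
  Y2[, 2] <- -0.02 * Y2[, 2] + 11  # sign flip allowed by z-scoring? no:
  # negative scaling flips that column's correlation sign, so use positive
  Y2[, 2] <- 0.02 * blocks$Y[, 2] + 11
  fit2 <- fit_pls(X2, Y2)
  expect_equal(fit1$singular_values, fit2$singular_values,
               tolerance = 1e-10)
  expect_equal(fit1$voxel_saliences, fit2$voxel_saliences,
               tolerance = 1e-8)
  expect_equal(fit1$behaviour_saliences, fit2$behaviour_saliences,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("fit is equivariant under joint subject permutation", {
  blocks <- planted_blocks(n = 18, v = 10, b = 3, seed = 6)
  perm <- sample(18)
  fit1 <- fit_pls(blocks$X, blocks$Y)
  fit2 <- fit_pls(blocks$X[perm, ], blocks$Y[perm, ])
  expect_equal(fit1$singular_values, fit2$singular_values,
               tolerance = 1e-10)
  expect_equal(fit1$voxel_saliences, fit2$voxel_saliences, tolerance = 1e-8)
  expect_equal(fit1$brain_scores[perm, ], fit2$brain_scores,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rank-deficient latent variables are dropped", {
  set.seed(3)
  y1 <- rnorm(12)
  Y <- cbind(a = y1, b = 2 * y1 + 3)  # rank-1 behaviour block
  X <- matrix(rnorm(12 * 6), 12, 6)
  fit <- fit_pls(X, Y)
  expect_length(fit$singular_values, 1L)
})

test_that("datamat correlation maps agree with a direct Pearson oracle", {
  set.seed(8)
  dims <- c(4, 3, 3)
  maps <- lapply(1:5, function(i) random_map(dims, seed = 20 + i))
  dm <- build_datamat(maps, all_true_mask(maps[[1]]))
  y <- rnorm(5)
  # plant exact copies of +/- y at two voxels
  dm$matrix[, 7] <- y
  dm$matrix[, 13] <- -y
  cmap <- datamat_correlation_map(dm, y)
  vals <- as.numeric(cmap$values)[dm$voxel_index]
  oracle <- apply(dm$matrix, 2, function(col) {
    n <- length(y)
    num <- sum((col - mean(col)) * (y - mean(y)))
    num / sqrt(sum((col - mean(col))^2) * sum((y - mean(y))^2))
  })
  expect_equal(vals, oracle, tolerance = 1e-12)
  expect_equal(vals[7], 1, tolerance = 1e-12)
  expect_equal(vals[13], -1, tolerance = 1e-12)

  dm$matrix[, 2] <- 5  # zero-variance voxel flagged, not zeroed
  cmap2 <- datamat_correlation_map(dm, y)
  expect_true(is.nan(as.numeric(cmap2$values)[dm$voxel_index][2]))
  expect_error(datamat_correlation_map(dm, rep(1, 5)), "constant")
})
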