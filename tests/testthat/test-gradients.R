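test_that("MPC equals the brute-force pairwise partial-Spearman oracle", {
  set.seed(11)
  vals <- matrix(rnorm(9 * 5), 9, 5) + outer(seq(0, 2, length.out = 9), rep(1, 5))
  pm <- profile_matrix(vals, 1:9)
  mpc <- compute_mpc(pm)
  expect_equal(mpc$values, mpc_oracle(vals), tolerance = 1e-10)
  expect_equal(mpc$values, t(mpc$values), tolerance = 1e-12)
  expect_true(all(diag(mpc$values) == 0))
})

test_that("MPC clipping, zero fixed point, and rank invariance", {
  set.seed(12)
  base <- matrix(rnorm(8 * 6), 8, 6)
  # two identical profiles: partial correlation clipped at 1 - 1e-7
  base[, 2] <- base[, 1]
  mpc <- compute_mpc(profile_matrix(base, 1:8))
  expect_equal(mpc$values[1, 2], 0.5 * log((2 - 1e-7) / 1e-7), tolerance = 1e-6)
  # monotone transform of a single profile leaves the matrix unchanged
  tr <- base
  tr[, 3] <- exp(tr[, 3])
  expect_equal(compute_mpc(profile_matrix(tr, 1:8))$values, mpc$values,
               tolerance = 1e-12)
  # constant profile flags its row/column
  cc <- base; cc[, 4] <- 2
  m2 <- compute_mpc(profile_matrix(cc, 1:8))
  expect_true(m2$flagged[4])
  expect_true(all(is.nan(m2$values[4, -4])))
  expect_false(any(is.nan(m2$values[-4, -4])))
  expect_error(compute_mpc(profile_matrix(base[1:2, ], 1:2)), "3 depths")
})

test_that("normalized-angle affinity has the contracted geometry", {
  # identical rows -> affinity 1; orthogonal nonnegative rows -> 0.5
  M <- rbind(c(0, 1, 1, 0, 0), c(0, 1, 1, 0, 0), c(1, 0, 0, 1, 1),
             c(1, 0, 0, 1, 0.5), c(0.5, 0, 0, 1, 1))
  A <- affinity_normalized_angle(M, sparsity = 0)
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], 0.5)
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(A, t(A), tolerance = 1e-12)
  expect_true(all(diag(A) == 1))

  # V = 100 at default sparsity: exactly 10 entries retained per row
  set.seed(13)
  M2 <- matrix(rnorm(100 * 100), 100)
  M2 <- (M2 + t(M2)) / 2; diag(M2) <- 0
  k <- 0
  A2 <- affinity_normalized_angle(M2, sparsity = 0.9)
  # count via the sparsification rule replicated: ceiling(0.1 * 100) = 10
  expect_equal(ceiling((1 - 0.9) * 100), 10)
  expect_true(all(is.finite(A2)))
  expect_error(affinity_normalized_angle(matrix(NaN, 3, 3)), "finite")
})

test_that("diffusion embedding matches a dense eigensolver oracle", {
  set.seed(14)
  # random symmetric nonnegative affinity
  A <- matrix(runif(50 * 50, 0.05, 1), 50)
  A <- (A + t(A)) / 2; diag(A) <- 1
  gs <- diffusion_embedding(A, alpha = 0.5, n_components = 5)
  # oracle: direct eigendecomposition of the (nonsymmetric) Markov operator
  d <- rowSums(A)
  W <- A / outer(d^0.5, d^0.5)
  P <- W / rowSums(W)
  eo <- eigen(P)
  lam <- Re(eo$values); vec <- Re(eo$vectors)
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; vec <- vec[, ord]
  expect_equal(gs$eigenvalues, lam[2:6], tolerance = 1e-8)
  for (k in 1:5) {
    ref <- vec[, k + 1] * lam[k + 1] / (1 - lam[k + 1])
    got <- gs$gradients[, k]
    err <- min(max(abs(got - ref * max(abs(got)) / max(abs(ref)))),
               max(abs(got + ref * max(abs(got)) / max(abs(ref)))))
    expect_lt(err, 1e-6)
    # up to sign and eigenvector scaling: correlation magnitude 1
    expect_equal(abs(cor(got, ref)), 1, tolerance = 1e-8)
  }
  # eigenvalues in (-1, 1] after dropping the trivial one
  expect_true(all(gs$eigenvalues > -1 & gs$eigenvalues < 1))
  # orthogonality under the stationary-distribution inner product
  for (k in 2:5)
    expect_lt(abs(sum(gs$stationary * gs$gradients[, 1] * gs$gradients[, k])),
              1e-6)
})

test_that("two-block affinity is separated by the G1 sign pattern", {
  V <- 40
  blk <- rep(c(1, 2), each = V / 2)
  A <- matrix(0.05, V, V)
  A[blk == 1, blk == 1] <- 1
  A[blk == 2, blk == 2] <- 1
  gs <- diffusion_embedding(A, n_components = 3)
  g1 <- gs$gradients[, 1]
  expect_true(all(g1[blk == 1] > 0) && all(g1[blk == 2] < 0) ||
              all(g1[blk == 1] < 0) && all(g1[blk == 2] > 0))
})

test_that("embedding is equivariant under vertex permutation", {
  set.seed(15)
  A <- matrix(runif(30 * 30, 0.1, 1), 30)
  A <- (A + t(A)) / 2; diag(A) <- 1
  gs <- diffusion_embedding(A, n_components = 3)
  p <- sample(30)
  gsp <- diffusion_embedding(A[p, p], n_components = 3)
  for (k in 1:3)
    expect_equal(abs(cor(gsp$gradients[, k], gs$gradients[p, k])), 1,
                 tolerance = 1e-8)
  expect_error(diffusion_embedding(diag(2) * 0 + diag(2)), "disconnected")
})

test_that("variance explained fractions are eigenvalue shares", {
  expect_equal(variance_explained(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(variance_explained(5), 1)
  set.seed(16)
  A <- matrix(runif(20 * 20, 0.2, 1), 20); A <- (A + t(A)) / 2; diag(A) <- 1
  gs <- diffusion_embedding(A, n_components = 19)
  expect_equal(sum(variance_explained(gs)), 1, tolerance = 1e-12)
})

test_that("gradient alignment flips sign and reports stability r", {
  set.seed(17)
  g <- rnorm(500)
  al <- align_gradients(g, -g)
  expect_true(al$flipped)
  expect_equal(al$pearson_r, 1)
  expect_equal(al$aligned, g)
  # independent maps: |r| small
  al2 <- align_gradients(rnorm(5000), rnorm(5000))
  expect_lt(abs(al2$pearson_r), 0.05)
  # monotone degradation with noise
  rs <- vapply(c(0.1, 0.5, 1, 2), function(s)
    align_gradients(g, g + rnorm(500, sd = s))$pearson_r, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_gt(rs[1], 0.99)
  expect_error(align_gradients(g, rep(1, 500)), "zero-variance")
})

test_that("planted gradient is recovered through the MPC pipeline", {
  pp <- make_planted_gradient_profiles(500, seq(0.2, 3, by = 0.2),
                                       noise_sd = 0.5, seed = 42)
  sm <- t(apply(pp$profiles, 1, smooth_surface_map, mesh = pp$adjacency))
  mpc <- compute_mpc(profile_matrix(sm, pp$depths))
  gs <- mpc_gradients(mpc)
  keep <- gs$kept
  rho <- cor(gs$gradients[keep, 1], pp$gradient_truth[keep],
             method = "spearman")
  expect_gt(abs(rho), 0.9)
})

test_that("gradient pipeline is deterministic up to the fixed sign convention", {
  pp <- make_planted_gradient_profiles(120, seq(0.2, 3, by = 0.2),
                                       noise_sd = 0.5, seed = 5)
  pm <- profile_matrix(pp$profiles, pp$depths)
  g1 <- mpc_gradients(compute_mpc(pm))
  g2 <- mpc_gradients(compute_mpc(pm))
  expect_identical(g1$gradients, g2$gradients)
  # sign convention: first nonzero loading positive
  expect_gt(g1$gradients[which(abs(g1$gradients[, 1]) > 1e-12)[1], 1], 0)
})
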