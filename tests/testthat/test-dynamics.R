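test_that("iqr follows the linear-interpolation quantile rule", {
  expect_equal(iqr(c(1, 1, 1, 1)), 0)
  expect_equal(iqr(c(1, 2, 3, 4)), 1.5)   # Q1 = 1.75, Q3 = 3.25
  expect_error(iqr(numeric(0)), "one sample")
  # robustness: an appended outlier moves the IQR less than the range
  set.seed(1)
  x <- rnorm(40)
  x_out <- c(x, 1e3)
  expect_lt(iqr(x_out) - iqr(x), diff(range(x_out)) - diff(range(x)))
})

test_that("iqr agrees with a sort-and-interpolate oracle", {
  set.seed(123)
  for (i in 1:1000) {
    x <- runif(sample(1:50, 1), -10, 10)
    expect_equal(iqr(x), oracle_iqr(x), tolerance = 1e-12)
  }
})

test_that("DV is zero for rigidly moving ensembles, symmetric, zero-diagonal", {
  g <- gaussian_chain(10, 8, 0, seed = 2)
  dv <- dv_matrix(rigid_scramble(g$ensemble))
  expect_lt(max(abs(dv$values)), 1e-8)
  g2 <- gaussian_chain(12, 30, 0.6, seed = 3)
  dv2 <- dv_matrix(g2$ensemble)
  expect_identical(dv2$values, t(dv2$values))
  expect_identical(diag(dv2$values), rep(0, 12))
  expect_true(all(dv2$values >= 0))
})

test_that("DV matches direct two-frame computation under the quantile rule", {
  # two frames with a single pair at distances 3.8 and 4.2: IQR = 0.2
  coords <- array(0, c(2, 3, 3))
  coords[1, 2, 1] <- 3.8
  coords[2, 2, 1] <- 4.2
  coords[, 3, 2] <- 10   # third residue to keep geometry non-trivial
  ens <- new_ensemble(coords, rep("CA", 3), 1:3)
  dv <- dv_matrix(ens)
  expect_equal(dv$values[1, 2], 0.2, tolerance = 1e-12)
  expect_equal(dv$quantile_method, "linear_type7")
  # general case against a brute-force per-pair oracle
  g <- gaussian_chain(6, 25, 0.5, seed = 4)
  dvg <- dv_matrix(g$ensemble)
  X <- g$ensemble$coords
  for (i in 1:5) for (j in (i + 1):6) {
    d <- sqrt(rowSums((X[, i, ] - X[, j, ])^2))
    expect_equal(dvg$values[i, j], oracle_iqr(d), tolerance = 1e-12)
  }
})

test_that("DV is invariant under per-frame rigid transforms", {
  h <- hinge_two_domain(c(8, 8), 2, 10, n_frames = 40, seed = 5)
  dv1 <- dv_matrix(h$ensemble)
  set.seed(99)
  dv2 <- dv_matrix(rigid_scramble(h$ensemble))
  expect_lt(max(abs(dv1$values - dv2$values)), 1e-8)
})

test_that("hinge DV shows intra-domain < inter-domain block structure", {
  h <- hinge_two_domain(c(30, 30), 5, 15, n_frames = 800, seed = 6)
  V <- dv_matrix(h$ensemble)$values
  far1 <- 1:20; far2 <- 45:65    # >= 10 residues from the pivot (residue 30)
  intra <- c(V[far1, far1][upper.tri(diag(length(far1)))],
             V[far2, far2][upper.tri(diag(length(far2)))])
  inter <- as.numeric(V[far1, far2])
  expect_lt(max(intra), min(inter))
  expect_lt(median(intra), median(inter))
})

test_that("DCCM satisfies its contracts on the hinge ensemble", {
  h <- hinge_two_domain(c(20, 20), 4, 15, n_frames = 500, seed = 7)
  d <- dccm(h$ensemble)
  expect_true(all(d >= -1 & d <= 1))
  expect_equal(unname(diag(d)), rep(1, 44))
  expect_identical(unclass(d)[1:44, ], t(unclass(d))[1:44, ])
  i1 <- 1:20; i2 <- 25:44
  expect_gt(mean(d[i1, i1][upper.tri(diag(20))]), 0)
  expect_gt(mean(d[i2, i2][upper.tri(diag(20))]), 0)
  expect_lt(mean(d[i1, i2]), 0)
})

test_that("opposite motions give DCCM -1 and pure common motion degenerates", {
  # residues 1 and 3 move in exactly opposite directions about a rigid frame
  base <- flexconcord:::.helix_trace(4)
  nf <- 30
  coords <- array(0, c(nf, 4, 3))
  set.seed(8)
  amp <- rnorm(nf, 0, 0.5)
  for (f in 1:nf) {
    fr <- base
    fr[1, 3] <- fr[1, 3] + amp[f]
    fr[3, 3] <- fr[3, 3] - amp[f]
    coords[f, , ] <- fr
  }
  ens <- new_ensemble(coords, rep("CA", 4), 1:4)
  d <- suppressWarnings(dccm(ens))
  expect_lt(d[1, 3], -0.9)
  # common translation only: superposition removes it, zero-variance warning
  rigid <- gaussian_chain(5, 10, 0, seed = 9)$ensemble
  trans <- rigid
  set.seed(10)
  for (f in 1:10) {
    trans$coords[f, , ] <- sweep(trans$coords[f, , ], 2, rnorm(3, 0, 4), `+`)
  }
  expect_warning(d0 <- dccm(trans), "zero positional variance")
  expect_equal(max(abs(d0)), 0)
})

test_that("PCA conserves variance and is orthonormal", {
  g <- gaussian_chain(10, 60, sigma_loop_profile(10), seed = 11)
  p <- pca_ensemble(g$ensemble)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(t(p$modes) %*% p$modes, diag(ncol(p$modes)), tolerance = 1e-8)
  # eigenvalue sum equals the trace of the mass-weighted covariance
  X <- matrix(0, 60, 30)
  ca <- select_calpha(g$ensemble)
  fit <- flexconcord:::.fit_to_mean(ca$coords, 1:10)
  for (k in 1:3) X[, seq(k, 30, 3)] <- fit$coords[, , k]
  Xw <- X * sqrt(12.011)
  expect_equal(sum(p$eigenvalues), sum(diag(stats::cov(Xw))), tolerance = 1e-8)
})

test_that("PCA recovers planted mode variances and rigid ensembles are flat", {
  # two orthogonal non-rigid shape modes with 9:1 variance ratio
  base <- flexconcord:::.helix_trace(12)
  set.seed(12)
  v1 <- matrix(rnorm(36), 12, 3); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- matrix(rnorm(36), 12, 3)
  v2 <- v2 - v1 * sum(v1 * v2); v2 <- v2 / sqrt(sum(v2^2))
  nf <- 5000
  a1 <- rnorm(nf, 0, 3); a2 <- rnorm(nf, 0, 1)
  coords <- array(0, c(nf, 12, 3))
  for (f in 1:nf) coords[f, , ] <- base + a1[f] * v1 + a2[f] * v2
  ens <- new_ensemble(coords, rep("CA", 12), 1:12)
  p <- pca_ensemble(ens)
  expect_equal(p$eigenvalues[1] / p$eigenvalues[2], 9, tolerance = 0.15)
  expect_lt(p$variance_fraction[3], 0.02)
  # rigid ensemble: all eigenvalues ~ 0
  rigid <- rigid_scramble(gaussian_chain(8, 10, 0, seed = 13)$ensemble)
  expect_lt(max(pca_ensemble(rigid)$eigenvalues), 1e-12)
})

test_that("hinge PC1 dominates and separates the domains", {
  h <- hinge_two_domain(c(20, 20), 4, 15, n_frames = 1000, seed = 14)
  p <- pca_ensemble(h$ensemble)
  expect_gt(p$variance_fraction[1], 0.8)
  # PC1 displaces the two domains in opposite senses along the hinge arc
  disp <- matrix(p$modes[, 1], ncol = 3, byrow = TRUE)
  lever <- sweep(flexconcord:::.helix_trace(44), 2,
                 flexconcord:::.helix_trace(44)[20, ])
  # mean projection of per-residue displacement onto the local arc direction
  arc <- cbind(0, -lever[, 3], lever[, 2])  # x-axis rotation tangent
  proj <- rowSums(disp * arc)
  expect_lt(mean(proj[1:20]) * mean(proj[25:44]), 0)
})

test_that("PC animation interpolates the mode and round-trips through PCA", {
  h <- hinge_two_domain(c(10, 10), 2, 10, n_frames = 300, seed = 15)
  p <- pca_ensemble(h$ensemble)
  anim <- pc_animation(p, mode = 1, n_steps = 3, amplitude = 2)
  expect_equal(n_frames(anim), 3)
  # middle frame is the mean structure
  expect_equal(anim$coords[2, , ], p$mean_coords, tolerance = 1e-10)
  # end frames are symmetric about the mean
  expect_equal(anim$coords[1, , ] + anim$coords[3, , ], 2 * p$mean_coords,
               tolerance = 1e-10)
  expect_error(pc_animation(p, amplitude = 0), "positive")
  # PCA of the animation recovers the animated mode direction
  anim2 <- pc_animation(p, mode = 1, n_steps = 25, amplitude = 2)
  p2 <- pca_ensemble(anim2)
  expect_gt(abs(sum(p2$modes[, 1] * p$modes[, 1])), 0.99)
  # tiny amplitude: all frames collapse onto the mean
  eps <- pc_animation(p, mode = 1, n_steps = 5, amplitude = 1e-9)
  expect_equal(eps$coords[5, , ], p$mean_coords, tolerance = 1e-6)
})
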