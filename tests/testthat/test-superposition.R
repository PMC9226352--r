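test_that("Kabsch recovers exact rigid transforms", {
  set.seed(11)
  P <- matrix(rnorm(30), 10, 3)
  # identity case
  k0 <- kabsch_superpose(P, P)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(k0$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(k0$rmsd, 0, tolerance = 1e-10)
  # rotated + shifted case
  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- sweep(P %*% t(Rz), 2, c(1, 2, 3), `+`)
  k <- kabsch_superpose(P, Q)
  expect_lt(k$rmsd, 1e-8)
  expect_equal(det(k$rotation), 1, tolerance = 1e-10)
  expect_equal(k$coords, Q, tolerance = 1e-8)
})

test_that("Kabsch matches a grid-search oracle on non-rigid point sets", {
  set.seed(21)
  for (i in 1:3) {
    P <- matrix(rnorm(12), 4, 3)
    Q <- matrix(rnorm(12), 4, 3)
    k <- kabsch_superpose(P, Q)
    expect_lte(k$rmsd, oracle_grid_rmsd(P, Q) + 1e-3)
  }
})

test_that("Kabsch rejects degenerate fit sets", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
  expect_error(kabsch_superpose(line[1:2, ], line[1:2, ]), "3 fit points")
})

test_that("Kabsch is invariant under pre-applied rigid transforms", {
  set.seed(31)
  P <- matrix(rnorm(24), 8, 3)
  Q <- P + 0.3 * matrix(rnorm(24), 8, 3)
  base <- kabsch_superpose(P, Q)
  for (i in 1:5) {
    R <- random_rotation()
    t <- rnorm(3, 0, 10)
    P2 <- sweep(P %*% t(R), 2, t, `+`)
    expect_equal(kabsch_superpose(P2, Q)$rmsd, base$rmsd, tolerance = 1e-8)
  }
  # fitted RMSD never exceeds the unfitted RMSD
  expect_lte(base$rmsd, sqrt(mean(rowSums((P - Q)^2))))
})

test_that("RMSD profile is zero at the reference and rigid-invariant", {
  g <- gaussian_chain(10, 5, 0.4, seed = 3)
  ens <- g$ensemble
  # identical frames
  rigid <- ens
  for (f in 2:5) rigid$coords[f, , ] <- rigid$coords[1, , ]
  expect_equal(rmsd_profile(rigid)$rmsd, rep(0, 5), tolerance = 1e-10)
  # rigidly moved frame
  R <- random_rotation()
  two <- ens
  two$coords <- ens$coords[1:2, , , drop = FALSE]
  two$coords[2, , ] <- sweep(two$coords[1, , ] %*% t(R), 2, c(5, -2, 1), `+`)
  p <- rmsd_profile(two)
  expect_equal(p$rmsd, c(0, 0), tolerance = 1e-8)
  expect_error(rmsd_profile(ens, reference_frame = 99), "range")
  # general 2-frame RMSD agrees with the grid-search oracle
  set.seed(7)
  small <- g$ensemble
  small$coords <- small$coords[1:2, 1:5, , drop = FALSE]
  small$atom_names <- small$atom_names[1:5]
  small$atom_residue <- 1:5
  small$masses <- small$masses[1:5]
  got <- rmsd_profile(small)$rmsd[2]
  oracle <- oracle_grid_rmsd(small$coords[2, , ], small$coords[1, , ])
  expect_lte(got, oracle + 1e-3)        # Kabsch is the global optimum
  expect_equal(got, oracle, tolerance = 0.05)
})

test_that("RMSF vanishes on rigid ensembles and needs 2+ frames", {
  g <- gaussian_chain(8, 6, 0, seed = 9)   # sigma 0: rigid
  scrambled <- rigid_scramble(g$ensemble)
  r <- rmsf_all_atom(scrambled)
  expect_lt(max(r$rmsf), 1e-8)
  one <- g$ensemble
  one$coords <- one$coords[1, , , drop = FALSE]
  expect_error(rmsf_all_atom(one), "2 frames")
})

test_that("two-frame RMSF equals half the post-fit displacement", {
  # two frames identical except one residue displaced; each frame then sits
  # at distance d from the mean, so that residue's RMSF is d
  base <- flexconcord:::.helix_trace(12)
  f2 <- base
  f2[6, ] <- f2[6, ] + c(0, 0, 2.4)
  ens <- new_ensemble(array(c(rbind(base[, 1], f2[, 1]),
                              rbind(base[, 2], f2[, 2]),
                              rbind(base[, 3], f2[, 3])), c(2, 12, 3)),
                      rep("CA", 12), 1:12)
  r <- rmsf_all_atom(ens)
  # the fit absorbs some displacement into the rigid modes; residue 6 keeps
  # most of the 1.2 A deviation about the mean and dominates the profile
  expect_gt(r$rmsf[6], 1.0)
  expect_lte(r$rmsf[6], 1.2 + 1e-10)
  expect_equal(which.max(r$rmsf), 6L)
})

test_that("RMSF recovers the generator's sigma sqrt(3) profile", {
  g <- gaussian_chain(60, 4000, sigma_loop_profile(60), seed = 13)
  r <- rmsf_all_atom(g$ensemble)
  rel <- abs(r$rmsf - g$truth$expected_rmsf) / g$truth$expected_rmsf
  expect_lt(max(rel), 0.05)
})

test_that("RMSF is permutation-equivariant in residue order", {
  g <- gaussian_chain(10, 40, sigma_loop_profile(10), seed = 17)
  r1 <- rmsf_all_atom(g$ensemble)
  perm <- sample(10)
  ens2 <- g$ensemble
  ens2$coords <- ens2$coords[, perm, , drop = FALSE]
  r2 <- rmsf_all_atom(ens2)
  expect_equal(r2$rmsf, r1$rmsf[perm], tolerance = 1e-10)
})

test_that("RMSF agrees with the bio3d reference implementation", {
  g <- gaussian_chain(20, 200, sigma_loop_profile(20), seed = 23)
  X <- g$ensemble$coords
  nf <- dim(X)[1]; nr <- dim(X)[2]
  xyz <- matrix(0, nf, 3 * nr)
  for (k in 1:3) xyz[, seq(k, 3 * nr, 3)] <- X[, , k]
  fit1 <- suppressWarnings(bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz))
  fit2 <- suppressWarnings(bio3d::fit.xyz(fixed = colMeans(fit1), mobile = xyz))
  ref <- bio3d::rmsf(fit2)
  # bio3d normalizes by F - 1 where this package uses the plain 1/F mean
  expect_equal(rmsf_all_atom(g$ensemble)$rmsf, ref * sqrt(199 / 200),
               tolerance = 1e-6)
})

test_that("domain-specific RMSF keeps rigid domains rigid and averages linkers", {
  h <- hinge_two_domain(c(15, 15), 4, 12, n_frames = 300, seed = 5)
  rd <- rmsf_domain_specific(h$ensemble, h$partition)
  ra <- rmsf_all_atom(h$ensemble)
  nonlinker <- c(1:15, 20:34)
  expect_lt(max(rd$rmsf[nonlinker]), 1e-8)         # internally rigid bodies
  expect_true(all(rd$rmsf[nonlinker] < ra$rmsf[nonlinker]))
  expect_equal(rd$segment[16:19], rep("linker", 4))
  # linker value is the mean over the two flanking fits, verified directly
  ca <- select_calpha(h$ensemble)
  fits <- lapply(list(1:15, 20:34), function(idx) {
    f <- flexconcord:::.fit_to_mean(ca$coords, idx)
    flexconcord:::.rmsf_from_fitted(f$coords, f$mean)
  })
  expect_equal(rd$rmsf[16:19], (fits[[1]][16:19] + fits[[2]][16:19]) / 2,
               tolerance = 1e-12)
})

test_that("a single segment spanning everything reproduces the global protocol", {
  g <- gaussian_chain(12, 30, sigma_loop_profile(12), seed = 7)
  one <- domain_partition(list(all = c(1, 12)))
  expect_equal(rmsf_domain_specific(g$ensemble, one)$rmsf,
               rmsf_all_atom(g$ensemble)$rmsf, tolerance = 1e-10)
})

test_that("invalid partitions are rejected", {
  expect_error(domain_partition(list(a = c(1, 10), b = c(5, 20))),
               "non-overlapping")
  expect_error(domain_partition(list(a = c(1, 10), b = c(15, 20)),
                                linkers = list(c(11, 13))), "flanked")
  expect_error(domain_partition(list(a = c(10, 1))), "precedes")
})

test_that("COM distance series matches the generator's closed form", {
  h <- hinge_two_domain(c(10, 10), 3, 20, n_frames = 150, seed = 29)
  got <- com_distance_series(h$ensemble, h$partition)$distance
  expect_equal(got, hinge_com_closed_form(h$truth), tolerance = 1e-8)
  # translation invariance
  shifted <- h$ensemble
  for (f in seq_len(n_frames(shifted))) {
    shifted$coords[f, , ] <- sweep(shifted$coords[f, , ], 2, c(10, -5, 3), `+`)
  }
  expect_equal(com_distance_series(shifted, h$partition)$distance, got,
               tolerance = 1e-8)
})

test_that("two single-atom domains at fixed separation give a constant series", {
  coords <- array(0, c(3, 2, 3))
  coords[, 2, 1] <- 5
  ens <- new_ensemble(coords, c("CA", "CA"), 1:2)
  part <- domain_partition(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(com_distance_series(ens, part)$distance, rep(5, 3))
  expect_error(com_distance_series(ens, domain_partition(list(a = c(1, 2)))),
               "exactly 2")
})
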