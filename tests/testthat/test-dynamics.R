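test_that("ensemble superposition removes rigid-body motion", {
  st <- tiny_structure(10, seed = 2)
  frames <- lapply(1:5, function(i) {
    structure3d(st$id, st$residue_numbers, st$residue_codes,
                rigid_copy(st$coords, angle_deg = 15 * i, shift = c(2 * i, -i, 0)))
  })
  ens <- ensemble("toy", frames, 0:4)

  sup <- superpose_ensemble(ens, reference = st)
  for (f in sup$frames) expect_equal(f$coords, st$coords, tolerance = 1e-7)

  # reference = frame 1 leaves frame 1 unchanged
  sup1 <- superpose_ensemble(ens, reference = ens$frames[[1]])
  expect_equal(sup1$frames[[1]]$coords, ens$frames[[1]]$coords, tolerance = 1e-8)

  # fit-to-mean converges to mutually identical frames on rigid copies
  supm <- superpose_ensemble(ens, reference = "mean")
  for (f in supm$frames) {
    expect_equal(f$coords, supm$frames[[1]]$coords, tolerance = 1e-5)
  }
  expect_error(superpose_ensemble(ens, positions = 1:2), "at least 3")
})

test_that("dccm reproduces constructed co- and anti-motions", {
  # four residues far apart; residues 1+2 move together, 3 moves oppositely,
  # 4 is static up to a tiny fluctuation guard case
  base <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0), c(0, 0, 20))
  disp <- c(-1.5, -0.5, 0.5, 1.5)
  frames <- lapply(seq_along(disp), function(f) {
    xy <- base
    xy[1, 1] <- xy[1, 1] + disp[f]
    xy[2, 1] <- xy[2, 1] + disp[f]
    xy[3, 1] <- xy[3, 1] - disp[f]
    structure3d("toy", 1:4, c("A", "A", "A", "A"), xy)
  })
  ens <- ensemble("toy", frames, 0:3)
  expect_warning(dc <- dccm(ens), "zero fluctuation")
  expect_equal(diag(dc$matrix), rep(1, 4))
  expect_equal(dc$matrix[1, 2], 1, tolerance = 1e-12)
  expect_equal(dc$matrix[1, 3], -1, tolerance = 1e-12)
  expect_equal(dc$matrix[1, 4], 0)
  expect_true(all(dc$matrix >= -1 & dc$matrix <= 1))
  expect_equal(dc$matrix, t(dc$matrix))

  # 1x1 sets return the single entry
  expect_equal(inter_set_correlation(dc, 1, 3), dc$matrix[1, 3])
  expect_equal(inter_set_correlation(dc, c(1, 2), 3), mean(dc$matrix[1:2, 3]))
  expect_error(inter_set_correlation(dc, c(1, 2), c(2, 3)), "disjoint")
})

test_that("dccm is invariant to a common rigid transform applied before
           superposition, and matches the bio3d estimator", {
  fold <- make_two_domain_fold(16, 8, 16, seed = 5)
  ens <- make_hinge_ensemble(fold$structure, 20, 25, jitter_sigma = 0.2, seed = 3)
  sup <- superpose_ensemble(ens, "mean")
  dc <- dccm(sup)

  moved <- ensemble(ens$homolog_id, lapply(ens$frames, function(f) {
    structure3d(f$id, f$residue_numbers, f$residue_codes,
                rigid_copy(f$coords, 41, c(1, 1, 0), c(3, 3, 3)))
  }), ens$times_ns)
  dc2 <- dccm(superpose_ensemble(moved, "mean"))
  expect_equal(dc2$matrix, dc$matrix, tolerance = 1e-6)

  # independent cross-check against bio3d on the same superposed matrix
  xyz <- t(vapply(sup$frames, function(f) as.numeric(t(f$coords)),
                  numeric(3 * 40)))
  ref <- bio3d::dccm(xyz, method = "pearson")
  expect_equal(unclass(dc$matrix), unclass(ref), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("trajectory PCA recovers planted one-dimensional motion", {
  st <- tiny_structure(9, seed = 6)
  n <- nrow(st$coords)
  set.seed(10)
  v <- rnorm(3 * n); v <- v / sqrt(sum(v^2))
  amps <- seq(-2, 2, length.out = 7)
  frames <- lapply(amps, function(a) {
    structure3d(st$id, st$residue_numbers, st$residue_codes,
                st$coords + matrix(a * v, ncol = 3, byrow = TRUE))
  })
  ens <- ensemble("toy", frames, seq_along(amps))
  pca <- trajectory_pca(ens)
  expect_gte(pca$variance_fractions[1], 0.999)
  cosang <- abs(sum(pca$eigenvectors[, 1] * v))
  expect_gte(cosang, 0.999)
  expect_equal(sum(pca$variance_fractions), 1, tolerance = 1e-9)
  # projections are centred
  expect_equal(colMeans(pca$projections), rep(0, ncol(pca$projections)),
               tolerance = 1e-9)

  # identical frames: all eigenvalues zero
  flat <- ensemble("toy", lapply(1:4, function(i) st), 1:4)
  expect_equal(trajectory_pca(flat)$eigenvalues,
               rep(0, length(trajectory_pca(flat)$eigenvalues)),
               tolerance = 1e-12)
})

test_that("PCA reconstruction recovers the frames from all components", {
  fold <- make_two_domain_fold(12, 8, 12, seed = 9)
  ens <- make_hinge_ensemble(fold$structure, 16, 20, jitter_sigma = 0.3, seed = 4)
  sup <- superpose_ensemble(ens, "mean")
  pca <- trajectory_pca(sup)
  xyz <- t(vapply(sup$frames, function(f) as.numeric(t(f$coords)),
                  numeric(3 * 32)))
  recon <- sweep(pca$projections %*% t(pca$eigenvectors), 2,
                 -as.numeric(t(pca$mean_coords)))
  expect_equal(recon, xyz, tolerance = 1e-6, ignore_attr = TRUE)

  # eigenvalues and eigenvectors agree with the bio3d implementation
  ref <- bio3d::pca.xyz(xyz)
  k <- min(5, length(pca$eigenvalues))
  expect_equal(pca$eigenvalues[1:k], ref$L[1:k], tolerance = 1e-6)
  for (j in 1:2) {
    expect_equal(abs(sum(pca$eigenvectors[, j] * ref$U[, j])), 1, tolerance = 1e-6)
  }
})

test_that("PC1 projections track the true hinge angle", {
  dyn <- get_ref_dynamics()
  truth <- dyn$truth[dyn$truth$time_ns >= 20, ]
  rho <- cor(dyn$pca$projections[, 1], truth$angle_deg, method = "spearman")
  expect_gte(abs(rho), 0.95)
})

test_that("principal-motion interpolation is symmetric about the mean and
           monotone in hinge angle", {
  dyn <- get_ref_dynamics()
  interp <- pc_interpolate(dyn$pca, 1, n_steps = 11)
  mid <- interp$frames[[6]]
  expect_equal(mid$coords, dyn$pca$mean_coords, tolerance = 1e-9)
  # endpoints mirror each other through the mean
  expect_equal(interp$frames[[1]]$coords - dyn$pca$mean_coords,
               -(interp$frames[[11]]$coords - dyn$pca$mean_coords),
               tolerance = 1e-9)

  # hinge angle of domain B (after aligning on stable domain A) changes
  # monotonically along the component
  dom_a <- 21:75
  dom_b <- 138:192
  aligned <- superpose_ensemble(interp, reference = interp$frames[[1]],
                                positions = dom_a)
  angles <- vapply(seq_len(11), function(i) {
    oracle_rotation_angle(aligned$frames[[1]]$coords[dom_b, ],
                          aligned$frames[[i]]$coords[dom_b, ])
  }, numeric(1))
  expect_true(all(diff(angles) > -1e-6))

  expect_error(pc_interpolate(dyn$pca, length(dyn$pca$eigenvalues) + 1), "exceeds")
})
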