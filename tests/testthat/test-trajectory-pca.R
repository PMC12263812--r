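test_that("superpose recovers pure translations and rotations exactly", {
  ref <- random_structure(8, seed = 1)
  mob <- set_coords(ref, ref$xyz + matrix(c(5, 0, 0), ref$natoms, 3, byrow = TRUE))
  tr <- superpose(mob, ref)
  expect_equal(tr$rmsd, 0, tolerance = 1e-10)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tr$translation, c(-5, 0, 0), tolerance = 1e-10)

  r0 <- rotation_about_z(30 * pi / 180)
  mob2 <- set_coords(ref, ref$xyz %*% t(r0) + matrix(c(1, -2, 3), ref$natoms, 3, byrow = TRUE))
  tr2 <- superpose(mob2, ref)
  expect_equal(tr2$rmsd, 0, tolerance = 1e-8)
  ## recovered rotation inverts the applied one
  expect_equal(tr2$rotation, t(r0), tolerance = 1e-8)
  expect_equal(det(tr2$rotation), 1, tolerance = 1e-10)
})

test_that("superpose of a noisy copy matches the bio3d least-squares oracle", {
  set.seed(21)
  ref <- random_structure(5, seed = 21)
  noisy <- ref$xyz + matrix(stats::rnorm(15, sd = 0.1), 5, 3)
  rot <- oracle_rotation()
  mob <- noisy %*% t(rot) + matrix(c(2, 1, -1), 5, 3, byrow = TRUE)
  ours <- superpose(mob, ref$xyz, weights = rep(1, 5))
  ## independent oracle: bio3d rigid-body fit RMSD (reported to 3 decimals)
  oracle <- bio3d::rmsd(as.numeric(t(ref$xyz)), as.numeric(t(mob)), fit = TRUE)
  expect_lt(abs(ours$rmsd - oracle), 1e-3)
  ## and close to the injected noise RMS scale
  expect_lt(abs(ours$rmsd - sqrt(mean(rowSums((noisy - ref$xyz)^2)))), 0.05)
})

test_that("superpose errors on degenerate selections", {
  ref <- random_structure(6, seed = 2)
  mob <- ref
  expect_error(superpose(mob, ref, sel = c(1, 2)), "degenerate|3 non-collinear")
  collinear <- set_coords(ref, cbind(1:6, 0, 0))
  expect_error(superpose(collinear, collinear), "degenerate|non-collinear")
  expect_error(superpose(mob, ref, sel = integer(0)), "empty")
})

test_that("superpose RMSD is invariant to pre-applied rigid transforms of mobile", {
  ref <- random_structure(10, seed = 4)
  set.seed(7)
  mob <- set_coords(ref, ref$xyz + matrix(stats::rnorm(30, sd = 0.5), 10, 3))
  base <- superpose(mob, ref)$rmsd
  for (i in 1:5) {
    rot <- oracle_rotation()
    shifted <- set_coords(mob, mob$xyz %*% t(rot) +
                            matrix(stats::runif(3, -8, 8), 10, 3, byrow = TRUE))
    expect_equal(superpose(shifted, ref)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("fitting removes pure rigid motion and is idempotent", {
  m <- make_planted_receptor(10, c(1e-16, 1e-16), seed = 5)
  tr <- sample_trajectory(m, 6, rigid_motion = TRUE, seed = 6)
  ft <- fit_trajectory(tr)
  spread <- apply(ft$xyz, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-6)
  ft2 <- fit_trajectory(ft)
  expect_lt(max(abs(ft2$xyz - ft$xyz)), 1e-10)
})

test_that("fitted covariance equals the covariance of the motion-free trajectory", {
  m <- make_planted_receptor(12, c(4, 2, 0.5), seed = 11)
  with_motion <- sample_trajectory(m, 400, rigid_motion = TRUE, seed = 13)
  without <- sample_trajectory(m, 400, rigid_motion = FALSE, seed = 13)
  cf <- stats::cov(fit_trajectory(with_motion, m$structure)$xyz)
  c0 <- stats::cov(fit_trajectory(without, m$structure)$xyz)
  expect_lt(norm(cf - c0, "F") / norm(c0, "F"), 1e-6)
})

test_that("rank-1 displacement data yields a single mode along the moved coordinate", {
  atom <- data.frame(atom_name = c("C1", "C2"), element = "C",
                     residue_name = "SYN", residue_id = 1:2, chain_id = "A")
  base <- rbind(c(0, 0, 0), c(3, 0, 0))
  xyz <- rbind(as.numeric(t(base + rbind(c(-0.5, 0, 0), 0))),
               as.numeric(t(base)),
               as.numeric(t(base + rbind(c(0.5, 0, 0), 0))))
  tr <- lrd_trajectory(atom, xyz)
  b <- pca_modes(tr, 1)
  expect_equal(b$eigenvalues, stats::var(c(-0.5, 0, 0.5)), tolerance = 1e-12)
  expect_equal(abs(b$eigenvectors[1, 1]), 1, tolerance = 1e-12)
  expect_lt(max(abs(b$eigenvectors[-1, 1])), 1e-12)
  ## total variance equals the single eigenvalue here
  expect_equal(msf_fraction(b, 1), 1, tolerance = 1e-12)
})

test_that("snapshot-SVD PCA is numerically identical to the dense covariance route", {
  m <- make_planted_receptor(8, c(3, 1, 0.3), seed = 17)
  tr <- sample_trajectory(m, 60, seed = 18)
  ft <- fit_trajectory(tr, m$structure)
  b <- pca_modes(ft, 5)
  dense <- eigen(stats::cov(ft$xyz), symmetric = TRUE)
  expect_equal(b$eigenvalues, dense$values[1:5], tolerance = 1e-10)
  for (k in 1:5) {
    expect_equal(abs(sum(b$eigenvectors[, k] * dense$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  ## trace identity: all eigenvalues sum to the total MSF
  expect_equal(pca_modes(ft, min(3 * 8, 59))$total_variance,
               sum(dense$values), tolerance = 1e-8)
  ## requesting too many modes errors
  expect_error(pca_modes(ft, 60), "n_modes")
})

test_that("pca eigenvalues are nonnegative descending with orthonormal vectors", {
  m <- make_planted_receptor(7, c(5, 2, 1, 0.5), seed = 23)
  ft <- fit_trajectory(sample_trajectory(m, 80, seed = 24), m$structure)
  b <- pca_modes(ft, 6)
  expect_true(all(diff(b$eigenvalues) <= 1e-12))
  expect_true(all(b$eigenvalues > 0))
  expect_lt(max(abs(crossprod(b$eigenvectors) - diag(6))), 1e-10)
})

test_that("closest_to_average picks the frame nearest the ensemble mean", {
  m <- make_planted_receptor(6, c(2, 1), seed = 31)
  tr <- sample_trajectory(m, 40, seed = 32)
  ## brute-force oracle
  avg <- colMeans(tr$xyz)
  oracle <- which.min(vapply(seq_len(tr$n_frames), function(f) {
    sqrt(mean((tr$xyz[f, ] - avg)^2))
  }, numeric(1)))
  expect_identical(closest_to_average(tr), oracle)

  ## symmetric three-frame trajectory: middle frame wins
  v <- m$basis$eigenvectors[, 1]
  xyz <- rbind(m$basis$reference_coords - v,
               m$basis$reference_coords,
               m$basis$reference_coords + v)
  tr3 <- lrd_trajectory(m$structure$atom, xyz)
  expect_identical(closest_to_average(tr3), 2L)

  ## a trajectory containing its own average returns that frame
  xyz2 <- rbind(tr$xyz[1:5, ], colMeans(tr$xyz[1:5, ]))
  xyz2[6, ] <- colMeans(xyz2)  # fixed point: frame 6 equals mean of all 6
  for (i in 1:50) xyz2[6, ] <- colMeans(xyz2)
  tr6 <- lrd_trajectory(m$structure$atom, xyz2)
  expect_identical(closest_to_average(tr6), 6L)
})

test_that("projections agree with the dense matrix-product oracle", {
  m <- make_planted_receptor(9, c(4, 2, 1), seed = 41)
  b <- m$basis
  ## displacement aligned with a single mode
  d <- 2.5 * b$eigenvectors[, 2]
  p <- project_modes(d, b, modes = 1:3)
  expect_equal(as.numeric(p), c(0, 2.5, 0), tolerance = 1e-10)
  expect_equal(as.numeric(project_modes(numeric(27), b, modes = 1:3)),
               rep(0, 3), tolerance = 1e-15)
  ## random displacement: dense oracle
  set.seed(42)
  d2 <- stats::rnorm(27)
  oracle <- as.numeric(t(b$eigenvectors[, 1:3]) %*% d2)
  expect_equal(as.numeric(project_modes(d2, b, modes = 1:3)), oracle,
               tolerance = 1e-10)
  ## absolute coordinates subtract the reference
  s <- set_coords(m$structure, as_coord_mat(b$reference_coords + d))
  expect_equal(as.numeric(project_modes(s, b, modes = 2)), 2.5, tolerance = 1e-10)
  expect_error(project_modes(d, b, modes = 4), "out of range")
})

test_that("extreme structures are the frames with extreme projections", {
  m <- make_planted_receptor(6, c(3, 1), seed = 51)
  tr <- sample_trajectory(m, 30, seed = 52)
  ft <- fit_trajectory(tr, m$structure)
  b <- pca_modes(ft, 2)
  p <- project_modes(ft, b, modes = 1)[, 1]
  ex <- extreme_structures(ft, b, mode = 1)
  expect_identical(ex$min_frame, which.min(p))
  expect_identical(ex$max_frame, which.max(p))
  expect_equal(as_xyz_vec(ex$min$xyz), ft$xyz[which.min(p), ], tolerance = 1e-12)
  ## flipping the eigenvector sign swaps min and max
  b2 <- b
  b2$eigenvectors[, 1] <- -b2$eigenvectors[, 1]
  ex2 <- extreme_structures(ft, b2, mode = 1)
  expect_identical(ex2$min_frame, ex$max_frame)
  expect_identical(ex2$max_frame, ex$min_frame)

  ## monotone projections give first and last frames
  v <- m$basis$eigenvectors[, 1]
  xyz <- t(vapply(seq(-1, 1, length.out = 5), function(a) {
    m$basis$reference_coords + a * v
  }, numeric(18)))
  trm <- lrd_trajectory(m$structure$atom, xyz)
  exm <- extreme_structures(trm, m$basis, mode = 1)
  expect_identical(c(exm$min_frame, exm$max_frame), c(1L, 5L))
})

test_that("rmsip is 1 for identical subspaces, 0 for orthogonal, invariant in-span", {
  m <- make_planted_receptor(10, c(5, 3, 2, 1), seed = 61)
  b <- m$basis
  expect_equal(rmsip(b, b, 4), 1, tolerance = 1e-12)

  ## orthogonal subspaces from one orthonormal frame
  q <- qr.Q(qr(matrix(stats::rnorm(30 * 4), 30, 4)))
  ba <- mode_basis(matrix(0, 10, 3), c(2, 1), q[, 1:2])
  bb <- mode_basis(matrix(0, 10, 3), c(2, 1), q[, 3:4])
  expect_equal(rmsip(ba, bb, 2), 0, tolerance = 1e-12)

  ## random rotation within the same span leaves RMSIP at 1
  set.seed(62)
  g <- qr.Q(qr(matrix(stats::rnorm(4), 2, 2)))
  br <- mode_basis(matrix(0, 10, 3), c(2, 1), q[, 1:2] %*% g)
  expect_equal(rmsip(ba, br, 2), 1, tolerance = 1e-10)

  ## symmetry and bounds on random bases
  for (i in 1:5) {
    qa <- qr.Q(qr(matrix(stats::rnorm(30 * 3), 30, 3)))
    qb <- qr.Q(qr(matrix(stats::rnorm(30 * 3), 30, 3)))
    xa <- mode_basis(matrix(0, 10, 3), c(3, 2, 1), qa)
    xb <- mode_basis(matrix(0, 10, 3), c(3, 2, 1), qb)
    r <- rmsip(xa, xb, 3)
    expect_equal(r, rmsip(xb, xa, 3), tolerance = 1e-12)
    expect_gte(r, 0)
    expect_lte(r, 1 + 1e-12)
  }
  expect_error(rmsip(ba, bb, 3), "mode count")
})

test_that("msf_fraction is the cumulative eigenvalue share of the trace", {
  b <- mode_basis(matrix(0, 4, 3), c(4, 3, 2, 1),
                  qr.Q(qr(matrix(stats::rnorm(48), 12, 4))),
                  total_variance = 10)
  expect_equal(msf_fraction(b, 2), 0.7, tolerance = 1e-12)
  expect_equal(msf_fraction(b, 4), 1, tolerance = 1e-12)
  expect_error(msf_fraction(b, 5), "between 1 and M")
})
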