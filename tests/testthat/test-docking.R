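test_that("rigid poses reproduce their reference exactly and validate rotations", {
  ref <- random_structure(5, seed = 101)$xyz
  p <- rigid_pose(ref)
  expect_identical(pose_coords(p), ref)
  expect_error(rigid_pose(ref, rotation = diag(3) * 1.1), "orthonormal")
  bad <- diag(3); bad[1, 1] <- -1   # improper reflection
  expect_error(rigid_pose(ref, rotation = bad), "orthonormal")
})

test_that("rigid steps translate with the force and rotate about the torque axis", {
  ref <- random_structure(4, seed = 102)$xyz
  p <- rigid_pose(ref)
  piv <- colMeans(ref)
  ## zero force and torque: unchanged
  p0 <- rigid_step(p, c(0, 0, 0), c(0, 0, 0), piv)
  expect_equal(pose_coords(p0), ref, tolerance = 1e-14)
  ## pure +x force below the clamp: translation exactly step_t * force
  p1 <- rigid_step(p, c(2, 0, 0), c(0, 0, 0), piv, step_t = 0.02, max_t = 1)
  expect_equal(pose_coords(p1), ref + matrix(c(0.04, 0, 0), 4, 3, byrow = TRUE),
               tolerance = 1e-12)
  ## clamped translation has length max_t
  p2 <- rigid_step(p, c(100, 0, 0), c(0, 0, 0), piv, step_t = 0.02, max_t = 0.1)
  expect_equal(pose_coords(p2)[1, ] - ref[1, ], c(0.1, 0, 0), tolerance = 1e-12)

  ## pure z torque on a planar triangle rotates about the pivot by step_r*|tau|
  tri <- rbind(c(1, 0, 0), c(-0.5, 0.8, 0), c(-0.5, -0.8, 0))
  pt <- rigid_pose(tri)
  tau <- c(0, 0, 3)
  ang <- 0.005 * 3
  p3 <- rigid_step(pt, c(0, 0, 0), tau, pivot = c(0, 0, 0),
                   step_r = 0.005, max_r = 1)
  oracle <- tri %*% t(rotation_about_z(ang))
  expect_equal(pose_coords(p3), oracle, tolerance = 1e-10)
  ## rotation angle clamps at max_r
  p4 <- rigid_step(pt, c(0, 0, 0), c(0, 0, 1000), pivot = c(0, 0, 0),
                   step_r = 0.005, max_r = 0.02)
  expect_equal(pose_coords(p4), tri %*% t(rotation_about_z(0.02)), tolerance = 1e-10)
})

test_that("rmsd_to_ghost is the plain fixed-frame RMSD", {
  lig <- random_structure(6, seed = 103, resname = "LIG", chain = "B")
  expect_equal(rmsd_to_ghost(lig, lig), 0, tolerance = 1e-15)
  shifted <- set_coords(lig, lig$xyz + matrix(c(3, 4, 0), 6, 3, byrow = TRUE))
  expect_equal(rmsd_to_ghost(shifted, lig), 5, tolerance = 1e-12)
  ## brute-force per-atom oracle on a random pose
  set.seed(104)
  pose <- rigid_pose(lig$xyz, oracle_rotation(), stats::runif(3, -5, 5))
  x <- pose_coords(pose)
  oracle <- sqrt(sum((x - lig$xyz)^2) / 6)
  expect_equal(rmsd_to_ghost(pose, lig), oracle, tolerance = 1e-12)
  ## invariance under a joint rigid transform of pose and ghost
  rot <- oracle_rotation(); tr <- c(2, -7, 1)
  expect_equal(rmsd_to_ghost(apply_transform(x, rot, tr),
                             set_coords(lig, apply_transform(lig$xyz, rot, tr))),
               oracle, tolerance = 1e-9)
  expect_error(rmsd_to_ghost(lig, random_structure(5)), "atom counts differ")
})

test_that("heavy-only ghost RMSD drops hydrogens", {
  atom <- data.frame(atom_name = c("C1", "H1"), element = c("C", "H"),
                     residue_name = "LIG", residue_id = 1L, chain_id = "B")
  g <- lrd_structure(atom, rbind(c(0, 0, 0), c(1, 0, 0)))
  moved <- rbind(c(0, 0, 0), c(9, 0, 0))  # only the hydrogen moved
  expect_equal(rmsd_to_ghost(moved, g, heavy_only = TRUE), 0, tolerance = 1e-15)
  expect_gt(rmsd_to_ghost(moved, g), 1)
})

test_that("ghost placement applies the protein superposition to the bound ligand", {
  ## build a fake holo: receptor protein + ligand appended
  n_res <- 8
  atom <- data.frame(
    atom_name = rep("CA", n_res), element = "C", residue_name = "GLY",
    residue_id = seq_len(n_res), chain_id = "A", stringsAsFactors = FALSE)
  set.seed(105)
  rec <- lrd_structure(atom, matrix(stats::rnorm(n_res * 3, sd = 6), n_res, 3))
  lig_atom <- data.frame(atom_name = c("C1", "O1"), element = c("C", "O"),
                         residue_name = "LIG", residue_id = 100L, chain_id = "B")
  lig_xyz <- rbind(c(1, 1, 1), c(2, 1, 0))
  holo <- lrd_structure(rbind(atom, lig_atom), rbind(rec$xyz, lig_xyz))

  ## identity case: ghost equals the appended ligand exactly
  g0 <- place_ghost(holo, rec, "LIG")
  expect_equal(g0$xyz, lig_xyz, tolerance = 1e-10)
  expect_equal(attr(g0, "superposition_rmsd"), 0, tolerance = 1e-10)
  expect_identical(attr(g0, "n_matched"), 8L)

  ## rigidly transformed holo: ghost still lands on the original ligand
  rot <- oracle_rotation(); tr <- c(4, -3, 9)
  holo2 <- set_coords(holo, apply_transform(holo$xyz, rot, tr))
  g2 <- place_ghost(holo2, rec, "LIG")
  expect_lt(max(abs(g2$xyz - lig_xyz)), 1e-8)
  expect_lt(attr(g2, "superposition_rmsd"), 1e-8)

  ## too few matched alpha-carbons
  rec2 <- subset_structure(rec, 1:2)
  expect_error(place_ghost(holo, rec2, "LIG"), "fewer than 3")
})

test_that("contact counting thresholds, excludes hydrogens and matches brute force", {
  mk <- function(xyz, el) {
    lrd_structure(data.frame(atom_name = paste0(el, seq_along(el)), element = el,
                             residue_name = "X", residue_id = seq_along(el),
                             chain_id = "A"), xyz)
  }
  a <- mk(rbind(c(0, 0, 0)), "C")
  expect_identical(contact_count(mk(rbind(c(3.9, 0, 0)), "C"), a), 1L)
  expect_identical(contact_count(mk(rbind(c(4.1, 0, 0)), "C"), a), 0L)
  ## hydrogens never count
  hlig <- mk(rbind(c(1, 0, 0)), "H")
  expect_error(contact_count(hlig, a), "empty heavy-atom")
  both <- mk(rbind(c(1, 0, 0), c(2, 0, 0)), c("H", "C"))
  expect_identical(contact_count(both, a), 1L)

  ## random configuration vs double-loop oracle
  set.seed(106)
  rec <- random_structure(12, seed = 106)
  lig <- random_structure(7, seed = 107, resname = "LIG", chain = "B")
  oracle <- 0L
  for (i in which(lig$is_heavy)) {
    for (j in which(rec$is_heavy)) {
      if (sqrt(sum((lig$xyz[i, ] - rec$xyz[j, ])^2)) <= 4) oracle <- oracle + 1L
    }
  }
  expect_identical(contact_count(lig, rec, 4), oracle)
  ## name-based cap selection restricts the ligand side
  sel_names <- lig$atom$atom_name[1:3]
  oracle_sel <- 0L
  for (i in intersect(which(lig$is_heavy), 1:3)) {
    for (j in which(rec$is_heavy)) {
      if (sqrt(sum((lig$xyz[i, ] - rec$xyz[j, ])^2)) <= 4) oracle_sel <- oracle_sel + 1L
    }
  }
  expect_identical(contact_count(lig, rec, 4, ligand_sel = sel_names), oracle_sel)
})

test_that("polar-contact report applies the distance threshold and element filter", {
  mk <- function(names, els, resn, resid, xyz) {
    lrd_structure(data.frame(atom_name = names, element = els,
                             residue_name = resn, residue_id = resid,
                             chain_id = "A"), xyz)
  }
  a <- mk("OH", "O", "TYR", 745L, rbind(c(0, 0, 0)))
  expect_identical(nrow(hbond_report(a, mk("O1", "O", "LIG", 1L, rbind(c(2.8, 0, 0))))), 1L)
  expect_identical(nrow(hbond_report(a, mk("O1", "O", "LIG", 1L, rbind(c(3.8, 0, 0))))), 0L)
  expect_identical(nrow(hbond_report(a, mk("C1", "C", "LIG", 1L, rbind(c(2.8, 0, 0))))), 0L)

  ## constructed gatekeeper-tyrosine / hydroxamate geometry: exactly one bond
  tyr <- mk(c("CZ", "OH"), c("C", "O"), "TYR", 745L,
            rbind(c(-1.4, 0, 0), c(0, 0, 0)))
  hydroxamate <- mk(c("C9", "O2", "N1", "O3"), c("C", "O", "N", "O"), "LIG", 1L,
                    rbind(c(4.0, 2.0, 0), c(2.7, 0.5, 0), c(4.9, 0.8, 0), c(6.0, 0, 0)))
  rep1 <- hbond_report(tyr, hydroxamate)
  expect_identical(nrow(rep1), 1L)
  expect_identical(rep1$atom_a, "TYR745-OH")
  expect_identical(rep1$atom_b, "LIG1-O2")
  expect_equal(rep1$distance, sqrt(2.7^2 + 0.5^2), tolerance = 1e-10)
})

test_that("a single-atom ligand descends to the pair-potential minimum distance", {
  rec <- point_particle(c(0, 0, 0), sigma = 3.0, epsilon = 0.2)
  lig <- point_particle(c(5, 0, 0), sigma = 3.0, epsilon = 0.2,
                        resname = "LIG", chain = "B")
  tiny_basis <- mode_basis(matrix(0, 1, 3), 1e-8, matrix(c(1, 0, 0), 3, 1))
  tr <- auto_dock(rec$structure, rec$topology, tiny_basis, lig$structure,
                  lig$topology,
                  config = run_config(docking = list(f_tol = 1e-3, max_steps = 2000)))
  expect_identical(attr(tr, "termination"), "converged")
  final_d <- sqrt(sum(pose_coords(attr(tr, "final_pose"))^2))
  expect_equal(final_d, 2^(1 / 6) * 3.0, tolerance = 1e-3)
})

test_that("the ghost never contributes to docking energetics", {
  f <- make_funnel_complex(seed = 3)
  start <- rigid_pose(f$ligand$xyz, diag(3), c(0.5, -0.3, 0.4))
  no_ghost <- auto_dock(f$structure, f$topology, f$basis, f$ligand,
                        f$ligand_topology, start_pose = start)
  with_ghost <- auto_dock(f$structure, f$topology, f$basis, f$ligand,
                          f$ligand_topology, start_pose = start, ghost = f$ligand)
  expect_equal(with_ghost$e_total, no_ghost$e_total, tolerance = 1e-12)
  expect_equal(pose_coords(attr(with_ghost, "final_pose")),
               pose_coords(attr(no_ghost, "final_pose")), tolerance = 1e-12)
  ## the ghost run does report per-step RMSD
  expect_true(all(is.finite(with_ghost$rmsd_to_ghost)))
  expect_true(all(is.na(no_ghost$rmsd_to_ghost)))
})

test_that("docking traces honour the quasi-static contract and energy monotonicity", {
  f <- make_funnel_complex(seed = 3)
  start <- rigid_pose(f$ligand$xyz, diag(3), c(0.8, 0.2, -0.5))
  cfg <- run_config()
  tr <- auto_dock(f$structure, f$topology, f$basis, f$ligand, f$ligand_topology,
                  start_pose = start, config = cfg, ghost = f$ligand)
  ## receptor residual within solver tolerance at every recorded step
  expect_true(all(tr$residual <= cfg$solver$tol))
  ## total energy non-increasing across accepted steps (convex toy funnel)
  expect_true(all(diff(tr$e_total) <= 1e-9))
  ## breakdown identity at every step
  expect_equal(tr$e_total, tr$e_interaction + tr$e_strain, tolerance = 1e-10)
  expect_gte(nrow(tr), 1L)
  expect_identical(attr(tr, "termination"), "converged")
})

test_that("barrier estimate is the path maximum relative to the start", {
  e <- c(-5, -2, 1.5, -0.5, -8)
  fake <- data.frame(step = 1:5, e_total = e)
  class(fake) <- c("lrd_docking_trace", class(fake))
  be <- barrier_estimate(fake)
  expect_equal(be$barrier, 6.5, tolerance = 1e-12)
  expect_identical(be$peak_step, 3L)
  expect_equal(be$final_energy, -8)
})
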