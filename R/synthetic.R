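## Seeded synthetic fixtures: planted-covariance receptors emulating an MD
## ensemble, and desk-scale receptor--ligand "funnel" complexes whose global
## minimum pose is known by construction. Everything is deterministic per
## seed and all generators draw through an isolated RNG scope.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

.synth_atom_table <- function(elements, residue_name = "SYN", chain = "A") {
  n <- length(elements)
  data.frame(
    atom_name = paste0(elements, seq_len(n)),
    element = elements,
    residue_name = residue_name,
    residue_id = seq_len(n),
    chain_id = chain,
    stringsAsFactors = FALSE
  )
}

#' Synthetic receptor with a planted covariance spectrum
#'
#' Builds a non-degenerate random geometry (jittered grid, guaranteed
#' minimum separation), a random orthonormal mode basis carrying exactly
#' the requested eigenvalue spectrum, and nonbonded parameters drawn from
#' small fixed palettes. The basis is the ground truth against which PCA
#' recovery and linear-response oracles are checked. Fully deterministic
#' per seed.
#'
#' @param n_atoms number of atoms (>= 4).
#' @param spectrum planted covariance eigenvalues, Angstrom^2, descending
#'   (length <= 3 n_atoms).
#' @param seed integer seed.
#' @param temperature Kelvin, stored in the basis.
#' @return List of class `lrd_planted_model` with `structure`,
#'   `topology`, `basis`, `seed`.
#' @export
make_planted_receptor <- function(n_atoms, spectrum, seed, temperature = 300) {
  stopifnot(n_atoms >= 4L, length(spectrum) >= 1L,
            length(spectrum) <= 3L * n_atoms, all(spectrum > 0))
  spectrum <- sort(as.numeric(spectrum), decreasing = TRUE)
  with_seed(seed, {
    side <- ceiling(n_atoms^(1 / 3))
    g <- as.matrix(expand.grid(x = seq_len(side + 1L), y = seq_len(side + 1L),
                               z = seq_len(side + 1L))) * 3.0
    g <- g[sample(nrow(g)), , drop = FALSE][seq_len(n_atoms), , drop = FALSE]
    xyz <- g + matrix(stats::runif(3L * n_atoms, -0.5, 0.5), n_atoms, 3L)
    xyz <- sweep(xyz, 2L, colMeans(xyz))
    elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE)
    structure <- lrd_structure(.synth_atom_table(elements, "REC"), xyz)
    topology <- lrd_topology(
      charge = sample(c(-0.5, -0.25, 0, 0.25, 0.5), n_atoms, replace = TRUE),
      sigma = sample(c(2.5, 3.0, 3.5), n_atoms, replace = TRUE),
      epsilon = sample(c(0.05, 0.1, 0.15, 0.2), n_atoms, replace = TRUE),
      combination_rule = "lorentz_berthelot"
    )
    m <- length(spectrum)
    ## plant eigenvectors in the orthogonal complement of the rigid-body
    ## subspace (3 translations + 3 infinitesimal rotations about the
    ## centroid): internal displacement modes of a fitted ensemble carry
    ## no net translation or rotation, and superposition would otherwise
    ## strip the rigid components and bias the recovered spectrum low
    rigid <- matrix(0, 3L * n_atoms, 6L)
    for (k in 1:3) rigid[seq(k, 3L * n_atoms, by = 3L), k] <- 1
    for (i in seq_len(n_atoms)) {
      r <- xyz[i, ]
      rows <- 3L * (i - 1L) + 1:3
      rigid[rows, 4L] <- c(0, -r[3L], r[2L])   # rotation about x
      rigid[rows, 5L] <- c(r[3L], 0, -r[1L])   # rotation about y
      rigid[rows, 6L] <- c(-r[2L], r[1L], 0)   # rotation about z
    }
    qb <- qr.Q(qr(rigid))
    raw <- matrix(stats::rnorm(3L * n_atoms * m), 3L * n_atoms, m)
    raw <- raw - qb %*% crossprod(qb, raw)
    v <- qr.Q(qr(raw))
    basis <- mode_basis(xyz, spectrum, v, temperature = temperature,
                        total_variance = sum(spectrum))
    out <- list(structure = structure, topology = topology, basis = basis,
                seed = seed)
    class(out) <- "lrd_planted_model"
    out
  })
}

#' Sample a Gaussian trajectory from a planted model
#'
#' Frames are r_o + sum_i a_i V_i with mode amplitudes a_i drawn
#' independently per frame from Normal(0, lambda_i) -- exactly the
#' statistical model under which the displacement covariance equals
#' V lambda V^t, so parameter recovery by [pca_modes()] is a fair test.
#' Optionally each frame additionally receives a random rigid rotation
#' and translation to exercise trajectory fitting; the amplitude draws
#' are identical for the same seed whether or not rigid motion is added.
#'
#' @param model an `lrd_planted_model`.
#' @param n_frames number of frames (>= 2).
#' @param rigid_motion inject per-frame random rigid transforms.
#' @param seed integer seed.
#' @return An [lrd_trajectory()].
#' @export
sample_trajectory <- function(model, n_frames, rigid_motion = FALSE, seed = 1L) {
  stopifnot(n_frames >= 2L)
  basis <- model$basis
  m <- basis$n_modes
  with_seed(seed, {
    amp <- matrix(stats::rnorm(n_frames * m), n_frames, m)
    amp <- sweep(amp, 2L, sqrt(basis$eigenvalues), "*")
    xyz <- amp %*% t(basis$eigenvectors)
    xyz <- sweep(xyz, 2L, basis$reference_coords, "+")
    if (rigid_motion) {
      for (f in seq_len(n_frames)) {
        rot <- .random_rotation()
        tr <- stats::runif(3L, -5, 5)
        xyz[f, ] <- as_xyz_vec(apply_transform(as_coord_mat(xyz[f, ]), rot, tr))
      }
    }
    lrd_trajectory(model$structure$atom, xyz, mass = model$structure$mass)
  })
}

## interaction energy of a ligand pose against a (rigid) funnel receptor
.pose_energy <- function(model, pose) {
  interaction_energy(model$structure, model$topology,
                     set_coords(model$ligand, pose_coords(pose)),
                     model$ligand_topology,
                     cutoff = 1e6, dielectric = dielectric_linear())
}

## local rigid minimisation of interaction energy over 6 pose parameters
## (translation + rotation vector composed onto the start pose)
.polish_pose <- function(model, pose) {
  com <- colMeans(pose_coords(pose))
  fn <- function(p) {
    rot <- if (sqrt(sum(p[4:6]^2)) > 1e-12) {
      .axis_angle_matrix(p[4:6] / sqrt(sum(p[4:6]^2)), sqrt(sum(p[4:6]^2)))
    } else diag(3)
    cand <- rigid_pose(pose$reference_coords,
                       rot %*% pose$rotation,
                       as.numeric(rot %*% (pose$translation - com)) + com + p[1:3])
    e <- .pose_energy(model, cand)
    e$lj + e$electrostatic
  }
  opt <- stats::optim(rep(0, 6L), fn, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  p <- opt$par
  rot <- if (sqrt(sum(p[4:6]^2)) > 1e-12) {
    .axis_angle_matrix(p[4:6] / sqrt(sum(p[4:6]^2)), sqrt(sum(p[4:6]^2)))
  } else diag(3)
  list(pose = rigid_pose(pose$reference_coords,
                         rot %*% pose$rotation,
                         as.numeric(rot %*% (pose$translation - com)) + com + p[1:3]),
       energy = opt$value)
}

## Fibonacci sphere points
.fib_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Synthetic receptor--ligand complex with a known global-minimum pose
#'
#' Builds a cage receptor (an attractive spherical shell with an aperture
#' towards +z) whose interior hosts the global minimum of the rigid-body
#' interaction energy. The pair minimum distance is matched to the shell
#' radius so the cage centre region is strongly favoured; the exact
#' planted pose is found by local minimisation at generation time and
#' then verified to be the global minimum by a seeded random scan over
#' poses (an error is raised if the scan finds anything lower).
#'
#' With `two_minimum = TRUE` a single-atom ligand and a tightened
#' aperture rim produce a second, shallower minimum at the cage mouth
#' separated from the interior minimum by a repulsive neck -- a
#' desk-scale emulation of an intermediate binding pose with an energy
#' barrier in front of the fully inserted pose. The mouth pose, the
#' on-axis scan, and a ready-made bias (push direction, magnitude and
#' step count that carry the ligand over the neck) are returned.
#'
#' @param seed integer seed.
#' @param two_minimum build the two-minimum (mouth + interior) variant.
#' @param n_scan number of random poses in the global-minimum
#'   verification scan.
#' @return List of class `lrd_planted_model` with `structure`,
#'   `topology`, `basis`, `ligand`, `ligand_topology`, `planted_pose`
#'   (identity pose on the planted ligand coordinates),
#'   `planted_energy`, `scan_min_energy`; for the two-minimum variant
#'   also `mouth_pose`, `mouth_energy`, `barrier_energy` (on-axis neck
#'   maximum) and `bias`.
#' @export
make_funnel_complex <- function(seed, two_minimum = FALSE, n_scan = 2000L) {
  with_seed(seed, {
    r_shell <- 6.0
    sigma_pair <- r_shell / 2^(1 / 6)      # pair minimum at the shell radius
    aperture <- if (two_minimum) 50 else 45  # degrees of polar angle removed
    pts <- .fib_sphere(60L, r_shell)
    polar <- acos(pmin(1, pmax(-1, pts[, 3L] / r_shell))) * 180 / pi
    pts <- pts[polar > aperture, , drop = FALSE]
    if (two_minimum) {
      ## explicit rim ring tightening the neck
      ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
      ## ring radius sized so the on-axis neck is mildly repulsive
      ## (about +0.5 kcal/mol per rim atom), giving a barrier of a few
      ## kcal/mol rather than a hard wall
      rim_rho <- 4.83
      rim_z <- r_shell * cos(aperture * pi / 180)
      rim <- cbind(rim_rho * cos(ang), rim_rho * sin(ang), rim_z)
      pts <- rbind(pts, rim)
    }
    n_rec <- nrow(pts)
    elements <- rep(c("C", "N", "O"), length.out = n_rec)
    receptor <- lrd_structure(.synth_atom_table(elements, "REC"), pts)
    eps_rec <- if (two_minimum) 0.08 else 0.12
    topology <- lrd_topology(
      charge = rep(0, n_rec), sigma = rep(sigma_pair, n_rec),
      epsilon = rep(eps_rec, n_rec), combination_rule = "lorentz_berthelot"
    )
    ## nearly rigid receptor: small planted spectrum, M = 2
    v <- qr.Q(qr(matrix(stats::rnorm(3L * n_rec * 2L), 3L * n_rec, 2L)))
    basis <- mode_basis(pts, c(0.02, 0.01), v, temperature = 300,
                        total_variance = 0.03)

    if (two_minimum) {
      lig_xyz <- matrix(c(0, 0, 0), 1L, 3L)
      lig_el <- "C"
    } else {
      a <- 1.0 / sqrt(3)
      lig_xyz <- rbind(c(a, a, a), c(a, -a, -a), c(-a, a, -a), c(-a, -a, a))
      lig_el <- c("C", "N", "O", "C")
    }
    ligand0 <- lrd_structure(.synth_atom_table(lig_el, "LIG", chain = "B"), lig_xyz)
    ligand_topology <- lrd_topology(
      charge = rep(0, nrow(lig_xyz)), sigma = rep(sigma_pair, nrow(lig_xyz)),
      epsilon = rep(eps_rec, nrow(lig_xyz)), combination_rule = "lorentz_berthelot"
    )
    model <- list(structure = receptor, topology = topology, basis = basis,
                  ligand = ligand0, ligand_topology = ligand_topology,
                  seed = seed)

    ## plant the interior pose: polish from the cage centre region
    start <- rigid_pose(ligand0$xyz, translation = c(0, 0, -0.5))
    pol <- .polish_pose(model, start)
    planted_xyz <- pose_coords(pol$pose)
    model$ligand <- set_coords(ligand0, planted_xyz)
    model$planted_pose <- rigid_pose(planted_xyz)
    model$planted_energy <- pol$energy

    if (two_minimum) {
      axis_z <- seq(-4, 12, by = 0.05)
      e_axis <- vapply(axis_z, function(z) {
        e <- .pose_energy(model, rigid_pose(planted_xyz,
                                            translation = c(0, 0, z) - planted_xyz[1, ]))
        e$lj + e$electrostatic
      }, numeric(1L))
      zi <- planted_xyz[1L, 3L]
      outer_ix <- which(axis_z > rim_z + 0.5)
      mouth_ix <- outer_ix[which.min(e_axis[outer_ix])]
      mouth_z <- axis_z[mouth_ix]
      between <- which(axis_z > zi & axis_z < mouth_z)
      bar_ix <- between[which.max(e_axis[between])]
      mouth_start <- rigid_pose(planted_xyz,
                                translation = c(0, 0, mouth_z) - planted_xyz[1, ])
      mpol <- .polish_pose(model, mouth_start)
      model$mouth_pose <- mpol$pose
      model$mouth_energy <- mpol$energy
      model$barrier_energy <- e_axis[bar_ix]
      if (!(model$planted_energy < model$mouth_energy &&
            model$mouth_energy < model$barrier_energy)) {
        stop("two-minimum landscape verification failed: ",
             sprintf("interior %.3f, mouth %.3f, neck %.3f kcal/mol",
                     model$planted_energy, model$mouth_energy, model$barrier_energy))
      }
      ## push strength: comfortably above the steepest uphill slope on
      ## the mouth -> interior segment of the axis scan
      seg <- which(axis_z >= zi & axis_z <= mouth_z)
      max_slope <- max(diff(e_axis[seg]) / 0.05)
      model$bias <- list(direction = c(0, 0, -1),
                         magnitude = 1.5 * max(max_slope, 1),
                         steps = ceiling((mouth_z - zi) / 0.1) + 10L)
    }

    ## global-minimum verification: seeded random pose scan
    scan_e <- numeric(n_scan)
    for (i in seq_len(n_scan)) {
      tr <- stats::rnorm(3L)
      tr <- tr / max(1e-9, sqrt(sum(tr^2))) * stats::runif(1L, 0, r_shell + 3)
      ## place the ligand centre at tr with a random orientation about it
      rot <- .random_rotation()
      ctr <- colMeans(planted_xyz)
      cand <- rigid_pose(planted_xyz, rot, as.numeric(tr - rot %*% ctr))
      e <- tryCatch(.pose_energy(model, cand), error = function(err) NULL)
      scan_e[i] <- if (is.null(e)) Inf else e$lj + e$electrostatic
    }
    model$scan_min_energy <- min(scan_e)
    if (model$scan_min_energy < model$planted_energy - 1e-6) {
      stop(sprintf(
        "funnel verification failed: scan found energy %.4f below planted %.4f",
        model$scan_min_energy, model$planted_energy))
    }
    class(model) <- "lrd_planted_model"
    model
  })
}

#' Seeded random starting poses outside the binding region
#'
#' Emulates the manual trial-position screening used to find starting
#' poses for automated docking: ligand centres are drawn on a sphere of
#' given radius around the receptor centre (biased towards the aperture
#' hemisphere when `hemisphere` is given) with uniformly random
#' orientations.
#'
#' @param model an `lrd_planted_model` with a ligand.
#' @param n number of poses.
#' @param radius sphere radius for the ligand centre, Angstrom.
#' @param seed integer seed.
#' @param hemisphere optional unit vector; drawn centres are reflected
#'   into the half-space it points into.
#' @return List of [rigid_pose()]s.
#' @export
sample_start_poses <- function(model, n, radius = 9, seed = 1L, hemisphere = NULL) {
  with_seed(seed, {
    ctr <- colMeans(model$ligand$xyz)
    lapply(seq_len(n), function(i) {
      u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u^2))
      if (!is.null(hemisphere) && sum(u * hemisphere) < 0) u <- u - 2 * sum(u * hemisphere) * hemisphere
      rot <- .random_rotation()
      tr <- radius * u
      rigid_pose(model$ligand$xyz, rot, as.numeric(tr - rot %*% ctr))
    })
  })
}

#' Write a planted model's files through the public writers
#'
#' Emits the same PDB / Gromacs-topology / mode-basis files the real
#' pipeline consumes, so fixtures can be exercised end-to-end through
#' the public readers.
#'
#' @param model an `lrd_planted_model`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the written paths.
#' @export
write_model_files <- function(model, dir, prefix = "model") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(x) file.path(dir, paste0(prefix, x))
  paths <- c(receptor_pdb = p("_receptor.pdb"),
             receptor_top = p("_receptor.top"),
             eigenvalues = p("_eigenvalues.txt"),
             eigenvectors = p("_eigenvectors.txt"))
  write_pdb(model$structure, paths[["receptor_pdb"]])
  write_topology(model$topology, model$structure, paths[["receptor_top"]], "REC")
  write_mode_basis(model$basis, paths[["eigenvalues"]], paths[["eigenvectors"]])
  if (!is.null(model$ligand)) {
    paths <- c(paths, ligand_pdb = p("_ligand.pdb"), ligand_top = p("_ligand.top"))
    write_pdb(model$ligand, paths[["ligand_pdb"]])
    write_topology(model$ligand_topology, model$ligand, paths[["ligand_top"]], "LIG")
  }
  paths
}
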