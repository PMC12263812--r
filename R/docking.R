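#' Rigid-body pose of the ligand
#'
#' The ligand is rigid: a pose is a proper rotation plus a translation
#' applied to a fixed reference conformation. Coordinates are
#' `reference %*% t(rotation) + translation` row-wise; the identity pose
#' reproduces the reference exactly.
#'
#' @param reference_coords L x 3 matrix of the reference ligand
#'   conformation, Angstrom.
#' @param rotation 3 x 3 proper rotation (orthonormal to 1e-10).
#' @param translation length-3 vector, Angstrom.
#' @return Object of class `lrd_pose`.
#' @export
rigid_pose <- function(reference_coords, rotation = diag(3), translation = c(0, 0, 0)) {
  ref <- as_coord_mat(reference_coords)
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10 || det(rotation) < 0) {
    stop("rotation must be proper orthonormal (det = +1) to 1e-10")
  }
  out <- list(reference_coords = ref, rotation = rotation,
              translation = as.numeric(translation))
  class(out) <- "lrd_pose"
  out
}

#' Ligand coordinates under a pose
#'
#' @param pose an [rigid_pose()].
#' @return L x 3 coordinate matrix, Angstrom.
#' @export
pose_coords <- function(pose) {
  apply_transform(pose$reference_coords, pose$rotation, pose$translation)
}

## Rodrigues rotation matrix about a unit axis
.axis_angle_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

#' One clamped steepest-descent rigid-body step
#'
#' Translates along the net force and rotates about the torque axis
#' through the given pivot: translation increment = step_t * force,
#' clamped to length max_t; rotation angle = step_r * |torque|, clamped
#' to max_r. Zero force and torque leave the pose unchanged.
#'
#' @param pose an [rigid_pose()].
#' @param force,torque length-3 net force (kcal/mol/A) and torque
#'   (kcal/mol/rad) on the ligand.
#' @param pivot rotation pivot (typically the ligand's centre of mass).
#' @param step_t translation scale, A per (kcal/mol/A).
#' @param step_r rotation scale, rad per (kcal/mol/rad).
#' @param max_t,max_r per-step clamps, A and rad.
#' @return The stepped `lrd_pose`.
#' @export
rigid_step <- function(pose, force, torque, pivot,
                       step_t = 0.02, step_r = 0.005,
                       max_t = 0.1, max_r = 0.02) {
  stopifnot(step_t > 0, step_r > 0, max_t > 0, max_r > 0)
  dt <- step_t * force
  nt <- sqrt(sum(dt^2))
  if (nt > max_t) dt <- dt * (max_t / nt)
  tau <- sqrt(sum(torque^2))
  if (tau > 1e-12) {
    ang <- min(step_r * tau, max_r)
    rinc <- .axis_angle_matrix(torque / tau, ang)
  } else {
    rinc <- diag(3)
  }
  new_rot <- rinc %*% pose$rotation
  ## re-orthonormalise drift from accumulated products
  sv <- svd(new_rot)
  new_rot <- sv$u %*% t(sv$v)
  new_trans <- as.numeric(rinc %*% (pose$translation - pivot)) + pivot + dt
  rigid_pose(pose$reference_coords, new_rot, new_trans)
}

#' Place a ghost ligand from a holo complex
#'
#' The ghost ligand marks where the ligand is experimentally bound: the
#' protein of the crystallographic ligand-bound structure is superposed
#' on the receptor (C-alpha atoms matched by residue id), and the same
#' rotation and translation is then applied to the bound ligand. The
#' ghost is a passive reference -- it never exerts or feels any force.
#'
#' @param holo [lrd_structure()] containing the ligand-bound complex.
#' @param receptor [lrd_structure()] the ghost is placed relative to.
#' @param ligand_sel integer indices of the ligand atoms within `holo`,
#'   or a residue name (e.g. `"LIG"`) selecting them.
#' @param holo_chain,receptor_chain optional chain ids restricting the
#'   C-alpha match (for multi-chain entries with different chain labels).
#' @param mass_weighted mass-weight the protein superposition (default
#'   FALSE: plain C-alpha least squares).
#' @return An `lrd_structure` of the ghost (class also `lrd_ghost`) with
#'   attributes `superposition_rmsd` (Angstrom, protein C-alpha) and
#'   `n_matched`.
#' @export
place_ghost <- function(holo, receptor, ligand_sel,
                        holo_chain = NULL, receptor_chain = NULL,
                        mass_weighted = FALSE) {
  if (is.character(ligand_sel) && length(ligand_sel) == 1L) {
    ligand_sel <- which(holo$atom$residue_name == ligand_sel)
  }
  ligand_sel <- as.integer(ligand_sel)
  if (!length(ligand_sel)) stop("ligand selection is empty")

  is_ca <- function(s, chain) {
    ok <- s$atom$atom_name == "CA" & toupper(s$atom$element) == "C"
    if (!is.null(chain)) ok <- ok & s$atom$chain_id == chain
    which(ok)
  }
  hca <- setdiff(is_ca(holo, holo_chain), ligand_sel)
  rca <- is_ca(receptor, receptor_chain)
  key_h <- holo$atom$residue_id[hca]
  key_r <- receptor$atom$residue_id[rca]
  common <- intersect(key_h, key_r)
  if (length(common) < 3L) stop("fewer than 3 matched C-alpha atoms between holo and receptor")
  hi <- hca[match(common, key_h)]
  ri <- rca[match(common, key_r)]
  w <- if (mass_weighted) holo$mass[hi] else rep(1, length(hi))
  tr <- superpose(holo$xyz[hi, , drop = FALSE], receptor$xyz[ri, , drop = FALSE],
                  weights = w)
  ghost_xyz <- apply_transform(holo$xyz[ligand_sel, , drop = FALSE],
                               tr$rotation, tr$translation)
  ghost <- lrd_structure(holo$atom[ligand_sel, , drop = FALSE], ghost_xyz,
                         mass = holo$mass[ligand_sel])
  class(ghost) <- c("lrd_ghost", class(ghost))
  attr(ghost, "superposition_rmsd") <- tr$rmsd
  attr(ghost, "n_matched") <- length(common)
  ghost
}

#' RMSD between a posed ligand and its ghost
#'
#' Plain coordinate RMSD in the fixed receptor frame -- no superposition
#' is performed, since the ghost's whole purpose is to measure how far
#' the pose is from the experimentally bound position.
#'
#' @param pose an [rigid_pose()], an [lrd_structure()], or an L x 3
#'   coordinate matrix.
#' @param ghost the ghost ligand (`lrd_structure`) or an L x 3 matrix,
#'   with identical atom count and order.
#' @param heavy_only drop hydrogens (requires structures on both sides).
#' @return RMSD in Angstrom.
#' @export
rmsd_to_ghost <- function(pose, ghost, heavy_only = FALSE) {
  x <- if (inherits(pose, "lrd_pose")) pose_coords(pose)
       else if (inherits(pose, "lrd_structure")) pose$xyz
       else as_coord_mat(pose)
  g <- if (inherits(ghost, "lrd_structure")) ghost$xyz else as_coord_mat(ghost)
  if (nrow(x) != nrow(g)) stop("pose and ghost atom counts differ")
  keep <- rep(TRUE, nrow(x))
  if (heavy_only) {
    if (!inherits(ghost, "lrd_structure")) stop("heavy_only needs a ghost structure")
    keep <- ghost$is_heavy
  }
  sqrt(mean(rowSums((x[keep, , drop = FALSE] - g[keep, , drop = FALSE])^2)))
}

#' Count heavy-atom contacts between a ligand selection and the receptor
#'
#' A contact is any pair of heavy atoms (one from the selection, one from
#' the receptor) within the cutoff; hydrogens are excluded on both
#' sides. The 4 A default is the conventional contact criterion.
#'
#' @param ligand [lrd_structure()] of the posed ligand.
#' @param receptor [lrd_structure()].
#' @param cutoff contact distance, Angstrom (default 4).
#' @param ligand_sel optional atom-name vector or integer indices
#'   restricting the ligand side (e.g. a cap selection).
#' @return Integer number of contacting pairs.
#' @export
contact_count <- function(ligand, receptor, cutoff = 4, ligand_sel = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  li <- which(ligand$is_heavy)
  if (!is.null(ligand_sel)) {
    sel <- if (is.character(ligand_sel)) which(ligand$atom$atom_name %in% ligand_sel)
           else as.integer(ligand_sel)
    li <- intersect(li, sel)
  }
  if (!length(li)) stop("empty heavy-atom ligand selection")
  ri <- which(receptor$is_heavy)
  if (!length(ri)) stop("receptor has no heavy atoms")
  lx <- ligand$xyz[li, , drop = FALSE]
  rx <- receptor$xyz[ri, , drop = FALSE]
  d2 <- outer(rowSums(lx^2), rowSums(rx^2), "+") - 2 * lx %*% t(rx)
  sum(d2 <= cutoff^2 + 1e-12)
}

#' Report intermolecular polar contacts (hydrogen-bond candidates)
#'
#' Lists all nitrogen/oxygen pairs (one atom from each molecule) within a
#' donor--acceptor distance threshold, labelled by residue (e.g.
#' `TYR745-OH`). This is a geometric report on heteroatom distances; no
#' angular criterion or explicit hydrogen positions are used.
#'
#' @param mol_a,mol_b [lrd_structure()]s.
#' @param d_max maximum N/O--N/O distance, Angstrom (default 3.5).
#' @return data.frame with columns `atom_a`, `atom_b` (labels),
#'   `index_a`, `index_b`, `distance`; zero rows when none.
#' @export
hbond_report <- function(mol_a, mol_b, d_max = 3.5) {
  polar <- function(s) which(toupper(s$atom$element) %in% c("N", "O"))
  ia <- polar(mol_a)
  ib <- polar(mol_b)
  lab <- function(s, i) {
    sprintf("%s%d-%s", s$atom$residue_name[i], s$atom$residue_id[i], s$atom$atom_name[i])
  }
  empty <- data.frame(atom_a = character(), atom_b = character(),
                      index_a = integer(), index_b = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!length(ia) || !length(ib)) return(empty)
  xa <- mol_a$xyz[ia, , drop = FALSE]
  xb <- mol_b$xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- which(d2 <= d_max^2 + 1e-12, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  data.frame(
    atom_a = lab(mol_a, ia[hit[, 1L]]),
    atom_b = lab(mol_b, ib[hit[, 2L]]),
    index_a = ia[hit[, 1L]],
    index_b = ib[hit[, 2L]],
    distance = sqrt(pmax(d2[hit], 0)),
    stringsAsFactors = FALSE
  )
}

#' Automated quasi-static docking of a rigid ligand
#'
#' Steepest descent for the rigid ligand against a linearly responding
#' receptor. Each accepted step does, in order: (1) relax the receptor
#' into static equilibrium with the ligand forces
#' ([static_equilibrium()], warm-started from the previous state);
#' (2) evaluate the interaction energy and forces at the relaxed
#' receptor; (3) translate and rotate the ligand according to the net
#' force and torque about its centre of mass ([rigid_step()]). A trial
#' step that raises the total energy (interaction + strain, both
#' re-evaluated after receptor relaxation) is rejected and retried at
#' half the step scale; the scale recovers geometrically after accepted
#' steps. The loop ends when the net force and torque fall below their
#' thresholds ("converged"), the scale underflows ("stalled"), or the
#' step budget is exhausted ("max_steps").
#'
#' An optional bias models a scripted "gentle push": for the first
#' `bias$steps` steps a constant external force
#' `bias$magnitude * bias$direction` is added to the net force, steps are
#' accepted unconditionally (the push is allowed to climb the energy
#' barrier), and convergence checking is suspended. After the bias ends
#' plain automated docking resumes.
#'
#' @param receptor [lrd_structure()] at the relaxed reference r_o.
#' @param receptor_top,ligand_top [lrd_topology()]s.
#' @param basis [mode_basis()] for the receptor.
#' @param ligand [lrd_structure()]; its coordinates are the rigid
#'   reference conformation.
#' @param start_pose [rigid_pose()]; default identity on the ligand
#'   coordinates.
#' @param config [run_config()]; cutoff defaults to 100 A here.
#' @param ghost optional ghost ligand for per-step RMSD.
#' @param bias optional list(direction, magnitude, steps).
#' @param trace_modes mode indices whose receptor projections are traced.
#' @return An `lrd_docking_trace`: a data.frame with one row per recorded
#'   step (step, e_lj, e_elec, e_interaction, e_strain, e_total,
#'   disp_norm, residual, proj_PC*, rmsd_to_ghost, n_hbonds, force_norm,
#'   torque_norm, biased) with attributes `final_pose`, `final_state`,
#'   `termination`, `poses`.
#' @export
auto_dock <- function(receptor, receptor_top, basis, ligand, ligand_top,
                      start_pose = NULL, config = run_config(),
                      ghost = NULL, bias = NULL,
                      trace_modes = c(1L, 2L)) {
  stopifnot(inherits(basis, "lrd_mode_basis"),
            receptor$natoms == basis$n_atoms)
  trace_modes <- trace_modes[trace_modes <= basis$n_modes]
  if (is.null(start_pose)) start_pose <- rigid_pose(ligand$xyz)
  dk <- config$docking
  sol <- config$solver
  diel <- config$dielectric

  relax <- function(lig_xyz, warm) {
    ffn <- function(coords) {
      interaction_energy(set_coords(receptor, coords), receptor_top,
                         set_coords(ligand, lig_xyz), ligand_top,
                         cutoff = config$cutoff, dielectric = diel)$receptor_forces
    }
    static_equilibrium(basis, ffn, start = warm, gamma = sol$gamma,
                       tol = sol$tol, max_iter = sol$max_iter)
  }
  evaluate <- function(pose, warm) {
    lx <- pose_coords(pose)
    st <- relax(lx, warm)
    en <- interaction_energy(set_coords(receptor, as_coord_mat(st$coords)),
                             receptor_top, set_coords(ligand, lx), ligand_top,
                             cutoff = config$cutoff, dielectric = diel)
    list(state = st, inter = en,
         breakdown = energy_breakdown(en$lj, en$electrostatic, st$strain),
         lig_xyz = lx)
  }

  pose <- start_pose
  cur <- tryCatch(evaluate(pose, NULL), lrd_nonconvergence = function(e) {
    stop("receptor relaxation failed at the starting pose: ", conditionMessage(e))
  })
  scale <- 1
  rows <- list()
  poses <- list()
  termination <- "max_steps"
  n_bias <- if (is.null(bias)) 0L else as.integer(bias$steps)
  bias_f <- if (is.null(bias)) c(0, 0, 0) else {
    u <- bias$direction / sqrt(sum(bias$direction^2))
    bias$magnitude * u
  }

  record <- function(step, cur, ft, biased) {
    pr <- if (length(trace_modes)) {
      as.numeric(project_modes(cur$state$displacement, basis, modes = trace_modes))
    } else numeric(0)
    row <- data.frame(
      step = step,
      e_lj = cur$breakdown$lj, e_elec = cur$breakdown$electrostatic,
      e_interaction = cur$breakdown$interaction,
      e_strain = cur$breakdown$strain, e_total = cur$breakdown$total,
      disp_norm = sqrt(sum(cur$state$displacement^2)),
      residual = cur$state$residual_norm,
      force_norm = sqrt(sum(ft$force^2)),
      torque_norm = sqrt(sum(ft$torque^2)),
      biased = biased
    )
    for (k in seq_along(trace_modes)) row[[paste0("proj_PC", trace_modes[k])]] <- pr[k]
    row$rmsd_to_ghost <- if (is.null(ghost)) NA_real_ else rmsd_to_ghost(cur$lig_xyz, ghost)
    row$n_hbonds <- nrow(hbond_report(
      set_coords(ligand, cur$lig_xyz),
      set_coords(receptor, as_coord_mat(cur$state$coords))))
    row
  }

  for (step in seq_len(dk$max_steps)) {
    biased <- step <= n_bias
    com <- colSums(pose_coords(pose) * ligand$mass) / sum(ligand$mass)
    ft <- net_force_torque(cur$inter$ligand_forces, pose_coords(pose), com)
    if (biased) ft$force <- ft$force + bias_f
    rows[[step]] <- record(step, cur, ft, biased)
    poses[[step]] <- pose
    if (!biased &&
        sqrt(sum(ft$force^2)) < dk$f_tol && sqrt(sum(ft$torque^2)) < dk$tau_tol) {
      termination <- "converged"
      break
    }
    accepted <- FALSE
    while (!accepted) {
      cand_pose <- rigid_step(pose, ft$force, ft$torque, com,
                              step_t = scale * dk$step_t, step_r = scale * dk$step_r,
                              max_t = scale * dk$max_t, max_r = scale * dk$max_r)
      cand <- tryCatch(evaluate(cand_pose, cur$state),
                       lrd_nonconvergence = function(e) {
                         stop(sprintf("receptor relaxation failed at docking step %d: %s",
                                      step, conditionMessage(e)))
                       })
      if (biased || cand$breakdown$total <= cur$breakdown$total + 1e-9) {
        pose <- cand_pose
        cur <- cand
        scale <- min(1, scale * 1.5)
        accepted <- TRUE
      } else {
        scale <- scale / 2
        if (scale < dk$min_scale) break
      }
    }
    if (!accepted) {
      termination <- "stalled"
      break
    }
  }

  trace <- do.call(rbind, rows)
  attr(trace, "final_pose") <- pose
  attr(trace, "final_state") <- cur$state
  attr(trace, "final_energy") <- cur$breakdown
  attr(trace, "termination") <- termination
  attr(trace, "poses") <- poses
  class(trace) <- c("lrd_docking_trace", class(trace))
  trace
}

#' @export
print.lrd_docking_trace <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<lrd_docking_trace> %d steps, termination: %s\n  final E_total = %.3f kcal/mol (interaction %.3f, strain %.3f)\n",
              n, attr(x, "termination"),
              x$e_total[n], x$e_interaction[n], x$e_strain[n]))
  invisible(x)
}

#' Path-based estimate of the energy barrier crossed by a biased segment
#'
#' For a docking trace that includes a biased push out of a local
#' minimum, estimates the barrier as the maximum total energy recorded
#' along the path minus the total energy at the starting (intermediate)
#' pose. Path-dependent by construction: it is an upper-bound style
#' estimate along the realised path, not a minimum-energy-path barrier.
#'
#' @param trace an `lrd_docking_trace` from [auto_dock()] with a bias.
#' @return List with `barrier` (kcal/mol), `peak_step`, `start_energy`,
#'   `peak_energy`, `final_energy`.
#' @export
barrier_estimate <- function(trace) {
  stopifnot(inherits(trace, "lrd_docking_trace"))
  e <- trace$e_total
  peak <- which.max(e)
  list(barrier = e[peak] - e[1L], peak_step = peak,
       start_energy = e[1L], peak_energy = e[peak],
       final_energy = e[length(e)])
}
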