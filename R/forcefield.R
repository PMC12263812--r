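#' Dielectric models for electrostatic screening
#'
#' Solvent screening of receptor--ligand electrostatics is modelled by a
#' relative permittivity. The default is the linear distance-dependent
#' form eps_r(r) = slope * (r / A), the simplest standard screening model,
#' giving a Coulomb energy ke q_i q_j / (slope r^2). A constant
#' permittivity is also available. The model is pluggable: any list with
#' fields `model` ("linear"/"constant"), `slope`, `constant` is accepted
#' wherever a dielectric is taken.
#'
#' @param slope dimensionless slope of the linear model.
#' @param constant value of the constant model.
#' @return A dielectric model list.
#' @export
dielectric_linear <- function(slope = 1) {
  list(model = "linear", slope = slope, constant = 1)
}

#' @rdname dielectric_linear
#' @export
dielectric_constant <- function(constant = 1) {
  list(model = "constant", slope = 1, constant = constant)
}

## pair parameter matrices under the combination rule
.pair_params <- function(top_a, top_b) {
  if (top_a$combination_rule != top_b$combination_rule) {
    stop("topologies use different combination rules")
  }
  if (top_a$combination_rule == "lorentz_berthelot") {
    sig <- outer(top_a$sigma, top_b$sigma, "+") / 2
  } else {
    sig <- sqrt(outer(top_a$sigma, top_b$sigma))
  }
  eps <- sqrt(outer(top_a$epsilon, top_b$epsilon))
  list(sigma = sig, epsilon = eps)
}

#' Intermolecular nonbonded energy and forces
#'
#' Sums 12-6 Lennard-Jones and screened Coulomb terms over all
#' receptor--ligand atom pairs within a spherical cutoff (hard
#' truncation, no switching); intramolecular terms are never computed
#' (the ligand is rigid and receptor deformation is priced by the strain
#' energy instead). Forces are the exact negative gradients of the
#' truncated sum, so Newton's third law holds pair by pair.
#'
#' LJ: 4 eps_ij \[(sig_ij/r)^12 - (sig_ij/r)^6\] with combination-rule
#' pair parameters. Coulomb: ke q_i q_j / (eps_r(r) r) with ke =
#' 332.0636 kcal A / (mol e^2).
#'
#' @param receptor,ligand [lrd_structure()]s.
#' @param receptor_top,ligand_top paired [lrd_topology()]s.
#' @param cutoff spherical cutoff, Angstrom.
#' @param dielectric a dielectric model (see [dielectric_linear()]).
#' @return List with `lj`, `electrostatic` (kcal/mol), `receptor_forces`
#'   (N x 3) and `ligand_forces` (L x 3) in kcal/mol/A.
#' @export
interaction_energy <- function(receptor, receptor_top, ligand, ligand_top,
                               cutoff = 100, dielectric = dielectric_linear()) {
  stopifnot(receptor$natoms == receptor_top$natoms,
            ligand$natoms == ligand_top$natoms)
  if (cutoff <= 0) stop("cutoff must be positive")
  rx <- receptor$xyz
  lx <- ligand$xyz
  n <- nrow(rx); l <- nrow(lx)
  dx <- outer(rx[, 1L], lx[, 1L], "-")
  dy <- outer(rx[, 2L], lx[, 2L], "-")
  dz <- outer(rx[, 3L], lx[, 3L], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  if (any(r2 < 1e-12)) {
    p <- which(r2 < 1e-12, arr.ind = TRUE)[1L, ]
    stop(sprintf("overlapping atoms: receptor atom %d and ligand atom %d", p[1L], p[2L]))
  }
  r <- sqrt(r2)
  within <- r <= cutoff
  pp <- .pair_params(receptor_top, ligand_top)
  sr6 <- (pp$sigma / r)^6
  sr12 <- sr6 * sr6
  e_lj_pair <- 4 * pp$epsilon * (sr12 - sr6)
  qq <- lrd_constants[["ke"]] * outer(receptor_top$charge, ligand_top$charge)
  if (dielectric$model == "linear") {
    e_el_pair <- qq / (dielectric$slope * r2)
    dEel <- -2 * e_el_pair / r                 # dE/dr
  } else {
    e_el_pair <- qq / (dielectric$constant * r)
    dEel <- -e_el_pair / r
  }
  dElj <- (4 * pp$epsilon / r) * (6 * sr6 - 12 * sr12)
  e_lj <- sum(e_lj_pair[within])
  e_el <- sum(e_el_pair[within])
  ## force coefficient C = (dE/dr)/r per pair; F_rec_i = -sum_j C*(x_i - x_j)
  cmat <- (dElj + dEel) / r
  cmat[!within] <- 0
  rec_f <- -(rx * rowSums(cmat) - cmat %*% lx)
  lig_f <- -(lx * colSums(cmat) - crossprod(cmat, rx))
  list(lj = e_lj, electrostatic = e_el,
       receptor_forces = rec_f, ligand_forces = lig_f)
}

#' Net force and torque on a rigid body
#'
#' @param forces L x 3 matrix of per-atom forces (kcal/mol/A).
#' @param coords L x 3 matrix of atom positions (Angstrom).
#' @param pivot length-3 point the torque is taken about.
#' @return List with `force` (length 3, kcal/mol/A) and `torque`
#'   (length 3, kcal/mol/rad).
#' @export
net_force_torque <- function(forces, coords, pivot) {
  f <- as_coord_mat(forces)
  x <- as_coord_mat(coords)
  stopifnot(nrow(f) == nrow(x), all(is.finite(pivot)))
  rrel <- sweep(x, 2L, pivot)
  tq <- c(sum(rrel[, 2L] * f[, 3L] - rrel[, 3L] * f[, 2L]),
          sum(rrel[, 3L] * f[, 1L] - rrel[, 1L] * f[, 3L]),
          sum(rrel[, 1L] * f[, 2L] - rrel[, 2L] * f[, 1L]))
  list(force = colSums(f), torque = tq)
}

#' Energy breakdown record
#'
#' @param lj,electrostatic,strain component energies, kcal/mol.
#' @return List with the components plus `interaction`
#'   (lj + electrostatic) and `total` (interaction + strain); the strain
#'   energy of the deformed receptor is added to the intermolecular
#'   interaction energy for display as the total energy.
#' @export
energy_breakdown <- function(lj, electrostatic, strain = 0) {
  stopifnot(is.finite(lj), is.finite(electrostatic), is.finite(strain))
  interaction <- lj + electrostatic
  list(lj = lj, electrostatic = electrostatic,
       interaction = interaction, strain = strain,
       total = interaction + strain)
}
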