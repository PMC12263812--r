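#' One-shot linear-response displacement for a fixed force vector
#'
#' Evaluates Delta_r = (1 / kB T) V_M lambda_M V_M^t f via two thin-matrix
#' products (amplitudes a = V^t f, then V (lambda a) / kB T); the dense
#' 3N x 3N response matrix is never formed. This is the receptor's
#' equilibrium displacement under a coordinate-independent force within
#' the retained mode subspace.
#'
#' @param basis an [mode_basis()].
#' @param forces flat 3N vector or N x 3 matrix, kcal/mol/A.
#' @return Flat 3N displacement vector, Angstrom.
#' @export
response_displacement <- function(basis, forces) {
  f <- as_xyz_vec(forces)
  if (length(f) != 3L * basis$n_atoms) stop("force vector is not 3N")
  a <- crossprod(basis$eigenvectors, f)
  kbt <- lrd_constants[["kB"]] * basis$temperature
  as.numeric(basis$eigenvectors %*% (basis$eigenvalues * a)) / kbt
}

#' Elastic strain energy of a receptor displacement
#'
#' E_strain = (kB T / 2) Delta_r^t V_M lambda_M^{-1} V_M^t Delta_r,
#' evaluated through the mode amplitudes a = V_M^t Delta_r as
#' (kB T / 2) sum_i a_i^2 / lambda_i. Components of the displacement
#' outside the mode subspace carry no strain (they are never created by
#' the solver either).
#'
#' @param basis an [mode_basis()].
#' @param displacement flat 3N vector or N x 3 matrix, Angstrom.
#' @return Strain energy, kcal/mol (non-negative).
#' @export
strain_energy <- function(basis, displacement) {
  d <- as_xyz_vec(displacement)
  if (length(d) != 3L * basis$n_atoms) stop("displacement vector is not 3N")
  a <- as.numeric(crossprod(basis$eigenvectors, d))
  0.5 * lrd_constants[["kB"]] * basis$temperature * sum(a^2 / basis$eigenvalues)
}

#' Receptor state after relaxation
#'
#' @param basis an [mode_basis()].
#' @param displacement flat 3N vector, Angstrom.
#' @param residual_norm self-consistency residual of the static
#'   equilibrium condition, Angstrom.
#' @param n_iter iterations used.
#' @return Object of class `lrd_receptor_state` with `displacement`,
#'   `coords` (r_o + Delta_r, flat 3N), `residual_norm`, `strain`,
#'   `n_iter`.
#' @export
receptor_state <- function(basis, displacement, residual_norm = NA_real_,
                           n_iter = 0L) {
  d <- as_xyz_vec(displacement)
  out <- list(displacement = d,
              coords = basis$reference_coords + d,
              residual_norm = residual_norm,
              strain = strain_energy(basis, d),
              n_iter = n_iter)
  class(out) <- "lrd_receptor_state"
  out
}

#' Relax the receptor into static equilibrium with a force field
#'
#' Solves the self-consistent condition
#' Delta_r = (1 / kB T) V_M lambda_M V_M^t f(r_o + Delta_r)
#' by damped fixed-point iteration
#' Delta_r <- (1 - gamma) Delta_r + gamma R(f(r_o + Delta_r)),
#' where R is [response_displacement()]. At the fixed point the total
#' energy (strain plus interaction) is stationary with respect to the
#' mode amplitudes, i.e. the receptor has descended smoothly into static
#' equilibrium with the ligand forces. The returned state records the
#' achieved residual norm ||Delta_r - R(f)||.
#'
#' @param basis an [mode_basis()].
#' @param force_fn function taking an N x 3 coordinate matrix and
#'   returning receptor forces (N x 3 or flat 3N), kcal/mol/A.
#' @param start optional starting `lrd_receptor_state` (warm start);
#'   defaults to zero displacement.
#' @param gamma damping factor in (0, 1].
#' @param tol residual tolerance, Angstrom.
#' @param max_iter iteration cap.
#' @return An [receptor_state()]; on failure to converge an error of
#'   class `lrd_nonconvergence` whose condition carries the last state in
#'   `$state`.
#' @export
static_equilibrium <- function(basis, force_fn, start = NULL,
                               gamma = 0.2, tol = 1e-4, max_iter = 2000) {
  stopifnot(gamma > 0, gamma <= 1, tol > 0, max_iter >= 1)
  n3 <- 3L * basis$n_atoms
  d <- if (is.null(start)) numeric(n3) else start$displacement
  if (length(d) != n3) stop("start displacement is not 3N")
  res <- Inf
  for (it in seq_len(max_iter)) {
    coords <- as_coord_mat(basis$reference_coords + d)
    f <- force_fn(coords)
    target <- response_displacement(basis, f)
    res <- sqrt(sum((d - target)^2))
    if (res <= tol) {
      return(receptor_state(basis, d, residual_norm = res, n_iter = it))
    }
    d <- (1 - gamma) * d + gamma * target
  }
  cond <- structure(
    class = c("lrd_nonconvergence", "error", "condition"),
    list(message = sprintf(
      "static equilibrium not reached in %d iterations (residual %.3g A > tol %.3g A)",
      max_iter, res, tol),
      call = sys.call(-1),
      state = receptor_state(basis, d, residual_norm = res, n_iter = max_iter)))
  stop(cond)
}
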