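#' Principal component analysis of a fitted ensemble
#'
#' Eigendecomposition of the 3N x 3N covariance of atomic displacements
#' from the ensemble average. Computed by thin SVD of the centred
#' F x 3N snapshot matrix (never forming the dense covariance), which is
#' numerically identical to the dense route but affordable when 3N is
#' large. Coordinates are unweighted: mass weighting applies to the fit
#' only, not to the covariance.
#'
#' The emitted basis uses the closest-to-average frame as its reference
#' coordinates r_o and records the trace of the covariance (total
#' mean-square fluctuation) as `total_variance`.
#'
#' @param traj a fitted [lrd_trajectory()] (see [fit_trajectory()]).
#' @param n_modes number of modes to retain (<= min(3N, F - 1)).
#' @param temperature Kelvin, stored in the basis.
#' @return An [mode_basis()].
#' @export
pca_modes <- function(traj, n_modes, temperature = 300) {
  f <- traj$n_frames
  n3 <- 3L * traj$natoms
  kmax <- min(n3, f - 1L)
  if (n_modes < 1L || n_modes > kmax) {
    stop("n_modes must be between 1 and min(3N, F-1) = ", kmax)
  }
  x <- sweep(traj$xyz, 2L, colMeans(traj$xyz))
  sv <- svd(x / sqrt(f - 1), nu = 0, nv = n_modes)
  lam_all <- (sv$d)^2                       # all min(F,3N) covariance eigenvalues
  total <- sum(lam_all)                     # trace of the covariance
  lam <- lam_all[seq_len(n_modes)]
  if (any(lam <= 0)) {
    stop("requested modes include zero-variance directions; reduce n_modes")
  }
  ref <- .frame_mat(traj, closest_to_average(traj))
  mode_basis(ref, lam, sv$v, temperature = temperature, total_variance = total)
}

#' Project displacements onto principal modes
#'
#' For each frame (or single conformation) the projection on mode k is
#' the inner product of the displacement from the basis reference with
#' the k-th eigenvector, in Angstrom.
#'
#' @param x an [lrd_trajectory()], an [lrd_structure()], an N x 3
#'   coordinate matrix, or a flat 3N displacement vector (taken as a
#'   displacement directly, not as absolute coordinates).
#' @param basis an [mode_basis()].
#' @param modes integer mode indices (1-based; default first two).
#' @param displacement set TRUE if `x` already holds displacements rather
#'   than absolute coordinates (automatic for flat vectors).
#' @return F x K matrix of projections (F = 1 for single conformations).
#' @export
project_modes <- function(x, basis, modes = c(1L, 2L), displacement = FALSE) {
  modes <- as.integer(modes)
  if (any(modes < 1L) || any(modes > basis$n_modes)) {
    stop("mode index out of range 1..", basis$n_modes)
  }
  if (inherits(x, "lrd_trajectory")) {
    mat <- x$xyz
  } else if (inherits(x, "lrd_structure")) {
    mat <- matrix(as_xyz_vec(x$xyz), nrow = 1L)
  } else if (is.matrix(x) && ncol(x) == 3L) {
    mat <- matrix(as_xyz_vec(x), nrow = 1L)
  } else {
    mat <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
    displacement <- TRUE
  }
  if (ncol(mat) != 3L * basis$n_atoms) stop("dimension mismatch with basis (3N)")
  if (!displacement) mat <- sweep(mat, 2L, basis$reference_coords)
  p <- mat %*% basis$eigenvectors[, modes, drop = FALSE]
  colnames(p) <- paste0("PC", modes)
  p
}

#' Frames attaining the extreme projections along one mode
#'
#' Returns the actual trajectory frames (not reconstructions) with the
#' minimum and maximum projection on the given mode -- the structure pair
#' conventionally fed to domain-motion analysis.
#'
#' @param traj a fitted [lrd_trajectory()].
#' @param basis an [mode_basis()].
#' @param mode 1-based mode index.
#' @return List with `min` and `max` ([lrd_structure()]s) and the frame
#'   indices `min_frame`, `max_frame`.
#' @export
extreme_structures <- function(traj, basis, mode = 1L) {
  p <- project_modes(traj, basis, modes = mode)[, 1L]
  i_min <- which.min(p)
  i_max <- which.max(p)
  list(min = trajectory_frame(traj, i_min),
       max = trajectory_frame(traj, i_max),
       min_frame = i_min, max_frame = i_max)
}

#' Root mean-square inner product between two mode subspaces
#'
#' RMSIP(m) = sqrt( (1/m) sum_{i<=m} sum_{j<=m} (u_i . v_j)^2 ), the
#' standard measure of overlap between the subspaces spanned by the first
#' m modes of each basis: 1 for identical subspaces, 0 for orthogonal
#' ones, and invariant to rotations within either subspace.
#'
#' @param basis_a,basis_b [mode_basis()] objects over the same 3N degrees
#'   of freedom.
#' @param m subspace dimension (<= both mode counts).
#' @return A number in \[0, 1\].
#' @export
rmsip <- function(basis_a, basis_b, m) {
  if (basis_a$n_atoms != basis_b$n_atoms) stop("bases have different atom counts")
  m <- as.integer(m)
  if (m < 1L || m > basis_a$n_modes || m > basis_b$n_modes) {
    stop("m exceeds the retained mode count of one of the bases")
  }
  g <- crossprod(basis_a$eigenvectors[, seq_len(m), drop = FALSE],
                 basis_b$eigenvectors[, seq_len(m), drop = FALSE])
  sqrt(sum(g^2) / m)
}

#' Cumulative mean-square-fluctuation fraction of the leading modes
#'
#' Fraction of the total MSF (trace of the displacement covariance)
#' carried by the first k modes: sum_{i<=k} lambda_i / total_variance.
#'
#' @param basis an [mode_basis()] whose `total_variance` was recorded.
#' @param k number of leading modes.
#' @return Fraction in \[0, 1\].
#' @export
msf_fraction <- function(basis, k) {
  k <- as.integer(k)
  if (k < 1L || k > basis$n_modes) stop("k must be between 1 and M")
  if (is.null(basis$total_variance) || !is.finite(basis$total_variance) ||
      basis$total_variance <= 0) {
    stop("basis has no recorded total variance")
  }
  sum(basis$eigenvalues[seq_len(k)]) / basis$total_variance
}
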