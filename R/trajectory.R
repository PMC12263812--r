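#' Conformational ensemble (trajectory) container
#'
#' Frames with identical atom lists, stored as an F x 3N coordinate matrix
#' (rows are frames, columns are x1,y1,z1,x2,... in Angstrom) alongside the
#' shared atom table.
#'
#' @param atom per-atom data.frame as in [lrd_structure()].
#' @param xyz F x 3N matrix.
#' @param mass optional per-atom masses (amu).
#' @param frame_times optional numeric vector (ns), one per frame.
#' @return An object of class `lrd_trajectory`.
#' @export
lrd_trajectory <- function(atom, xyz, mass = NULL, frame_times = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2L) stop("a trajectory needs at least 2 frames")
  if (ncol(xyz) != 3L * nrow(atom)) stop("xyz columns must equal 3 x atom count")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (is.null(mass)) mass <- element_mass(atom$element)
  if (!is.null(frame_times) && length(frame_times) != nrow(xyz)) {
    stop("frame_times length must equal frame count")
  }
  out <- list(atom = atom, xyz = xyz, mass = as.numeric(mass),
              frame_times = frame_times,
              n_frames = nrow(xyz), natoms = nrow(atom))
  class(out) <- "lrd_trajectory"
  out
}

#' @export
print.lrd_trajectory <- function(x, ...) {
  cat(sprintf("<lrd_trajectory> %d frames x %d atoms\n", x$n_frames, x$natoms))
  invisible(x)
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param path multi-model PDB file.
#' @param frame_range optional integer vector `c(first, last)` (1-based,
#'   inclusive) selecting a frame window, e.g. to drop equilibration
#'   frames.
#' @return An [lrd_trajectory()].
#' @export
read_trajectory_pdb <- function(path, frame_range = NULL) {
  if (!file.exists(path)) stop("no such PDB file: ", path)
  pdb <- .read_pdb_checked(path)
  s1 <- .structure_from_bio3d(pdb, 1L)
  xyz <- pdb$xyz
  if (!is.null(frame_range)) {
    fr <- as.integer(frame_range)
    if (length(fr) != 2L || fr[1L] < 1L || fr[2L] > nrow(xyz) || fr[1L] > fr[2L]) {
      stop("invalid frame range ", paste(frame_range, collapse = ":"),
           " for ", nrow(xyz), " frames")
    }
    xyz <- xyz[fr[1L]:fr[2L], , drop = FALSE]
  }
  lrd_trajectory(s1$atom, xyz, mass = s1$mass)
}

#' Extract one frame of a trajectory as a structure
#'
#' @param traj an [lrd_trajectory()].
#' @param frame 1-based frame index.
#' @return An [lrd_structure()].
#' @export
trajectory_frame <- function(traj, frame) {
  stopifnot(frame >= 1L, frame <= traj$n_frames)
  lrd_structure(traj$atom, as_coord_mat(traj$xyz[frame, ]), mass = traj$mass)
}

## coordinates of a frame as an N x 3 matrix
.frame_mat <- function(traj, frame) as_coord_mat(traj$xyz[frame, ])

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimising the
#' (optionally mass-)weighted sum of squared deviations of the mobile
#' selection from the reference selection. The fitted coordinates are
#' `xyz %*% t(rotation) + translation` applied row-wise.
#'
#' @param mobile,reference `lrd_structure`s (or N x 3 matrices; then
#'   `weights` must be given explicitly for mass weighting).
#' @param sel integer atom indices used for the fit (default all atoms);
#'   the same indices apply to both structures.
#' @param mass_weighted weight each atom by its mass in the fit (default
#'   TRUE). The reported RMSD is always unweighted.
#' @param weights optional explicit fit weights, overriding masses.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom, over `sel`, after fitting).
#' @export
superpose <- function(mobile, reference, sel = NULL, mass_weighted = TRUE,
                      weights = NULL) {
  xm <- if (inherits(mobile, "lrd_structure")) mobile$xyz else as_coord_mat(mobile)
  xr <- if (inherits(reference, "lrd_structure")) reference$xyz else as_coord_mat(reference)
  n <- nrow(xm)
  if (nrow(xr) != n) stop("mobile and reference atom counts differ")
  if (is.null(sel)) sel <- seq_len(n)
  sel <- as.integer(sel)
  if (!length(sel)) stop("empty atom selection")
  if (any(sel < 1L | sel > n)) stop("selection index out of range")
  if (is.null(weights)) {
    weights <- if (mass_weighted && inherits(mobile, "lrd_structure")) {
      mobile$mass[sel]
    } else rep(1, length(sel))
  }
  w <- weights / sum(weights)
  a <- xm[sel, , drop = FALSE]
  b <- xr[sel, , drop = FALSE]
  ca <- colSums(a * w)
  cb <- colSums(b * w)
  a0 <- sweep(a, 2L, ca)
  b0 <- sweep(b, 2L, cb)
  if (length(sel) < 3L || qr(a0)$rank < 2L) {
    stop("degenerate selection: need at least 3 non-collinear atoms")
  }
  h <- crossprod(a0 * w, b0)              # 3x3 weighted correlation
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cb - rot %*% ca)
  fitted <- a %*% t(rot) + matrix(trans, length(sel), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz N x 3 matrix.
#' @param rotation 3 x 3 proper rotation.
#' @param translation length-3 vector.
#' @return Transformed N x 3 matrix (`xyz %*% t(rotation) + translation`).
#' @export
apply_transform <- function(xyz, rotation, translation) {
  as_coord_mat(xyz) %*% t(rotation) + matrix(translation, nrow(as_coord_mat(xyz)), 3L, byrow = TRUE)
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' Removes overall translation and rotation frame by frame via
#' (mass-weighted) least-squares fits, the standard preprocessing before
#' a PCA of internal displacements. The input is left untouched.
#'
#' @param traj an [lrd_trajectory()].
#' @param reference_frame 1-based index of the frame fitted onto, or an
#'   [lrd_structure()] with the same atoms to use as an external
#'   reference.
#' @param sel fit selection (default all atoms).
#' @param mass_weighted mass-weight the fits (default TRUE).
#' @return A new fitted `lrd_trajectory` with attribute `fitted = TRUE`.
#' @export
fit_trajectory <- function(traj, reference_frame = 1L, sel = NULL,
                           mass_weighted = TRUE) {
  if (inherits(reference_frame, "lrd_structure")) {
    if (reference_frame$natoms != traj$natoms) {
      stop("reference structure atom count differs from trajectory")
    }
    ref <- reference_frame$xyz
  } else {
    stopifnot(reference_frame >= 1L, reference_frame <= traj$n_frames)
    ref <- .frame_mat(traj, reference_frame)
  }
  if (is.null(sel)) sel <- seq_len(traj$natoms)
  w <- if (mass_weighted) traj$mass[sel] else rep(1, length(sel))
  out <- traj$xyz
  for (f in seq_len(traj$n_frames)) {
    m <- .frame_mat(traj, f)
    tr <- superpose(m[sel, , drop = FALSE], ref[sel, , drop = FALSE], weights = w)
    out[f, ] <- as_xyz_vec(apply_transform(m, tr$rotation, tr$translation))
  }
  res <- lrd_trajectory(traj$atom, out, mass = traj$mass, frame_times = traj$frame_times)
  attr(res, "fitted") <- TRUE
  res
}

#' Index of the frame closest to the ensemble average
#'
#' The arithmetic mean of fitted coordinates is generally not a viable
#' bonded structure, so the frame with minimum all-atom RMSD to the
#' average is used as the relaxed reference conformation r_o. Ties break
#' to the lowest index.
#'
#' @param traj a fitted [lrd_trajectory()].
#' @return Integer frame index.
#' @export
closest_to_average <- function(traj) {
  avg <- colMeans(traj$xyz)
  dev <- sweep(traj$xyz, 2L, avg)
  ss <- rowSums(dev^2)
  which.min(ss)   # which.min takes the first minimum: lowest-index tie-break
}
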