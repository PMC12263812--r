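#' Principal-mode basis for linear response
#'
#' Holds everything the linear-response model needs: the relaxed reference
#' coordinates r_o (3N, Angstrom), the top M eigenvalues (Angstrom^2) and
#' orthonormal eigenvectors (3N x M) of the atomic-displacement covariance,
#' the temperature of the ensemble they were derived from, and the total
#' variance (trace of the full covariance, for mean-square-fluctuation
#' fractions).
#'
#' @param reference_coords N x 3 matrix or flat 3N vector, Angstrom.
#' @param eigenvalues length-M positive numeric, Angstrom^2.
#' @param eigenvectors 3N x M matrix with orthonormal columns.
#' @param temperature Kelvin.
#' @param total_variance sum of ALL covariance eigenvalues, Angstrom^2;
#'   defaults to `sum(eigenvalues)` (exact only when M = 3N).
#' @param resort re-sort eigenpairs into descending eigenvalue order if
#'   needed (default TRUE).
#' @return An object of class `lrd_mode_basis` with fields
#'   `reference_coords` (flat 3N), `eigenvalues`, `eigenvectors`,
#'   `temperature`, `total_variance`, `n_atoms`, `n_modes`.
#' @export
mode_basis <- function(reference_coords, eigenvalues, eigenvectors,
                       temperature = 300, total_variance = sum(eigenvalues),
                       resort = TRUE) {
  r0 <- as_xyz_vec(reference_coords)
  V <- as.matrix(eigenvectors)
  lam <- as.numeric(eigenvalues)
  if (length(r0) %% 3L != 0L) stop("reference coordinates are not 3N")
  if (nrow(V) != length(r0)) {
    stop("eigenvector length ", nrow(V), " does not match 3N = ", length(r0))
  }
  if (ncol(V) != length(lam)) stop("eigenvalue / eigenvector count mismatch")
  if (ncol(V) > nrow(V)) stop("more modes than degrees of freedom (M > 3N)")
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("retained eigenvalues must be positive and finite")
  }
  if (is.unsorted(rev(lam))) {
    if (!resort) stop("eigenvalues not in descending order")
    o <- order(lam, decreasing = TRUE)
    lam <- lam[o]
    V <- V[, o, drop = FALSE]
  }
  g <- crossprod(V)
  if (max(abs(g - diag(ncol(V)))) > 1e-8) {
    stop("eigenvector columns are not orthonormal (tolerance 1e-8)")
  }
  if (temperature <= 0) stop("temperature must be positive")
  if (total_variance < sum(lam) - 1e-8 * max(1, sum(lam))) {
    stop("total_variance cannot be smaller than the retained eigenvalue sum")
  }
  out <- list(
    reference_coords = r0,
    eigenvalues = lam,
    eigenvectors = V,
    temperature = temperature,
    total_variance = total_variance,
    n_atoms = length(r0) %/% 3L,
    n_modes = ncol(V)
  )
  class(out) <- "lrd_mode_basis"
  out
}

#' @export
print.lrd_mode_basis <- function(x, ...) {
  cat(sprintf(
    "<lrd_mode_basis> N = %d atoms, M = %d modes, T = %g K\n  top eigenvalues (A^2): %s\n  retained / total variance: %.1f%%\n",
    x$n_atoms, x$n_modes, x$temperature,
    paste(signif(utils::head(x$eigenvalues, 4), 4), collapse = ", "),
    100 * sum(x$eigenvalues) / x$total_variance))
  invisible(x)
}

#' Write a mode basis to eigenvalue and eigenvector files
#'
#' The on-disk dialect is plain text. The eigenvalue file has a header
#' line `n_atoms n_modes temperature total_variance` followed by one
#' eigenvalue (Angstrom^2) per line, descending. The eigenvector file has
#' a header line `n_atoms n_modes`, then one row per degree of freedom
#' (3N rows) of M whitespace-separated components, then 3N further rows
#' of `x y z` reference coordinates.
#'
#' @param basis an [mode_basis()] object.
#' @param eigenvalue_path,eigenvector_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_mode_basis <- function(basis, eigenvalue_path, eigenvector_path) {
  con <- file(eigenvalue_path, "w")
  writeLines(sprintf("%d %d %.17g %.17g", basis$n_atoms, basis$n_modes,
                     basis$temperature, basis$total_variance), con)
  writeLines(sprintf("%.17g", basis$eigenvalues), con)
  close(con)
  con <- file(eigenvector_path, "w")
  writeLines(sprintf("%d %d", basis$n_atoms, basis$n_modes), con)
  writeLines(apply(basis$eigenvectors, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  rm <- as_coord_mat(basis$reference_coords)
  writeLines(apply(rm, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  close(con)
  invisible(c(eigenvalue_path, eigenvector_path))
}

#' Read a mode basis from eigenvalue and eigenvector files
#'
#' Reads the dialect written by [write_mode_basis()] and validates the
#' [mode_basis()] invariants (descending positive eigenvalues, orthonormal
#' columns to 1e-8, M <= 3N). If `reference` is given its coordinates
#' override the reference block in the file and its atom count must match.
#'
#' @param eigenvalue_path,eigenvector_path input paths.
#' @param reference optional [lrd_structure()] supplying r_o.
#' @param temperature optional override, Kelvin.
#' @return An `lrd_mode_basis`.
#' @export
read_mode_basis <- function(eigenvalue_path, eigenvector_path,
                            reference = NULL, temperature = NULL) {
  ev <- readLines(eigenvalue_path, warn = FALSE)
  hdr <- as.numeric(strsplit(trimws(ev[1L]), "[[:space:]]+")[[1L]])
  if (length(hdr) < 4L) stop("malformed eigenvalue header (need N M T total_variance)")
  n <- as.integer(hdr[1L]); m <- as.integer(hdr[2L])
  lam <- as.numeric(ev[-1L][nzchar(trimws(ev[-1L]))])
  if (length(lam) != m) stop("expected ", m, " eigenvalues, found ", length(lam))

  vv <- readLines(eigenvector_path, warn = FALSE)
  vhdr <- as.integer(strsplit(trimws(vv[1L]), "[[:space:]]+")[[1L]])
  if (vhdr[1L] != n || vhdr[2L] != m) {
    stop("eigenvector header disagrees with eigenvalue header")
  }
  body <- vv[-1L][nzchar(trimws(vv[-1L]))]
  if (length(body) != 3L * n + n) {
    stop("eigenvector file has ", length(body), " data rows; expected 3N + N = ", 4L * n)
  }
  V <- do.call(rbind, lapply(body[seq_len(3L * n)], function(ln) {
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1L]])
  }))
  if (ncol(V) != m) stop("eigenvector rows have ", ncol(V), " columns; expected M = ", m)
  rm <- do.call(rbind, lapply(body[3L * n + seq_len(n)], function(ln) {
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1L]])
  }))
  if (!is.null(reference)) {
    if (reference$natoms != n) {
      stop("reference structure has ", reference$natoms, " atoms; basis has ", n)
    }
    rm <- reference$xyz
  }
  mode_basis(rm, lam, V,
             temperature = if (is.null(temperature)) hdr[3L] else temperature,
             total_variance = hdr[4L])
}
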