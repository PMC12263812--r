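#' Molecular structure container
#'
#' A light container for one conformation of a molecule: a per-atom table
#' and an N x 3 coordinate matrix in Angstrom. Atom order is significant
#' and shared with [read_topology()] and [mode_basis()] objects paired with
#' the structure.
#'
#' @param atom data.frame with columns `atom_name`, `element`,
#'   `residue_name`, `residue_id`, `chain_id`.
#' @param xyz numeric N x 3 matrix of coordinates (Angstrom).
#' @param mass optional numeric vector of atomic masses (amu); looked up
#'   from the element when omitted.
#' @return An object of class `lrd_structure` with fields `atom`, `xyz`,
#'   `mass`, `is_heavy` (element != H) and `natoms`.
#' @export
lrd_structure <- function(atom, xyz, mass = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(is.data.frame(atom), ncol(xyz) == 3L, nrow(xyz) == nrow(atom))
  req <- c("atom_name", "element", "residue_name", "residue_id", "chain_id")
  missing_cols <- setdiff(req, names(atom))
  if (length(missing_cols)) {
    stop("atom table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(mass)) mass <- element_mass(atom$element)
  if (!all(is.finite(mass)) || any(mass <= 0)) stop("masses must be positive")
  if (length(mass) != nrow(atom)) stop("mass length must equal atom count")
  dimnames(xyz) <- NULL
  out <- list(
    atom = atom,
    xyz = xyz,
    mass = as.numeric(mass),
    is_heavy = toupper(atom$element) != "H",
    natoms = nrow(atom)
  )
  class(out) <- "lrd_structure"
  out
}

#' @export
print.lrd_structure <- function(x, ...) {
  cat(sprintf("<lrd_structure> %d atoms, %d residues\n",
              x$natoms, length(unique(paste(x$atom$chain_id, x$atom$residue_id)))))
  invisible(x)
}

#' Convert between flat 3N vectors and N x 3 coordinate matrices
#'
#' Mode vectors, forces and displacements are stored flat in the order
#' x1, y1, z1, x2, ...; structure coordinates are N x 3 matrices. These
#' helpers convert between the two layouts.
#'
#' @param m N x 3 matrix (or already-flat vector).
#' @param v flat 3N vector (or already an N x 3 matrix).
#' @return `as_xyz_vec`: a flat 3N numeric vector; `as_coord_mat`: an
#'   N x 3 matrix.
#' @export
as_xyz_vec <- function(m) {
  if (is.matrix(m)) as.numeric(t(m)) else as.numeric(m)
}

#' @rdname as_xyz_vec
#' @export
as_coord_mat <- function(v) {
  if (is.matrix(v) && ncol(v) == 3L) return(v)
  matrix(as.numeric(v), ncol = 3L, byrow = TRUE)
}

#' Read a structure from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] returning a single model as an
#' [lrd_structure()]. Elements come from the PDB element column when
#' present, otherwise they are inferred from the atom name; masses come
#' from the package's internal atomic-mass table.
#'
#' @param path path to a PDB file.
#' @param model 1-based model index for multi-model files.
#' @return An `lrd_structure`.
#' @export
read_pdb <- function(path, model = 1L) {
  if (!file.exists(path)) stop("no such PDB file: ", path)
  pdb <- .read_pdb_checked(path)
  nmod <- nrow(pdb$xyz)
  if (model < 1L || model > nmod) {
    stop("model ", model, " not present (file has ", nmod, " model(s))")
  }
  .structure_from_bio3d(pdb, model)
}

.read_pdb_checked <- function(path) {
  tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) {
      stop("PDB parse error in ", path,
           " (missing coordinates or malformed record): ", conditionMessage(e),
           call. = FALSE)
    })
}

.structure_from_bio3d <- function(pdb, model) {
  a <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  if (!all(is.finite(xyz))) {
    bad <- which(!stats::complete.cases(xyz))[1L]
    stop("missing coordinates at atom record ", bad)
  }
  elesy <- toupper(trimws(as.character(a$elesy)))
  need <- is.na(elesy) | elesy == ""
  elesy[need] <- .infer_element(a$elety[need])
  known <- elesy %in% names(.lrd_masses)
  if (!all(known)) {
    stop("unknown element(s) in PDB: ", paste(unique(elesy[!known]), collapse = ", "))
  }
  atom <- data.frame(
    atom_name = trimws(a$elety),
    element = elesy,
    residue_name = trimws(a$resid),
    residue_id = as.integer(a$resno),
    chain_id = ifelse(is.na(a$chain), "", as.character(a$chain)),
    stringsAsFactors = FALSE
  )
  lrd_structure(atom, xyz)
}

#' Write one or more structures to a PDB file
#'
#' @param x an `lrd_structure`, or a list of them with identical atom
#'   tables (written as a multi-model file), or an `lrd_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "lrd_trajectory")) {
    atom <- x$atom
    xyz <- x$xyz
    mass <- NULL
  } else if (inherits(x, "lrd_structure")) {
    atom <- x$atom
    xyz <- matrix(as_xyz_vec(x$xyz), nrow = 1L)
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "lrd_structure"))) {
    atom <- x[[1L]]$atom
    xyz <- do.call(rbind, lapply(x, function(s) as_xyz_vec(s$xyz)))
  } else {
    stop("cannot write object of class ", paste(class(x), collapse = "/"))
  }
  bio3d::write.pdb(
    file = path, xyz = xyz,
    elety = atom$atom_name, resid = atom$residue_name,
    resno = atom$residue_id, chain = atom$chain_id,
    elesy = atom$element
  )
  invisible(path)
}

#' Subset a structure by atom indices
#'
#' @param x an `lrd_structure`.
#' @param idx integer vector of atom indices to keep.
#' @return An `lrd_structure` with the selected atoms, original order kept.
#' @export
subset_structure <- function(x, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L), all(idx <= x$natoms))
  lrd_structure(x$atom[idx, , drop = FALSE], x$xyz[idx, , drop = FALSE],
                mass = x$mass[idx])
}

#' Replace the coordinates of a structure
#'
#' @param x an `lrd_structure`.
#' @param xyz N x 3 matrix or flat 3N vector of new coordinates (Angstrom).
#' @return The structure with coordinates replaced.
#' @export
set_coords <- function(x, xyz) {
  m <- as_coord_mat(xyz)
  stopifnot(nrow(m) == x$natoms)
  x$xyz <- m
  x
}

#' Indices of backbone atoms (N, CA, C)
#'
#' @param x an `lrd_structure`.
#' @return Integer vector of atom indices whose atom name is N, CA or C.
#' @export
backbone_indices <- function(x) {
  which(x$atom$atom_name %in% c("N", "CA", "C"))
}
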