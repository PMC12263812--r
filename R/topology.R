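#' Nonbonded topology container
#'
#' Per-atom nonbonded force-field parameters for a paired
#' [lrd_structure()]: partial charge (elementary charges), Lennard-Jones
#' sigma (Angstrom) and epsilon (kcal/mol), plus the combination rule used
#' to form pair parameters.
#'
#' @param charge numeric vector, elementary charges.
#' @param sigma numeric vector, Angstrom.
#' @param epsilon numeric vector, kcal/mol (non-negative).
#' @param combination_rule `"lorentz_berthelot"` (arithmetic sigma,
#'   geometric epsilon) or `"geometric"` (geometric for both).
#' @param mass optional numeric vector of masses (amu) carried from the
#'   topology file.
#' @return An object of class `lrd_topology`.
#' @export
lrd_topology <- function(charge, sigma, epsilon,
                         combination_rule = c("lorentz_berthelot", "geometric"),
                         mass = NULL) {
  combination_rule <- match.arg(combination_rule)
  n <- length(charge)
  stopifnot(length(sigma) == n, length(epsilon) == n)
  if (any(!is.finite(charge)) || any(!is.finite(sigma)) || any(!is.finite(epsilon))) {
    stop("non-finite topology parameters")
  }
  if (any(epsilon < 0)) stop("epsilon must be non-negative")
  if (any(epsilon > 0 & sigma <= 0)) stop("sigma must be positive where epsilon > 0")
  out <- list(charge = as.numeric(charge), sigma = as.numeric(sigma),
              epsilon = as.numeric(epsilon), combination_rule = combination_rule,
              mass = if (is.null(mass)) NULL else as.numeric(mass),
              natoms = n)
  class(out) <- "lrd_topology"
  out
}

#' @export
print.lrd_topology <- function(x, ...) {
  cat(sprintf("<lrd_topology> %d atoms, %s combination rule, net charge %.3f e\n",
              x$natoms, x$combination_rule, sum(x$charge)))
  invisible(x)
}

## Strip comments / blank lines from a Gromacs topology and split into
## [section] blocks (names lower-cased).
.top_sections <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^\\[", lines)
  sec_name <- tolower(gsub("[][[:space:]]", "", lines))
  idx <- cumsum(hdr)
  out <- list()
  for (i in which(hdr)) {
    body <- lines[idx == idx[i] & !hdr]
    out[[length(out) + 1L]] <- list(name = sec_name[i], body = body)
  }
  out
}

#' Read nonbonded parameters from a Gromacs-format topology file
#'
#' Parses the subset of the Gromacs .top dialect needed for intermolecular
#' nonbonded energies: `[defaults]` (combination rule), `[atomtypes]`
#' (sigma/epsilon per atom type) and, per `[moleculetype]`, the `[atoms]`
#' table (type, charge, optional mass). Bonded sections are ignored.
#'
#' With `units = "gromacs"` (the native convention) sigma is read in nm
#' and epsilon in kJ/mol and converted to Angstrom and kcal/mol
#' (1 nm = 10 A, 1 kJ/mol = 0.23900574 kcal/mol). With `units = "real"`
#' the file is taken to already be in Angstrom/kcal/mol.
#'
#' @param path path to the topology file.
#' @param structure optional paired [lrd_structure()]; when given, the
#'   molecule whose atom count matches the structure is selected and a
#'   count mismatch is an error.
#' @param units `"gromacs"` (nm, kJ/mol; default) or `"real"`
#'   (Angstrom, kcal/mol).
#' @return An [lrd_topology()].
#' @export
read_topology <- function(path, structure = NULL, units = c("gromacs", "real")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such topology file: ", path)
  secs <- .top_sections(readLines(path, warn = FALSE))
  if (!length(secs)) stop("no sections found in topology: ", path)

  comb <- "lorentz_berthelot"
  atomtypes <- NULL
  molecules <- list()
  cur_mol <- NULL
  for (s in secs) {
    if (s$name == "defaults") {
      if (length(s$body)) {
        f <- strsplit(s$body[1L], "[[:space:]]+")[[1L]]
        cr <- if (length(f) >= 2L) as.integer(f[2L]) else 2L
        comb <- switch(as.character(cr),
                       "2" = "lorentz_berthelot",
                       "3" = "geometric",
                       stop("unsupported comb-rule ", cr,
                            " (only sigma/epsilon rules 2 and 3 are supported)"))
      }
    } else if (s$name == "atomtypes") {
      rows <- lapply(s$body, function(ln) strsplit(ln, "[[:space:]]+")[[1L]])
      ## column layout varies; type name is field 1, sigma/epsilon are the
      ## last two numeric fields (standard Gromacs convention)
      tn <- vapply(rows, `[[`, "", 1L)
      se <- t(vapply(rows, function(f) {
        v <- suppressWarnings(as.numeric(f))
        v <- v[!is.na(v)]
        if (length(v) < 2L) stop("cannot parse [atomtypes] line: need sigma and epsilon")
        utils::tail(v, 2L)
      }, numeric(2L)))
      atomtypes <- rbind(atomtypes,
                         data.frame(type = tn, sigma = se[, 1L], epsilon = se[, 2L],
                                    stringsAsFactors = FALSE))
    } else if (s$name == "moleculetype") {
      cur_mol <- if (length(s$body)) strsplit(s$body[1L], "[[:space:]]+")[[1L]][1L] else "MOL"
    } else if (s$name == "atoms") {
      rows <- lapply(s$body, function(ln) strsplit(ln, "[[:space:]]+")[[1L]])
      ## [atoms]: nr type resnr residue atom cgnr charge [mass]
      typ <- vapply(rows, `[[`, "", 2L)
      chg <- vapply(rows, function(f) {
        if (length(f) < 7L) stop("[atoms] line too short (need charge in field 7)")
        as.numeric(f[7L])
      }, numeric(1L))
      mas <- vapply(rows, function(f) {
        if (length(f) >= 8L) suppressWarnings(as.numeric(f[8L])) else NA_real_
      }, numeric(1L))
      molecules[[length(molecules) + 1L]] <-
        list(name = if (is.null(cur_mol)) "MOL" else cur_mol,
             type = typ, charge = chg, mass = mas)
    }
  }
  if (is.null(atomtypes)) stop("topology has no [atomtypes] section: ", path)
  if (!length(molecules)) stop("topology has no [atoms] section: ", path)

  mol <- molecules[[1L]]
  if (!is.null(structure)) {
    nmatch <- which(vapply(molecules, function(m) length(m$charge), 0L) == structure$natoms)
    if (!length(nmatch)) {
      stop("no molecule in ", path, " has ", structure$natoms,
           " atoms to match the paired structure (found: ",
           paste(vapply(molecules, function(m) length(m$charge), 0L), collapse = ", "), ")")
    }
    mol <- molecules[[nmatch[1L]]]
  }

  ix <- match(mol$type, atomtypes$type)
  if (anyNA(ix)) {
    stop("unresolvable atom type(s): ", paste(unique(mol$type[is.na(ix)]), collapse = ", "))
  }
  sigma <- atomtypes$sigma[ix]
  epsilon <- atomtypes$epsilon[ix]
  if (units == "gromacs") {
    sigma <- sigma * 10
    epsilon <- epsilon * 0.23900574
  }
  lrd_topology(mol$charge, sigma, epsilon, comb,
               mass = if (all(is.na(mol$mass))) NULL else mol$mass)
}

#' Write a nonbonded topology in the Gromacs dialect read by
#' [read_topology()]
#'
#' @param topology an [lrd_topology()].
#' @param structure the paired [lrd_structure()] (atom/residue names).
#' @param path output path.
#' @param molecule_name moleculetype name to write.
#' @param units `"gromacs"` (write nm, kJ/mol) or `"real"`.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, structure, path, molecule_name = "MOL",
                           units = c("gromacs", "real")) {
  units <- match.arg(units)
  stopifnot(topology$natoms == structure$natoms)
  sig <- topology$sigma
  eps <- topology$epsilon
  if (units == "gromacs") {
    sig <- sig / 10
    eps <- eps / 0.23900574
  }
  key <- paste(signif(sig, 10), signif(eps, 10))
  types <- paste0("T", match(key, unique(key)))
  cr <- if (topology$combination_rule == "lorentz_berthelot") 2L else 3L
  mass <- if (is.null(topology$mass)) element_mass(structure$atom$element) else topology$mass
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("; nonbonded topology written by lrdock")
  w("[ defaults ]")
  w("; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ")
  w("1 %d no 1.0 1.0", cr)
  w("")
  w("[ atomtypes ]")
  w("; name  at.num  mass  charge  ptype  sigma  epsilon")
  uk <- !duplicated(key)
  for (i in which(uk)) {
    w("%s  0  %.4f  0.0000  A  %.10g  %.10g", types[i], mass[i], sig[i], eps[i])
  }
  w("")
  w("[ moleculetype ]")
  w("%s 3", molecule_name)
  w("")
  w("[ atoms ]")
  w("; nr type resnr residue atom cgnr charge mass")
  for (i in seq_len(topology$natoms)) {
    w("%d %s %d %s %s %d %.6f %.4f",
      i, types[i], structure$atom$residue_id[i], structure$atom$residue_name[i],
      structure$atom$atom_name[i], i, topology$charge[i], mass[i])
  }
  invisible(path)
}
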