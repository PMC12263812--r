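## Physical constants in the package's working units:
## lengths in Angstrom, energies in kcal/mol, charges in elementary charges.

#' Physical constants used throughout lrdock
#'
#' Boltzmann's constant in kcal/(mol K) and the Coulomb conversion factor
#' in kcal A / (mol e^2), matching Amber conventions.
#'
#' @format Named numeric vector with elements `kB` and `ke`.
#' @export
lrd_constants <- c(kB = 0.0019872041, ke = 332.0636)

## Fixed internal atomic mass table (amu). The Gromacs topology mass column,
## when present, overrides these.
.lrd_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845, SE = 78.971, MN = 54.938, CU = 63.546
)
names(.lrd_masses)[names(.lrd_masses) == "NA."] <- "NA"

.lrd_two_letter <- c("CL", "BR", "ZN", "FE", "MG", "SE", "MN", "CU", "NA")

#' Atomic mass lookup
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  el <- toupper(element)
  m <- .lrd_masses[el]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(el[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

## Infer an element symbol from a PDB atom name when the element column is
## blank. Two-letter ion/metal names are matched exactly; otherwise the
## first alphabetic character decides (so "CA" in a protein is carbon).
.infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  out <- character(length(nm))
  two <- nm %in% .lrd_two_letter
  out[two] <- nm[two]
  out[!two] <- substr(nm[!two], 1L, 1L)
  bad <- !(out %in% names(.lrd_masses))
  if (any(bad)) {
    stop("cannot infer element for atom name(s): ",
         paste(unique(atom_name[bad]), collapse = ", "))
  }
  out
}
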