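## Shared fixture builders. Everything is generated in code at test time;
## nothing is read from checked-in data files.

## simple 3-residue-ish peptide-like structure built by hand
tiny_structure <- function() {
  atom <- data.frame(
    atom_name = c("N", "CA", "C"),
    element = c("N", "C", "C"),
    residue_name = "ALA",
    residue_id = 1L,
    chain_id = "A",
    stringsAsFactors = FALSE
  )
  lrd_structure(atom, rbind(c(0, 0, 0), c(1.46, 0, 0), c(2.0, 1.42, 0)))
}

## random non-degenerate structure with n atoms
random_structure <- function(n, seed = 1, resname = "SYN", chain = "A",
                             elements = NULL) {
  set.seed(seed)
  if (is.null(elements)) elements <- sample(c("C", "N", "O"), n, replace = TRUE)
  atom <- data.frame(
    atom_name = paste0(elements, seq_len(n)),
    element = elements,
    residue_name = resname,
    residue_id = seq_len(n),
    chain_id = chain,
    stringsAsFactors = FALSE
  )
  lrd_structure(atom, matrix(stats::rnorm(3 * n, sd = 4), n, 3))
}

random_topology <- function(n, seed = 1, rule = "lorentz_berthelot") {
  set.seed(seed)
  lrd_topology(
    charge = stats::runif(n, -0.5, 0.5),
    sigma = sample(c(2.5, 3.0, 3.5), n, replace = TRUE),
    epsilon = sample(c(0.05, 0.1, 0.2), n, replace = TRUE),
    combination_rule = rule
  )
}

## quaternion-based uniform random rotation, independent of package internals
oracle_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

## hand-written Gromacs-dialect topology text (units chosen by caller)
write_two_atom_topology <- function(path, sigma, epsilon, comb_rule = 2,
                                    charges = c(0.5, -0.5)) {
  writeLines(c(
    "; hand-written two-atom topology",
    "[ defaults ]",
    sprintf("1 %d no 1.0 1.0", comb_rule),
    "",
    "[ atomtypes ]",
    sprintf("CX 6 12.011 0.0 A %.10g %.10g", sigma, epsilon),
    "",
    "[ moleculetype ]",
    "TWO 3",
    "",
    "[ atoms ]",
    sprintf("1 CX 1 TWO C1 1 %.6f 12.011", charges[1]),
    sprintf("2 CX 1 TWO C2 2 %.6f 12.011", charges[2])
  ), path)
  path
}

two_atom_structure <- function(coords = rbind(c(0, 0, 0), c(3, 0, 0))) {
  atom <- data.frame(
    atom_name = c("C1", "C2"), element = c("C", "C"),
    residue_name = "TWO", residue_id = c(1L, 1L), chain_id = "A",
    stringsAsFactors = FALSE
  )
  lrd_structure(atom, coords)
}

## one-atom structure + topology pair for pairwise-energy checks
point_particle <- function(xyz, element = "C", sigma = 3.0, epsilon = 0.1,
                           charge = 0, resname = "PT", chain = "A") {
  atom <- data.frame(
    atom_name = paste0(element, "1"), element = element,
    residue_name = resname, residue_id = 1L, chain_id = chain,
    stringsAsFactors = FALSE
  )
  list(structure = lrd_structure(atom, matrix(xyz, 1, 3)),
       topology = lrd_topology(charge, sigma, epsilon, "lorentz_berthelot"))
}
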