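Package: lrdock
Title: Flexible-Receptor Docking by Linear Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quasi-static rigid-ligand docking against a flexible receptor
    whose conformational response to ligand forces is modelled by linear
    response within a principal-component (essential dynamics) mode subspace.
    Provides all-atom PCA of conformational ensembles (mass-weighted
    superposition, covariance eigendecomposition, projections, extreme
    structures, RMSIP subspace overlap, mean-square-fluctuation fractions),
    a static-equilibrium receptor relaxation solver with elastic strain
    energy, 12-6 Lennard-Jones plus distance-dependent-dielectric Coulomb
    intermolecular energies and forces, ghost-ligand placement and pose
    analysis utilities, seeded synthetic fixture generators with planted
    covariance spectra and known docking funnels, and a command-line
    front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
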