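# lrdock — flexible-receptor docking by linear response

`lrdock` is an R package for docking a rigid ligand against a receptor
whose conformational flexibility is modelled by **linear response**
within an essential-dynamics (principal component) subspace. It is
aimed at structural bioinformaticians who have an equilibrium ensemble
of a receptor — typically MD snapshots — and want to ask how the
receptor deforms as a ligand approaches, where quasi-static docking
takes the ligand, and what energy barriers separate intermediate from
fully bound poses.

## The model

Let $V_M$ (3N × M) hold the top M orthonormal eigenvectors of the
atomic-displacement covariance of the ligand-free ensemble and
$\lambda_M$ their eigenvalues (Å²). Under forces $f$ from the ligand,
the receptor displacement in static equilibrium satisfies

$$\Delta r = \frac{1}{k_B T} V_M \lambda_M V_M^{t} f(r_o + \Delta r),$$

and deforming the receptor costs the elastic strain energy

$$E_\mathrm{strain} = \tfrac{1}{2} k_B T \, \Delta r^{t} V_M \lambda_M^{-1} V_M^{t} \Delta r,$$

which is added to the 12-6 Lennard-Jones + screened-Coulomb
intermolecular energy to form the total. Automated docking is
quasi-static steepest descent: before every clamped rigid-body ligand
step (translation along the net force, rotation about the net torque
axis) the receptor is fully relaxed into static equilibrium.

The package covers the whole pipeline:

* **I/O** — PDB structures and multi-model trajectories (via bio3d), a
  Gromacs-format nonbonded topology subset, a documented plain-text
  mode-basis dialect, YAML run configuration.
* **Trajectory analysis** — mass-weighted Kabsch superposition,
  ensemble fitting, snapshot-SVD PCA, projections, extreme-projection
  structures (ready for domain-motion analysis), RMSIP subspace
  overlap, MSF fractions.
* **Energetics** — LJ 12-6 with Lorentz–Berthelot or geometric
  combination rules, Coulomb with a distance-dependent dielectric,
  exact analytic forces, net force/torque on a rigid body.
* **Docking** — static-equilibrium receptor relaxation, automated
  quasi-static docking with per-step traces, ghost-ligand placement and
  RMSD, scripted bias ("gentle push") segments with path-based barrier
  estimates, contact counts and polar-contact reports.
* **Synthetic fixtures** — seeded planted-covariance receptors and
  verified docking funnels, so everything is testable offline.
* **CLI** — `lrdock pca|dock|rmsip|ghost|contacts|synth` (installed
  under `exec/`), emitting run manifests with input hashes and seeds.

Units: Å, kcal/mol, elementary charges, Kelvin (Amber conventions,
$k_e = 332.0636$, $k_B = 0.0019872041$).

## Worked example

Recover a planted mode basis from a synthetic ensemble, then dock a
ligand into a funnel whose global-minimum pose is known by
construction:

```r
library(lrdock)

model  <- make_planted_receptor(25, c(10, 5, 1, 0.1), seed = 42)
traj   <- sample_trajectory(model, 2000, rigid_motion = TRUE, seed = 43)
fitted <- fit_trajectory(traj, reference_frame = model$structure)
basis  <- pca_modes(fitted, n_modes = 4)
basis
#> <lrd_mode_basis> N = 25 atoms, M = 4 modes, T = 300 K
#>   top eigenvalues (A^2): 10.23, 4.737, 0.9892, 0.109
#>   retained / total variance: 100.0%
rmsip(basis, model$basis, 4)       # 0.993
msf_fraction(basis, 2)             # 0.931

fun   <- make_funnel_complex(seed = 3)
start <- rigid_pose(fun$ligand$xyz, translation = c(0.8, -0.5, 0.6))
trace <- auto_dock(fun$structure, fun$topology, fun$basis,
                   fun$ligand, fun$ligand_topology,
                   start_pose = start, ghost = fun$ligand)
trace
#> <lrd_docking_trace> 15 steps, termination: converged
#>   final E_total = -13.876 kcal/mol (interaction -13.877, strain 0.001)
rmsd_to_ghost(attr(trace, "final_pose"), fun$ligand)   # 0.072 A
```

The recovered eigenvalues sit within a few percent of the planted
spectrum (10, 5, 1, 0.1 Å²) and the recovered 4-mode subspace overlaps
the planted one at RMSIP 0.993. Docking from the displaced start
descends monotonically from +30.3 to −13.9 kcal/mol and stops 0.07 Å
from the planted global minimum; the per-step trace records the energy
breakdown, receptor displacement norm and its projections on the
leading modes.

The same run from the shell:

```sh
lrdock synth --kind funnel --seed 3 --out-dir fix --prefix fun
lrdock dock --receptor fix/fun_receptor.pdb --receptor-top fix/fun_receptor.top \
  --modes-eval fix/fun_eigenvalues.txt --modes-evec fix/fun_eigenvectors.txt \
  --ligand fix/fun_ligand.pdb --ligand-top fix/fun_ligand.top \
  --cutoff 100 --out-trace trace.csv --out-pose pose.pdb
```

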