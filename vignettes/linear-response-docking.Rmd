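---
title: "Flexible-receptor docking by linear response: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible-receptor docking by linear response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrdock)
```

## The model

lrdock docks a rigid ligand against a receptor whose flexibility is
modelled by **linear response** within a truncated principal-component
subspace. The premise is the fluctuation–response relation: the
equilibrium fluctuations of the unperturbed receptor predict its
deformation under an external perturbation. If $V_M$ ($3N \times M$)
holds the top $M$ orthonormal eigenvectors of the atomic-displacement
covariance of an equilibrium conformational ensemble, and $\lambda_M$
the corresponding eigenvalues (Å$^2$), then the receptor displacement
$\Delta r$ in static equilibrium with the ligand forces
$f(r_o + \Delta r)$ satisfies

$$
\Delta r \;=\; \frac{1}{k_B T}\, V_M \lambda_M V_M^{t}\, f(r_o + \Delta r),
$$

where $r_o$ is the relaxed reference conformation. Because $f$ depends
on the displaced coordinates, this is a self-consistency condition, not
a one-shot formula. The elastic energy of any deformation within the
subspace is the quadratic **strain energy**

$$
E_\mathrm{strain} \;=\; \tfrac{1}{2} k_B T\, \Delta r^{t} V_M \lambda_M^{-1} V_M^{t} \Delta r ,
$$

which is added to the intermolecular interaction energy to form the
total energy. Soft (large-$\lambda$) modes deform cheaply; stiff modes
resist. Both operators are evaluated through the mode amplitudes
$a = V_M^t \Delta r$, never by forming the $3N \times 3N$ matrices
(`response_displacement()`, `strain_energy()`).

**Assumptions.** (i) Fluctuations are Gaussian (harmonic/elastic
approximation); anharmonic rearrangements outside the sampled ensemble
are represented only to the extent the retained modes can express them.
(ii) The ligand is rigid. (iii) Receptor internal energetics are fully
captured by the strain term; the force field computes intermolecular
terms only.

## Automated quasi-static docking

`auto_dock()` alternates two relaxations. Before every ligand step the
receptor is brought into static equilibrium with the current ligand
forces by the damped fixed-point iteration
$\Delta r \leftarrow (1-\gamma)\,\Delta r + \gamma\, \mathcal{R}(f(r_o+\Delta r))$,
where $\mathcal{R}$ is the linear-response map (`static_equilibrium()`).
The ligand then takes one steepest-descent rigid-body step: it is
translated along the net force and rotated about the net torque axis
through its centre of mass, with per-step clamps. A trial step that
raises the total energy (re-evaluated after receptor relaxation) is
rejected and retried at half scale; the scale recovers geometrically.
The loop terminates when net force and torque fall under their
thresholds. Because the receptor is fully relaxed at every recorded
step, the trace satisfies the quasi-static contract: the equilibrium
residual is at most the solver tolerance row by row.

A **ghost ligand** — the ligand at its experimentally bound pose,
mapped into the receptor frame by superposing the holo protein on the
receptor (`place_ghost()`) — serves as a passive reference for RMSD; it
never exerts or feels forces, which the test suite asserts by running
identical docks with and without one.

The "gentle push" used to carry a ligand over an energy barrier in an
interactive session is reproduced non-interactively as a scripted
**bias segment**: a constant external force added to the net ligand
force for a fixed number of steps, during which steps are accepted
unconditionally (the push is allowed to climb). `barrier_estimate()`
then reports the maximum total energy along the realised path minus the
starting (intermediate-pose) energy. This is deliberately a
path-dependent estimate — an upper bound along the path actually taken,
not a minimum-energy-path barrier — and is labelled as such.

## Obtaining the mode basis

`pca_modes()` performs the standard essential-dynamics pipeline:
mass-weighted least-squares superposition of every frame onto a
reference (`fit_trajectory()`, Kabsch with proper rotations only),
arithmetic ensemble average, and eigendecomposition of the displacement
covariance. Two choices deserve note:

* **Snapshot SVD route.** The covariance eigenpairs are computed by thin
  SVD of the centred $F \times 3N$ snapshot matrix rather than by
  forming the $3N \times 3N$ covariance. The two routes are numerically
  identical (asserted against `eigen(cov(X))` in the tests), but the
  snapshot route stays affordable when $3N$ is large.
* **Reference coordinates.** The arithmetic average of fitted frames is
  generally not a viable bonded structure, so the emitted basis uses the
  closest-to-average *frame* as $r_o$ (`closest_to_average()`, ties to
  the lowest index). Coordinates are unweighted in the covariance; mass
  weighting applies to the fit only.

Subspace agreement between bases is measured by the root mean-square
inner product, $\mathrm{RMSIP}(m) = \sqrt{\frac{1}{m}\sum_{i\le m}\sum_{j\le m} (u_i\!\cdot\! v_j)^2}$,
which is 1 for identical subspaces, 0 for orthogonal ones, and invariant
to rotations within either span. Mode importance is quoted as the
cumulative eigenvalue fraction of the covariance trace
(`msf_fraction()`), which is why the basis records the full trace, not
just the retained eigenvalues. Backbone-only analysis is the same code
path under an N/CA/C atom selection.

## Force field

Intermolecular energies are a 12-6 Lennard-Jones term with
combination-rule pair parameters (Lorentz–Berthelot or geometric, as
declared by the topology) plus a screened Coulomb term
$k_e q_i q_j / (\varepsilon_r(r)\, r)$ with
$k_e = 332.0636$ kcal Å mol$^{-1}$ e$^{-2}$. Solvent screening uses a
**distance-dependent relative permittivity**, by default the linear form
$\varepsilon_r(r) = r/\mathrm{Å}$ — the simplest standard screening
model. The dielectric is pluggable (`dielectric_linear()`,
`dielectric_constant()`, selectable in `run_config()`), so a sigmoidal
variant can be dropped in without touching callers. The cutoff is a
hard truncation with no switching function; the docking default of
100 Å (versus 8 Å for interactive-style evaluation) exists precisely so
that no atom pair crosses the cutoff boundary during a descent, which
would otherwise produce energy jumps. The zinc ion, when present in a
topology, is an ordinary 12-6 particle. Forces are exact analytic
negative gradients of the truncated sum; Newton's third law holds pair
by pair, and the tests compare every component against central finite
differences. Units are Å, kcal/mol, elementary charges and Kelvin
throughout, with $k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$.

Hydrophobic/solvation free-energy terms, polarisation and lattice
electrostatics are out of scope, as is any intramolecular energy.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff` | 100 (docking), 8 available | Å | no cutoff crossings during descent |
| `temperature` | 300 | K | ensemble temperature of the mode basis |
| `dielectric` | linear, slope 1 | — | standard distance-dependent screening |
| `solver$gamma` | 0.2 | — | damping of the fixed-point receptor update |
| `solver$tol` | 1e-4 | Å | equilibrium residual norm |
| `solver$max_iter` | 2000 | — | relaxation budget per evaluation |
| `docking$step_t` | 0.02 | Å per kcal/mol/Å | steepest-descent translation scale |
| `docking$step_r` | 0.005 | rad per kcal/mol/rad | rotation scale |
| `docking$max_t`, `max_r` | 0.1 Å, 0.02 rad | | per-step clamps: quasi-static steps stay small |
| `docking$f_tol`, `tau_tol` | 0.5, 0.5 | kcal/mol/Å, kcal/mol/rad | convergence thresholds |
| number of modes $M$ | caller-chosen; 100 is a typical operating point for a ~5500-atom receptor (roughly two-thirds of the total MSF) | | speed/completeness trade-off |

The rotation pivot is the ligand centre of mass (exposed in the code
path, not hard-wired into the physics). The iteration scheme itself is
a design choice: only the equilibrium residual condition is normative,
and any solver meeting it is conformant; damped fixed-point iteration
was chosen for robustness at stiff spectra.

## What the synthetic generators emulate

`make_planted_receptor()` + `sample_trajectory()` stand in for an MD
ensemble: frames are $r_o + \sum_i a_i V_i$ with
$a_i \sim \mathcal{N}(0, \lambda_i)$ — exactly the Gaussian model linear
response assumes — optionally wrapped in random per-frame rigid
transforms to exercise the superposition machinery. Planted
eigenvectors are drawn orthogonal to the six-dimensional rigid-body
subspace of the reference geometry, as real fitted-ensemble covariances
are; without this, superposition strips the rigid components of each
planted mode and systematically deflates recovered eigenvalues by about
$6/3N$. Amplitudes are drawn before any rigid transforms, so paired
seeds give identical internal motions with and without rigid motion.

`make_funnel_complex()` builds a desk-scale docking landscape whose
answer is known by construction: an attractive spherical shell
(pair-minimum distance matched to the shell radius, so the interior is
strongly favoured) with an aperture. The planted pose is locally
minimised at generation time and then *verified* to be the global
minimum by a seeded random scan over poses; generation fails rather
than returning an unverified fixture. The two-minimum variant adds a
rim ring sized to make the neck mildly repulsive (a few kcal/mol), so
a mouth-side local minimum, a barrier, and a deeper interior minimum
sit on one axis — the topology of an intermediate binding pose guarding
a fully inserted pose — together with a ready-made bias that carries
the ligand across.

What these fixtures do **not** emulate: bonded protein geometry,
anisotropic/anharmonic fluctuations, water, zinc coordination
chemistry, or realistic charge distributions. Passing tests demonstrate
the correctness of the machinery (operators, solvers, bookkeeping,
file formats) under the model's own assumptions — not predictive
accuracy on real receptor–ligand systems, which additionally depends on
force-field fidelity and the sampled ensemble.

Test and acceptance problem sizes were chosen so that dense
$3N \times 3N$ oracles are affordable: planted receptors of 8–50 atoms
with up to 6 modes for the operator oracles, 25 atoms × 5000 frames for
spectrum recovery, and a ~55-atom cage for docking. These sizes are a
package choice for oracle affordability; the implementation paths are
the same at any size.

## Numerical choices and degenerate inputs

* Superposition requires at least 3 non-collinear selection atoms and
  always returns a proper rotation (det = +1), guarded by an SVD sign
  correction; reflections are never produced.
* `mode_basis()` re-sorts eigenpairs into descending order, requires
  strictly positive retained eigenvalues, and rejects column sets that
  are not orthonormal to 1e-8.
* Composed pose rotations are re-orthonormalised by SVD each step to
  stop drift over long traces.
* Overlapping receptor/ligand atoms (r < 1e-6 Å) are an error naming
  the pair, not a silent infinity.
* Zero torque (below 1e-12) yields an identity rotation increment;
  `closest_to_average()` breaks ties to the lowest frame index.
* Receptor relaxation failure raises a typed condition
  (`lrd_nonconvergence`) carrying the last state, and `auto_dock()`
  annotates it with the docking step.
* Energies are reported with the invariant total = (LJ + electrostatic)
  + strain, checked to 1e-10 in the trace.

## Known limitations

* The linear dielectric is a stand-in for whatever screening model a
  given published energy was computed with; absolute energies are only
  comparable across implementations once the dielectric form matches.
* Steepest descent with step clamps finds the local minimum of the
  basin it starts in — by design (the barrier-crossing experiment
  depends on it) — so binding-site *search* is out of scope.
* The ligand is rigid; torsional flexibility would change barrier
  estimates for caps squeezing through narrow apertures.
* The strain model cannot price deformations outside the retained
  subspace, and no operation ever creates such components; a too-small
  $M$ silently stiffens the receptor.

## A minimal end-to-end run

```{r example, eval = FALSE}
model <- make_planted_receptor(25, c(10, 5, 1, 0.1), seed = 42)
traj <- sample_trajectory(model, 2000, rigid_motion = TRUE, seed = 43)
fitted <- fit_trajectory(traj, reference_frame = model$structure)
basis <- pca_modes(fitted, n_modes = 4)
rmsip(basis, model$basis, 4)          # subspace recovery
msf_fraction(basis, 2)                # share of total MSF in two modes

fun <- make_funnel_complex(seed = 3)
trace <- auto_dock(fun$structure, fun$topology, fun$basis,
                   fun$ligand, fun$ligand_topology, ghost = fun$ligand)
attr(trace, "termination")
rmsd_to_ghost(attr(trace, "final_pose"), fun$ligand)
```
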