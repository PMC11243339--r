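---
title: "Elastic-network modes and interface statistics for enzymes on carbon nanostructures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network modes and interface statistics for enzymes on carbon nanostructures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmox)
```

## The problem

Glucose oxidase (GOx) is a homodimeric flavoenzyme whose FAD cofactor
oxidizes glucose; immobilizing it on conductive carbon nanomaterials
(graphene sheets, single-walled carbon nanotubes and their composites)
is a standard route to enzymatic biosensor and biofuel-cell electrodes.
Two computational questions recur in that setting:

1. **How does immobilization change the enzyme's collective dynamics?**
   Answered here with an all-atom, distance-weighted elastic network
   model (ENM) and normal-mode analysis (NMA): natural frequencies and
   modal shapes of the enzyme free in solution versus bound to a carbon
   surface.
2. **How efficient is direct electron transfer at the resulting
   electrode?** Answered from scan-rate-dependent cyclic voltammetry
   (CV): the growth of the redox peak separation with scan rate yields
   an apparent heterogeneous electron-transfer rate constant.

Around these two cores the package provides the supporting machinery:
honeycomb-lattice generators for the carbon supports, PDB/XYZ I/O,
trajectory interface statistics (RMSD, radius of gyration, contacts,
minimum distance, tail averaging), and synthetic generators that
produce every input with known ground truth, so the whole pipeline is
testable without any external data.

## The elastic network model

Heavy atoms only (hydrogens and deuteriums are stripped) are joined by
harmonic springs at their reference separations. Pairs closer than a
cutoff interact with a distance-weighted stiffness

$$k(r) = k_0 \, \exp\!\left(1 - (r/r_0)^2\right),$$

which equals $k_0$ at $r = r_0$ and decays with distance. Defaults are
$k_0 = 100$ kcal/(mol Å$^2$) and $r_0 = 5$ Å, with interactions
smoothly cut off within 12 Å. Because only the product
$k_0 \times$(geometry) enters the eigenproblem, $k_0$ sets the overall
frequency scale ($\omega \propto \sqrt{k_0}$, a tested invariant) while
$r_0$ shapes the relative weighting of short against long contacts.

**Smooth cutoff.** The functional form of "smoothly cut off" is a
genuine design choice; we multiply $k(r)$ by a cubic smoothstep falling
from 1 at `switch_start` (default 10 Å) to 0 at `cutoff` (12 Å). This
keeps every spring below 10 Å untouched, is $C^1$ at both ends, and
both bounds are configurable. The stiffness function itself is
injectable (`spring_fun` in `build_network()`), so an alternative
distance weighting can be swapped in without touching the assembly
code.

**Hessian.** The potential is
$E = \tfrac12 \sum_{ij} k_{ij} (|x_i - x_j| - r^0_{ij})^2$. At the
reference configuration its second derivative has the closed form used
by `assemble_hessian()`: the off-diagonal $3\times3$ block of pair
$(i,j)$ is $-(k_{ij}/r_{ij}^{0\,2}) \, d_{ij} d_{ij}^T$ with $d_{ij}$
the reference separation vector, and each diagonal block is minus the
sum of the row's off-diagonal blocks. That construction is exactly
symmetric, annihilates rigid translations, and is positive
semi-definite; the test suite additionally checks it against a central
finite-difference Hessian of an independently coded energy.

**Mass weighting and frequencies.** Normal modes come from
$H' = M^{-1/2} H M^{-1/2}$ with $M$ the diagonal matrix of atomic
masses; $\omega_k = \sqrt{\lambda_k}$. The internal frequency unit is
$\sqrt{\text{kcal mol}^{-1}\text{Å}^{-2}\text{amu}^{-1}}$;
`freq_unit_to_cm1()` converts to spectroscopic wavenumbers
(1 internal unit $\approx$ 108.6 cm$^{-1}$), a factor derived by unit
analysis and verified in the tests against an SI hand computation of
the diatomic.

## Solving the eigenproblem

Below 300 atoms (configurable) the dense symmetric `eigen()` is used.
Large systems use ARPACK Lanczos (via igraph) **directly on the sparse
$H'$**, with the six analytically constructed rigid-body vectors
deflated by a low-rank spectral shift: the operator becomes
$H' + \beta V V^T$ with $V$ the orthonormal rigid basis and $\beta$
twice the Gershgorin bound, so the rigid modes move to the top of the
spectrum and the physically interesting low modes become the extremal
ones. This needs only matrix-vector products. We deliberately avoid
shift-invert: an all-atom network at a 12 Å cutoff couples each atom to
several hundred neighbours, and sparse Cholesky fill-in on the
resulting $3N \times 3N$ matrix (27,000 coordinates at GOx-dimer
scale, ~24 M nonzeros) exceeds a desktop memory budget, whereas the
deflated direct iteration converges in a few hundred matvecs. A
9,000-atom globule resolves its lowest nine non-rigid modes in about a
minute on one CPU; the acceptance suite runs exactly that computation.

**Rigid modes.** Flagged when $\lambda < 10^{-8} \lambda_{\max}$ and
cross-checked by projection onto the analytic translation/rotation
basis (a disagreement warns rather than fails, since it usually
signals a degenerate *input*, not a solver problem). A non-collinear
3-D structure has exactly 6; a diatomic has 5. Perfectly collinear
chains of three or more atoms and perfectly planar sheets are
degenerate inputs for any pairwise-distance network: transverse or
out-of-plane displacements cost no energy to second order, so extra
zero modes appear. This is a property of the model, not a bug; the
tests pin it down, and "first three modes" always means the first
three *non-rigid* modes.

**Determinism and degeneracy.** Eigenvector signs are fixed by making
the largest-magnitude component positive. Eigenvalues within
$10^{-10}$ relative are reported as degenerate blocks
(`degenerate_groups`); overlap-based comparisons should restrict to
well-separated modes (the rotation-invariance test filters on a
relative spectral gap of $10^{-3}$).

**Immobilized condition.** Surface atoms can enter the network as
mobile nodes or be held as rigid anchors (`fixed` in
`assemble_hessian()`); anchor springs add only to their partner's
diagonal block, removing translation invariance and lifting the rigid
modes. Anchoring adds a positive semi-definite term on the enzyme's
own degrees of freedom, so by eigenvalue monotonicity no mode can
soften — the testable form of the observation that immobilization
stiffens the enzyme. Note the comparison subtlety visible in
`analysis/02_normal_modes.R`: the lowest modes of the anchored system
are tethered librations of the whole enzyme on its contact springs,
which may lie *below* the bulk internal modes; monotonicity holds
mode-for-mode against the full bulk spectrum (whose first six entries
are zeros), not between the two "first non-rigid" triplets.

## Carbon geometry builders

Graphene is generated as a honeycomb lattice with a C–C bond of
exactly 1.42 Å (armchair edge along x by default), trimmed to the
requested rectangle; nanotubes by the standard roll-up construction
with arc-length mapping, so bonds keep their length along the curved
surface and chord distances shrink by well under 0.05 Å at the
diameters used. The lattice constant is derived from the bond
($\sqrt3 \times 1.42 = 2.4595$ Å); diameters agree with the
conventional $d = (2.46/\pi)\sqrt{n^2+nm+m^2}$ Å formula within
0.01 Å. These conventions (bond length, lattice constant) are standard
generator values, stated here because upstream descriptions of such
builders rarely pin them down.

## Synthetic data: what it emulates and what it does not

- `make_random_globule()` emulates the compact heavy-atom cloud of a
  globular dimeric enzyme: uniform in a sphere, minimum pair
  separation 1.0 Å (rejection sampling; keeps the spring geometry
  non-degenerate), two chain labels. At GOx-dimer scale we use 9,000
  atoms in a 35 Å sphere, matching a realistic heavy-atom density of
  ~0.05 Å$^{-3}$.
- `make_trajectory()` emulates recorded MD output (1 ps intervals):
  per-frame rigid rotation + translation plus isotropic Gaussian noise
  per coordinate. Frame 0 is always the noise-free reference. The
  testable contract: the expected superposed RMSD of a noisy frame
  against the base is $\sigma\sqrt3$, a generator property used to
  validate the RMSD machinery (recovered within 3% at 5,000 atoms).
- `make_synthetic_cv()` emits peak tables from the same Laviron
  forward model the estimator inverts (below), with optional Gaussian
  peak-potential noise; `make_cv_trace()` builds full two-branch
  traces with Gaussian waves on a linear capacitive baseline for the
  peak-extraction path.

None of this emulates force-field physics, solvent, realistic protein
topology, or real electrode kinetics. Passing tests therefore
demonstrate that the *operations* are implemented correctly (against
closed forms, brute force, and independent oracles), not that the
synthetic systems reproduce any particular experimental value. The
headline numbers of the motivating experimental systems (sub-nm RMSD
plateaus, ten-thousand-scale contact counts, specific fold changes)
require long explicit-solvent MD or laboratory CV data and are out of
scope by design.

All generators are pure functions of their arguments and seed, using
R's default Mersenne-Twister generator, and restore the caller's RNG
state.

## Interface statistics

Superposition uses the Kabsch algorithm (SVD with a proper-rotation
correction, optional mass weighting); the tests check it against an
exhaustive rotation-grid search and an established implementation.
Radius of gyration is mass-weighted. Contacts are **pairs** of atoms
(one from each selection) closer than a configurable cutoff —
defaulting to 6.0 Å, a common choice that the source analyses leave
unstated — with a unique-atom mode (`mode = "atoms"`) provided because
"number of contact atoms" is ambiguous between the two conventions.
Contact counting and minimum distance use a cell grid and are
tested equal to the $O(N^2)$ loop. Coordinates are Å internally;
RMSD, Rg and minimum distance are reported in nm to match the field's
reporting habits. Tail averaging (`window_average()`) takes the mean
over the half-open trailing window $(t_{end} - w,\; t_{end}]$, so a
window of $w$ ps covers exactly the trailing $w$ samples at 1 ps
spacing.

## Electron-transfer rates from scan-rate CV

For a surface-confined couple, Laviron's analysis predicts the anodic
and cathodic peaks to sit at the formal potential $E^0$ in the
slow-scan (reversible) limit, and to fan out linearly in $\ln v$
beyond characteristic scan rates set by the rate constant:

$$E_{pa} = E^0 + \max\!\left(0,\; \frac{RT}{(1-\alpha)nF}
  \ln \frac{v}{v_a}\right),\qquad
  v_a = \frac{RT k_s}{(1-\alpha) n F},$$

and symmetrically for the cathodic branch with $\alpha$ in place of
$1-\alpha$. `estimate_ks()` inverts this in closed form: over the scan
rates with resolvable separation (> 10 mV by default), each branch's
peak potential is linear in $\ln v$ with slope fixed by $\alpha$, and
the two branch intercepts give $E^0$ and $\ln k_s$ directly; a short
refinement pass re-selects the usable rates when $\alpha$ is far from
0.5. Defaults $\alpha = 0.5$, $n = 2$, $T = 298.15$ K are the typical
two-electron FAD treatment, all configurable and echoed in the output.

Two consequences worth knowing. First, the generator and estimator
share this forward model, so the zero-noise round trip is exact — that
is a *consistency* check, not evidence about real electrodes; the
peak-*extraction* path is validated separately on constructed traces
with baselines. Second, the model dictates a measurable window: at
10–120 mV/s and $n = 2$, peaks only separate for
$k_s \lesssim 4.7$ s$^{-1}$, so the synthetic electrodes use rate
constants of 0.05–0.23 s$^{-1}$, chosen inside the window, with
designed ratios 4.61 and 2.45 (composite vs. CNT and vs. graphene)
mirroring the reported fold differences between such electrodes. With
2 mV peak noise, 0.1 s$^{-1}$ is recovered with a mean error well
under 5% across 100 replicates. The experimental method this stands in
for was described by its authors only as Marcus-theory-based with
details in an unavailable appendix; the Laviron regression here is a
documented, injectable substitute model, and recovered rates should
not be attributed to that unpublished procedure.

## Problem sizes and numerical choices

The test and analysis scales were chosen as the smallest sizes at
which each property is sharply testable: finite-difference Hessian
checks on 5–10 atoms ($h = 10^{-5}$ Å, agreement to $10^{-6}$
relative); scaling laws and rotation invariance on 100-atom globules
(to $10^{-8}$); monotone stiffening on 20 seeded 25-atom fixtures;
the $\sigma\sqrt3$ contract at 5,000 atoms and 50 frames (3%);
feasibility at 9,000 atoms (lowest 9 non-rigid modes, sparse path).
Coincident atoms (zero rest length) are rejected at network build;
eigensolver tolerance is $10^{-9}$ with a 100,000-iteration cap;
rigid detection at $10^{-8}$ relative; degeneracy grouping at
$10^{-10}$ relative.

## Known limitations

- The ENM is harmonic and topology-blind: no force-field normal
  modes, no solvent damping, no thermodynamics from modes.
- Degenerate inputs (collinear, planar) carry extra zero modes, as
  discussed above; use 3-D fixtures for rigid-mode assertions.
- No chemical decoration of the carbon supports (GO/rGO
  functionalisation) and no docking; geometry only.
- The CV module handles peak positions only; it does not simulate
  full Butler–Volmer transients, and baseline correction is linear.
- `mode_overlap()` compares modes pairwise; for degenerate blocks use
  the block structure reported by the solver and compare subspaces.
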