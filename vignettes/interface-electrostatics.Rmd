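---
title: "Continuum electrostatics of protein-protein binding interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum electrostatics of protein-protein binding interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifacelec)
```

## Scope

Long-range electrostatics steers protein-protein association long before
shape complementarity takes over, and short-range polar contacts (hydrogen
bonds, salt bridges) then lock the complex in place. A well-studied example
is the tubulin system: the four head-to-tail and lateral binding modes of
alpha- and beta-tubulin differ markedly in their electrostatic
complementarity, which rationalises why free monomers assemble into
alpha/beta dimers and why protofilaments separate more easily laterally than
longitudinally. `ifacelec` packages the three computations such a study
rests on:

1. a finite-difference Poisson-Boltzmann (PB) solver producing potential
   maps in kT/e from a charged structure,
2. a rigid-body separation scan that classifies a two-molecule binding mode
   as attractive or repulsive from the net electrostatic force at a series
   of center-of-mass separations, and
3. a conformational-ensemble analysis of interface hydrogen-bond and
   salt-bridge occupancies with distance/angle cutoffs and reporting tiers.

A fourth, first-class component generates synthetic inputs with known
answers — analytically solvable charge configurations and trajectories with
planted contact statistics — so that every stage is testable without any
external structure or simulation.

## The model

The electrostatic potential $\phi(\mathbf r)$ (in units of $kT/e$) around a
fixed charge distribution in an ionic solvent obeys the Poisson-Boltzmann
equation

$$
\nabla \cdot \left[\varepsilon(\mathbf r)\,\nabla\phi(\mathbf r)\right]
 \;=\; -4\pi C\,\rho(\mathbf r)
 \;+\; \bar\kappa^2(\mathbf r)\,\sinh\phi(\mathbf r),
$$

where $\varepsilon$ is the position-dependent relative permittivity,
$\rho$ the permanent charge density of the solute (e/Å$^3$),
$\bar\kappa^2 = \varepsilon_s \kappa^2$ the modified screening coefficient
with $\kappa$ the Debye-Hückel parameter, and
$C = e^2/(4\pi\varepsilon_0 k_B T)$ the Coulomb constant in thermal units
(the vacuum Bjerrum length, ≈ 557 Å·kT/e at 300 K — computed from CODATA
constants at run time, never hard-coded). $\kappa$ is derived from the ionic
strength $I = \tfrac12\sum_i c_i z_i^2$; at 150 mM 1:1 salt in water the
screening length $1/\kappa$ is about 7.95 Å. Divalent cations enter through
the same mean-field ionic strength (`salt_ions(0.15, z_plus = 2)`), which is
the appropriate treatment at the linearised level; ion-ion correlations are
outside the model.

### Discretisation

The equation is discretised on a regular cubic grid with a 7-point stencil.
Permittivity is stored per node and harmonically averaged at stencil faces,
the standard conservative treatment of the dielectric jump. Atomic charges
are spread to the 8 surrounding nodes with trilinear weights (exactly charge
conserving). The solute envelope is the union of atom spheres inflated by
the 1.4 Å solvent probe (`surface_inflation = 1`); the true reentrant
molecular surface is *not* constructed — a documented simplification that
keeps the map construction exact and testable. Mobile ions are additionally
excluded from a Stern shell of 2.0 Å measured from the vdW radius.

The linear system is solved by red-black successive over-relaxation
(ω = 1.9, tolerance 10⁻⁶ kT/e on the maximum node update, at most 10,000
sweeps); the checkerboard ordering makes results independent of sweep
direction. In nonlinear mode the sinh term is kept and each node update
performs one Newton linearisation of sinh about the current value
(nonlinear SOR, run without over-relaxation). An outer fixed-point
("Picard") iteration around the linear solver was considered and rejected:
once $|\phi|$ exceeds a few kT/e near a charged surface, sinh grows so fast
that no fixed damping factor keeps the outer iteration stable, whereas the
per-node Newton step inherits SOR's robustness and converges even for a
q = +4 e test ion.

### Grid geometry and boundary values

The cubic box is sized so the structure fills 70% of the edge (a
`fill_percent` parameter), floored at 20 Å, centered on the bounding-box
center; node counts default to at most 97 per axis. Three boundary modes are
provided. `coulomb_dh` (default) sums, per atom, the screened-Coulomb
potential of a charge with ion-exclusion radius $a$ (vdW + Stern):
$\phi_b = qC\,e^{-\kappa(r-a)} / (\varepsilon_s r (1+\kappa a))$.
`dipole_dh` applies the same form to the structure's net monopole plus point
dipole at its center of charge — the analogue of the "dipolar" boundary
condition of DelPhi-style solvers, whose exact formula is not published;
both modes are provided and agree asymptotically for compact charge
distributions (a property test). `zero` is available for debugging. Note the
$e^{-\kappa(r-a)}$ factor: dropping the $e^{+\kappa a}$ surface term (a
tempting simplification) biases the whole far field low by
$1 - e^{-\kappa a}$, which is a 22% error already at $a = 2$ Å and 150 mM —
this was caught by the Born-ion oracle during development.

### Validation against closed forms

The canonical solver oracle is the Born ion: a charged sphere whose exterior
potential has the closed form
$\phi(r) = qC\,e^{-\kappa(r-b)}/(\varepsilon_s r(1+\kappa b))$ with $b$ the
ion-exclusion radius. `born_ion_potential()` implements the general
piecewise solution (Coulombic Stern shell between sphere radius and $b$,
screened outside), so the oracle stays consistent with whatever
`stern_radius` the solver uses. The headline benchmark solves
q = +1 e, a = 2 Å, ε = 2/80, 150 mM salt on a 65³ grid at 0.5 Å spacing with
the exclusion boundary at the sphere radius itself (`stern_radius = 0`), the
configuration in which the textbook form applies verbatim; the measured
maximum relative error over all exterior nodes (r ≥ a + 2 h) is about 1.4%,
against a 5% acceptance band, and decreases under grid refinement. A second
test keeps the default 2 Å Stern shell and checks against the
shell-corrected closed form (≈1.3%). The zero-salt limit is checked against
plain Coulomb, linearity against charge scaling, and symmetry against
coordinate permutations.

## Force scan and binding-mode classification

The net electrostatic force of molecule A on molecule B uses the two-solve
scheme: the PB equation is solved with **A's charges only** but with the
dielectric and ion-exclusion maps of the **full A+B complex** (B contributes
its low-dielectric cavity, not its charges); the force on each B atom is
then $q_B \mathbf E$ with $\mathbf E = -\nabla\phi$ from central differences
interpolated at the atom position. Dielectric-boundary and ionic-pressure
force terms are omitted — at the ≥ 14 Å separations of a scan the $q\mathbf E$
term dominates the attract/repel trend, and the omission is the documented
price of a transparent force definition. Newton's third law, which is not
built into the scheme (it takes two independent solves), is recovered to
≈10⁻¹²% on the symmetric dumbbell fixture and is asserted within 5% as an
acceptance property.

The separation scan translates B rigidly along the line joining the two
centroids (PQR files carry no masses, so "center of mass" is operationally
the unweighted centroid). The scanned distances are **offsets added to the
bound-state geometry**, the reading adopted for the conventional 14-40 Å
range in 2 Å steps (14 points); an absolute-center-distance mode is
available behind `mode = "absolute"` since the zero point is a genuine
ambiguity. Each point re-solves on a grid sized to the instantaneous
complex, so box artifacts do not grow with separation. A point is
**attractive** iff the net force on B has negative component along the A→B
axis; flipping all of B's charges provably flips every classification (a
property test). On an opposite-charge dumbbell in 150 mM salt the profile
decays strictly monotonically and the 40 Å force is ≈2% of the 14 Å force —
the screened-Coulomb envelope behind the qualitative statement that at 40 Å
two proteins effectively stop interacting.

## Interface contacts and occupancies

Contacts are evaluated per ensemble frame with inclusive cutoffs:

* **Hydrogen bond**: donor-acceptor distance ≤ 3.2 Å *and* deviation from
  linearity ≤ 20°. Two angle conventions exist in the wild; the default
  measures the angle between the D→H and D→A vectors, and
  `angle_convention = "dha"` measures 180° minus the D-H⋯A angle instead.
  Donor/acceptor chemistry is an explicit table (backbone amide/carbonyl
  plus standard side-chain donors and acceptors) rather than an opaque tool
  default, so the computation is reproducible; a heavy-atom-only fallback
  (distance criterion alone) exists for hydrogen-free structures and is
  labelled by `NA` angles.
* **Salt bridge**: minimum distance between acidic side-chain oxygens
  (ASP OD1/OD2, GLU OE1/OE2, C-terminal OXT) and basic side-chain nitrogens
  (LYS NZ, ARG NE/NH1/NH2; histidine ring nitrogens only when flagged
  protonated) ≤ 4.0 Å, keyed at residue-pair level with the closest atom
  pair reported.
* **Interfacial residue**: any atom within 15 Å of any atom of the opposite
  side. This is applied once (first frame) purely as a performance
  prefilter; it cannot change results because both contact cutoffs are far
  below 15 Å.

Occupancy is the percentage of analysed frames in which a pair satisfies its
criterion. Pairs under 10% are dropped (inclusive: exactly 10% is kept,
matching the convention that only sub-10% contacts are "rarely formed");
tiers label pairs above 40% and above 80%. Per-residue aggregation reports
the union occupancy (frames with ≥ 1 retained contact involving the residue)
and a multi-partner flag for residues in ≥ 2 retained pairs — the starring
convention used when mapping salt-bridge hubs onto an interface. Trimming a
trajectory to its stable tail (e.g. the last half of a run) is the loader's
job: `read_ensemble(..., frame_range = "last 50%")`; the occupancy engine
analyses exactly the frames it is given, which keeps counts like 947/1000 →
94.7% exact.

Both detectors are verified **set-identical** to an independent brute-force
all-pairs oracle on 50 randomized two-chain fixtures in the acceptance
suite.

## What the synthetic generators emulate — and what they do not

`make_born_ion()` and `make_dumbbell()` are analytic fixtures.
`make_charged_interface_pair()` builds two rigid pseudo-chains with GLU
carboxylate and LYS ammonium groups at controlled cross-chain distances
using standard atom naming, so the real detectors run unmodified.
`make_contact_trajectory()` plants independent per-frame Bernoulli contacts
(probability p per pair) by translating the mobile group between an
"in" position (the base geometry, inside the cutoff) and an "out" position
(2× the cutoff); `exact = TRUE` instead realises exactly round(p·n) contact
frames, for fixtures that must reproduce a printed percentage to the digit.
One seeded Mersenne-Twister stream drives all randomness, so fixtures are
bit-reproducible.

These trajectories test *criteria and counting*, not physics: there is no
correlation between frames, no partial or bifurcated geometry, no solvent,
no conformational strain. Passing the recovery tests therefore demonstrates
that the counting machinery is unbiased and the filters behave as specified
— it says nothing about force-field quality or sampling adequacy in a real
simulation, which are upstream of this package. Occupancy recovery is
checked against 99% binomial intervals at n = 1000 for p ∈ {0.2, 0.5, 0.85},
and a planted p = 0.085 pair falls to the 10% filter whenever its realised
count does (both asserted).

## Numerical and design choices

* **Units.** Å, elementary charges, kT/e, kT/Å throughout; no conversion at
  I/O boundaries. Temperature fixed at 300 K by default (matching the usual
  simulation temperature); all unit constants derive from CODATA values at
  run time.
* **Charge template.** The packaged residue table
  (`charge_template()`) carries integer formal charges concentrated on the
  charged/polar groups with element-based radii (H 1.0, C 1.7, N 1.55,
  O 1.52, S 1.8 Å). It reproduces charge-level physics (ASP/GLU −1,
  LYS/ARG +1, HIS neutral by default and switchable to +1) without shipping
  a force field; PQR input is the canonical charged format and bypasses the
  template entirely. N-/C-terminal patches (H1/H2/H3, OXT) keep terminal
  residues at integer net charge.
* **Histidine.** Neutral single-tautomer by default; `"protonated"`
  switches the template, and `include_his = TRUE` admits HIS ring nitrogens
  as salt-bridge bases. Protonation-state *prediction* is out of scope.
* **Degenerate inputs.** Coincident centroids make the separation axis
  undefined (error); atoms outside the grid, missing radii/charges, unknown
  residues, atom-count mismatches between frames and topology, and
  non-convergent solves all raise typed, informative errors rather than
  propagating nonsense.
* **Tie-breaks.** Occupancy reports sort by occupancy descending, then
  lexicographically by chain/resid/atom, so outputs are byte-deterministic;
  mode rankings use a stable sort (attractive first, then force magnitude,
  then retained H-bond and salt-bridge counts).
* **Problem sizes.** The shipped tests solve on 33³-65³ grids (the Born
  benchmark at 65³/0.5 Å as specified by its oracle); production maps
  default to at most 97³. These sizes were chosen so the full validation
  suite runs in a few minutes on one core.

## Known limitations

The dielectric envelope is a union of (optionally probe-inflated) spheres,
not the reentrant molecular surface, so potentials immediately at the
dielectric boundary are approximate even though exterior fields are
accurate. The force model omits dielectric-boundary and ionic-pressure
terms. The mean-field ion treatment ignores correlations that matter for
multivalent ions at close range. Contact chemistry covers the 20 standard
amino acids; HETATM groups (nucleotides, ions, ligands) are flagged by the
template rather than parameterised. Binding free energies, PMFs, torques
and electric-field-line rendering are out of scope.
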