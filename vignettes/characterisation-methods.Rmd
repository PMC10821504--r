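---
title: "Ground-state characterisation methods in MolDFT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ground-state characterisation methods in MolDFT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

MolDFT characterises small organic molecules from their structure alone:
it carries its own Gaussian-basis Kohn–Sham engine and, on top of it,
conceptual-DFT reactivity indices, ELF basin topology, non-covalent
interaction (NCI) analysis, electrostatic potential maps, RRHO reaction
thermochemistry and a drug-likeness rule engine.  This vignette explains
the models, the tunable parameters and the numerical choices, in the
order a calculation flows through the package.

## The electronic-structure engine

All quantum-mechanical quantities come from a self-contained restricted
(closed-shell) or unrestricted Kohn–Sham implementation over contracted
Cartesian Gaussian basis functions.

* **Functional.** `"b3lyp"` is the three-parameter hybrid in the
  *Gaussian-program convention*: 20% exact exchange, 80% Slater +
  72% Becke-88 gradient-corrected exchange, and 19% VWN functional III
  (the RPA parametrisation) + 81% LYP correlation.  The local
  correlation variant matters: frontier orbital energies at the
  0.01 eV level depend on whether VWN III or VWN V enters the hybrid,
  and the reference data this package reproduces were computed with the
  VWN III convention.  `"hf"` (Hartree–Fock) is available for cheap
  survey work.
* **Basis sets.** 6-31G(d) (the production level, with the standard
  d exponent 0.8 on C/N/O and Cartesian 6d components) and STO-3G
  (survey level).  The parameter tables ship as plain text under
  `inst/extdata/basis/`; elements H, C, N, O are supported, which
  covers the chemistry the package targets.
* **Integrals.** One- and two-electron integrals use McMurchie–Davidson
  Hermite expansions with Schwarz screening at both the shell-pair and
  primitive-pair level (thresholds 1e-10 and a derived primitive bound).
  The implementation is validated in the test suite against an
  independent recursive reference implementation and against classic
  minimal-basis H2 values.
* **SCF.** DIIS-accelerated, with a spherically averaged
  superposition-of-atomic-densities starting guess.  Convergence
  demands both an energy change below 1e-8 Hartree and a maximum
  orbital-gradient (commutator) element below 1e-5.  An SCF that fails
  these criteria raises an error; unconverged states are never
  propagated.
* **Quadrature.** Becke-partitioned atomic grids (Mura–Knowles radial
  mapping, pruned Gauss–Legendre × uniform azimuthal angular product
  grids).  Presets: `coarse` (35 radial shells), `default` (50),
  `fine` (75).  Total-energy differences between `default` and `fine`
  are of order 1e-6 Hartree for the molecules treated here, and
  frontier orbital energies move by less than 0.001 eV between
  `coarse` and `default`, so the desk-scale reproduction runs use
  `coarse` throughout and `default` remains the single-point default
  for user calculations.
* **Gradients.** Analytic nuclear gradients (Hellmann–Feynman + Pulay +
  two-electron derivative contraction + exchange–correlation term).
  Quadrature-weight derivatives are neglected, a fixed-grid
  approximation that leaves a residual of order 1e-5 Hartree/Bohr,
  comfortably below the optimiser thresholds.  The test suite checks
  analytic gradients against finite differences for both HF and B3LYP.

## Geometry optimisation and fixtures

Optimisation uses rational-function (RFO) steps in Cartesian
coordinates with a Lindh-type model starting Hessian assembled from
redundant internal coordinates, BFGS updates and a trust radius.
Convergence presets: `default` (max force 4.5e-4, RMS 3e-4
Hartree/Bohr — the common production criterion) and `fast`
(2e-3/1.3e-3) for survey scans.

The built-in fixture molecules are generated from internal Z-matrices
with idealised bond parameters chosen at typical B3LYP/6-31G(d)
equilibrium values, so that the optimiser refines rather than rebuilds
the structure; the refinement is always run, and the final geometry is
whatever the gradient says it is.  The ester diastereomers are
constructed by the sign pattern of the two acetoxy dihedrals over an
anti backbone: equal signs give the meso form (internal inversion),
opposite signs the C2-symmetric (R,R) form.

## Thermochemistry

Harmonic frequencies come from central finite differences of analytic
gradients (0.005 Bohr displacements), mass-weighted with projection of
overall translation/rotation, unscaled.  Ideal-gas RRHO thermodynamics
are evaluated at 298.15 K and 1 atm with a rotational symmetry number
of 1 for every species; for the isomer-ranking question this cancels
almost entirely, and the package exposes `sigma` for users who need
point-group-resolved entropies.  `ThermoRecord` objects enforce the
G = H − TS identity at construction.

The decomposition table (ester → diene + 2 acetic acid) optimises all
six species, runs frequencies, and reports ΔH, ΔG and ΔS per
(ester, diene) combination.  Because the ester and acid terms are
common within a row block, the identity of the thermodynamically
preferred diene reduces to the ordering of the diene free energies —
a Hess-cycle cancellation the tests exploit as an internal consistency
check.

The table has two scale switches.  `optimize = FALSE` evaluates the
species at the package's reference geometries, and
`vibrational = FALSE` produces rigid-body records (translation,
rotation and pV only, no ZPE or vibrational entropy).  The in-suite
ranking test uses both at HF/STO-3G: numerical Hessians cost 3N+1
gradient evaluations per species, which for the 30-atom esters is
hours of single-CPU work at any level this engine offers, while the
isomer ranking itself is decided by electronic-energy gaps of 7
kcal/mol and more — an order of magnitude beyond both the vibrational
isomer differences (a few tenths of kcal/mol) and any geometry
refinement effect.  The full-RRHO, fully optimised table runs through
exactly the same `decompositionTable` code path when time permits.

## Scalar fields, ELF topology and NCI

Fields are evaluated on axis-aligned grids (default 0.1 Bohr spacing,
4 Bohr padding) directly from the converged density matrix.

* **ELF** uses the Becke–Edgecombe kernel
  ELF = 1/(1 + (D/Dh)²), D = τ − |∇ρ|²/(8ρ),
  Dh = (3/10)(3π²)^{2/3} ρ^{5/3}, with a 1e-12 density floor and D
  clamped at zero.  In the uniform-gas limit the kernel gives exactly
  1/2 (a unit test, via the analytic field generators).
* **Basins** are found by 26-neighbour steepest-ascent watershed on the
  ELF grid.  Two merge criteria heal grid artefacts: attractors closer
  than 0.5 Bohr with ELF values within 0.02 are combined, and adjacent
  basins whose dividing valley is shallower than 0.002 ELF units are
  combined (this removes plateau fragmentation around hydrogens and the
  grid-sensitive V/V′ sub-basin splittings, whose populations are only
  ever reported as sums).  Basins carrying less than 5e-3 e are
  discarded as vacuum-tail artefacts.  Voxels below ρ = 1e-8 stay
  unassigned (≪0.001 e in total).
* **Populations** integrate the density with Yu–Trinkle fractional
  boundary weights rather than whole-voxel assignment.  This matters
  quantitatively: on the 0.1 Bohr grid the butadiene C1–C2 disynaptic
  population is 3.43 e with flux weights but 3.30 e with whole-voxel
  assignment, a first-order-in-spacing boundary bias concentrated at
  the steep core–valence interface.  Symmetry-equivalent basins agree
  to better than 0.001 e with the flux weights.
* **Synapticity** is classified from basin adjacency to core basins
  (attractor within 0.7 Bohr of a nucleus with Z > 2) plus any hydrogen
  nuclei contained in the basin; labels follow the V(A), V(A,B)
  convention.  At the STO-3G level the valence ELF of water is too flat
  to separate lone pairs from O–H basins (the saddle depths fall below
  the merge threshold); the split-valence basis restores the textbook
  2 lone pairs + 2 protonated basins, and the package's ELF analyses
  are intended for split-valence densities.
* **NCI** computes the reduced density gradient
  s = |∇ρ|/(2(3π²)^{1/3}ρ^{4/3}) and sign(λ₂)ρ from the analytic
  density Hessian.  The scatter is restricted to |sign(λ₂)ρ| ≤ 0.05
  a.u.; "interaction points" are low-gradient points (s < 0.5, a
  conventional choice — the literature does not fix one) outside
  covalent regions (ρ < 0.1 a.u.).  The SCF density is used, not the
  promolecular approximation.
* **MEP** is evaluated with analytic one-electron Coulomb integrals per
  grid point; because this is the most expensive field per point, the
  default MEP grid is coarser (0.4 Bohr) and points within 0.3 Bohr of
  a nucleus are masked.

## Conceptual-DFT indices

From the converged frontier orbital energies (eV): μ = (εH + εL)/2,
η = εL − εH, S = 1/η, X = −μ, ω = μ²/2η, and the nucleophilicity
N = εH − εH(TCE) against tetracyanoethylene computed in-package at the
identical level (never hard-coded).  Two conventions deserve note:

* **LUMO sign.** The reference tabulation this package reproduces
  prints positive LUMO energies (0.61/3.91 eV) that contradict its own
  printed gaps (5.62/4.40 eV) and ω values; with negative LUMOs
  (−0.61/−3.91 eV) every other printed number is reproduced exactly.
  The package reports the signed orbital energies as computed — both
  LUMOs come out negative — and the regression tests pin the
  internally consistent sign convention.
* **Softness** is defined as 1/η (not 1/2η); nothing in the reproduced
  data constrains the choice, and it is stated in the documentation.

Parr functions are Mulliken atomic spin densities of the radical anion
(P⁺) and cation (P⁻), evaluated as unrestricted single points at the
frozen neutral geometry.  The package reports raw per-atom values by
default: these sum to one and reproduce the reference factors
(butadiene terminal P⁺ ≈ 0.46, P⁻ ≈ 0.47) directly, whereas folding
the small negative hydrogen populations into the carbons
(`condenseHydrogens = TRUE`) lowers the terminal values by ≈0.05.
Local indices are the exact products ω·P⁺ and N·P⁻.  ⟨S²⟩ of both ions
is carried in the result and a warning fires above 1.2.

Natural population analysis is out of scope (the natural-orbital
machinery is not implemented); Mulliken and Löwdin charges are provided
and labelled as such.

## Drug-likeness

Descriptors are computed through OpenBabel (via ChemmineOB): molecular
weight, Ertl TPSA, Wildman–Crippen logP and molar refractivity, SMARTS
counts for rotatable bonds, sp³ carbons and H-bond donors.  The
Lipinski acceptor/donor counts use the classic N+O and NH+OH
definitions.  Ring counts are cyclomatic.  Water solubility is an
ESOL-type (Delaney) estimate and, like the skin-permeation style
quantities it would feed, is estimator-dependent; the logP estimator
name is recorded in every descriptor set.  The five filters
(Lipinski ≤1 violation; Ghose; Veber; Egan; Muegge) use the thresholds
of the original publications with inclusive bounds.  Structural alerts
are a small documented fragment list (nitro group, no organic ring,
aldehyde, epoxide, azo, peroxide, thiol, acyl halide) plus a
five-pattern PAINS subset; the full 480-pattern PAINS catalogue is not
reproduced.  The bioavailability radar uses the six conventional axes
with inclusive bounds (unsaturation: fraction of sp³ carbons in
[0.25, 1]).

## What the fixtures do and do not show

The built-in structure generator produces chemically correct starting
geometries for every species in the study plus analytic scalar fields
(normalised Gaussians, uniform-gas densities) that exercise the grid
machinery against closed forms.  Passing tests therefore demonstrate
internal correctness (integrals, SCF, fields, thermochemistry,
topology) and faithful reproduction of the reference molecules'
properties.  They do not probe conformational ensembles (only a minimal
rotamer scan is provided), heavier elements than O, solvent effects
(everything is gas phase), or excited states.

## Problem sizes

The test and acceptance workloads run at deliberate desk scale on one
CPU: the three production optimisations (butadiene, TCE, nitrodiene;
72–158 basis functions) start from near-equilibrium fixtures and are
refined with the fast preset on the coarse quadrature (frontier
orbital energies at these geometries agree with tightly converged
default-grid ones to better than 0.01 eV); the ELF acceptance grid is 0.1 Bohr
(≈3M voxels); NCI grids are 0.2 Bohr; the decomposition table runs at
HF/STO-3G with the fast preset.  All thresholds above are the defaults
of the corresponding functions and are independent of these choices.

## Known limitations

* Elements beyond H/C/N/O require extending the basis-set tables.
* No solvent models, no post-SCF correlation, no TD-DFT.
* The grid watershed does not resolve the V/V′ sub-basin split
  reliably (populations are reported as bond sums, which is also how
  the reference data are compared).
* Numerical Hessians cost 6N gradient evaluations; frequencies for
  molecules much beyond ~30 atoms are slow at the production level.
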