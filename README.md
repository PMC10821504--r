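# MolDFT

Self-contained DFT characterisation of small organic molecules in R:
from a structure (built-in fixture, XYZ file or SMILES) to reactivity
indices, electron-localisation topology, non-covalent interaction
analysis, reaction thermochemistry and drug-likeness screening —
without any external quantum-chemistry program.

## Who this is for

Computational and organic chemists who want to reproduce or extend the
standard ground-state characterisation workflow for small conjugated
molecules — the kind of panel reported for nitro-substituted dienes
such as (1E,3E)-1,4-dinitro-1,3-butadiene and its parent
s-trans-1,3-butadiene — inside a single R package with a test suite.

## What is inside

**A compact Kohn–Sham engine.** Restricted/unrestricted B3LYP (in the
Gaussian-program correlation convention, i.e. VWN functional III in the
local part) and Hartree–Fock over 6-31G(d) / STO-3G Cartesian Gaussian
bases: McMurchie–Davidson integrals, DIIS SCF, Becke-grid quadrature,
analytic nuclear gradients, RFO/BFGS geometry optimisation and
numerical-Hessian harmonic frequencies.

**Conceptual DFT** (all in eV, from frontier orbital energies
ε_H, ε_L):

- chemical potential μ = (ε_H + ε_L)/2, hardness η = ε_L − ε_H,
  softness S = 1/η, electronegativity X = −μ
- global electrophilicity **ω = μ²/2η**
- global nucleophilicity **N = ε_H − ε_H(TCE)** with the
  tetracyanoethylene reference computed at the same level
- Parr functions P⁺/P⁻ from the Mulliken atomic spin densities of the
  radical anion/cation at the frozen neutral geometry, and local
  indices ω_k = ω·P⁺_k, N_k = N·P⁻_k

**ELF topology.** Becke–Edgecombe electron localisation function on a
grid, watershed basin partition with saddle-depth merging, Yu–Trinkle
fractional-weight population integration, core/valence and synapticity
classification (V(A), V(A,B) labels, bond-pair population sums).

**NCI.** Reduced density gradient s = |∇ρ|/(2(3π²)^{1/3}ρ^{4/3})
against sign(λ₂)ρ, scatter data and interaction-point detection.

**MEP**, Gaussian cube file I/O, **RRHO thermochemistry** (298.15 K,
1 atm, unscaled frequencies) with a decomposition table for the
dehydro-acetylation reaction ester → diene + 2 CH₃COOH over both ester
diastereomers and all three diene geometric isomers.

**Drug-likeness.** Descriptor panel (MW, TPSA, Wildman–Crippen
logP/MR via OpenBabel, rotatable bonds, HBA/HBD, fraction Csp³, rings),
the Lipinski/Ghose/Veber/Egan/Muegge filters as an auditable rule
engine with named violations, structural alerts, a PAINS subset and the
six-axis bioavailability radar.

## Worked example

```r
library(MolDFT)
mol <- builtinMolecule("butadiene_s_trans")
print(mol)
scf <- singlePoint(mol, LevelOfTheory("b3lyp", "6-31g(d)"))
print(scf)
g <- globalIndicesFromEnergies(homoEnergy(scf), lumoEnergy(scf),
                               homoReference = -9.12)
print(g)
rep <- druglikeReport("C(=C/[N+](=O)[O-])\\C=C\\[N+](=O)[O-]")
```

prints (the reactivity block is at the fixture starting geometry; the
reference value −9.12 eV is the TCE HOMO that `tceReference()`
computes):

```
Molecule 'butadiene_s_trans': 10 atoms, charge +0, multiplicity 1, 30 electrons
  formula: C4H6
SCFResult: b3lyp/6-31g(d)  E = -155.99216521 Hartree  (converged, 11 iterations)
  HOMO -6.2303 eV   LUMO -0.6119 eV
Global reactivity indices (eV):
  HOMO   -6.23   LUMO   -0.61   gap   5.62
  mu     -3.42   eta     5.62   X     3.42
  omega   1.04   N       2.89   S    0.178 eV^-1
MW 144.09  TPSA 91.64  rotatable bonds 3  fraction Csp3 0.00
filters passed: lipinski, veber, egan
alerts: nitro_group, no_organic_ring
```

Reading the output: butadiene is a moderate electrophile (ω ≈ 1 eV)
and moderate nucleophile (N ≈ 2.9 eV); the nitrodiene descriptor panel
shows a small (MW 144), fully unsaturated molecule that clears the
Lipinski/Veber/Egan filters but trips the nitro-group and no-ring
structural alerts.  The fixture geometry is a near-equilibrium
starting structure; `optimizeGeometry` refines it (and the frontier
energies in the third decimal) before production analyses.

A full characterisation in one call:

```r
rep <- runPipeline("dinitrobutadiene_EE", pipelineConfig())
writeReport(rep, "nitrodiene.json")
```

A thin command-line wrapper lives at `inst/scripts/moldft`
(`moldft list-fixtures`, `moldft report --target ... --stages ...`,
`moldft druglike --smiles ...`, `moldft fields --quantity elf`).

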