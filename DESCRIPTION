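Package: MolDFT
Title: Self-Contained DFT Characterization of Small Molecules: Reactivity
    Indices, ELF Topology, Non-Covalent Interactions and Drug-Likeness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained computational chemistry toolkit for ground
    state characterization of small organic molecules. Implements a compact
    Gaussian-basis Kohn-Sham engine (restricted and unrestricted B3LYP with
    the Gaussian-program correlation convention, 6-31G(d) and STO-3G basis
    sets, analytic nuclear gradients, numerical Hessians) and, on top of it,
    conceptual-DFT global and local reactivity indices with Parr functions
    from atomic spin densities, topological analysis of the electron
    localization function (ELF) with grid watershed basin integration,
    non-covalent interaction (NCI) reduced-density-gradient analysis,
    molecular electrostatic potential maps, rigid-rotor harmonic-oscillator
    reaction thermochemistry, and an auditable drug-likeness rule engine
    (Lipinski, Ghose, Veber, Egan, Muegge filters, structural alerts and a
    bioavailability radar).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    ChemmineOB
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
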