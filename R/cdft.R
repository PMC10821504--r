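# Conceptual-DFT reactivity indices: global indices from frontier
# orbital energies, Parr functions from atomic spin densities of the
# radical ions, local indices, and Mulliken/Loewdin charges.

#' Global reactivity indices from frontier orbital energies
#'
#' Frontier-orbital (Koopmans-like) conceptual-DFT ledger in eV:
#' chemical potential mu = (eHOMO + eLUMO)/2, hardness eta =
#' eLUMO - eHOMO, softness 1/eta, electronegativity -mu, global
#' electrophilicity omega = mu^2/(2 eta), and global nucleophilicity
#' N = eHOMO - eHOMO(reference), the reference being tetracyanoethylene
#' at the same level of theory.
#'
#' @param scf converged closed-shell \linkS4class{SCFResult}
#' @param homoReference reference HOMO energy, eV (see
#'   \code{\link{tceReference}})
#' @return a \linkS4class{GlobalIndices}
#' @export
globalIndices <- function(scf, homoReference) {
  if (!scf@converged) stop("SCF result is not converged")
  globalIndicesFromEnergies(homoEnergy(scf), lumoEnergy(scf), homoReference)
}

#' @rdname globalIndices
#' @param eHomo,eLumo frontier orbital energies, eV
#' @export
globalIndicesFromEnergies <- function(eHomo, eLumo, homoReference = NA_real_) {
  eta <- eLumo - eHomo
  if (eta <= 0) stop("nonpositive hardness (eLumo <= eHomo)")
  mu <- (eHomo + eLumo) / 2
  new("GlobalIndices", eHomo = eHomo, eLumo = eLumo, gap = eta,
      mu = mu, eta = eta, softness = 1 / eta, electronegativity = -mu,
      omega = mu^2 / (2 * eta),
      nucleophilicity = eHomo - homoReference,
      homoReference = homoReference)
}

#' Tetracyanoethylene HOMO reference for the nucleophilicity scale
#'
#' Optimises TCE at the given level and returns its HOMO in eV.  The
#' result is cached per level of theory for the session.
#'
#' @param level a \linkS4class{LevelOfTheory}
#' @param preset,gridPreset forwarded to the optimiser
#' @return HOMO energy, eV
#' @export
tceReference <- function(level = LevelOfTheory(), preset = "default",
                         gridPreset = "default") {
  key <- paste("tceref", level@functional, level@basis, preset, gridPreset)
  if (!is.null(.pkgenv[[key]])) return(.pkgenv[[key]])
  opt <- optimizeGeometry(builtinMolecule("tce"), level, preset = preset,
                          gridPreset = gridPreset)
  ref <- homoEnergy(opt$scf)
  .pkgenv[[key]] <- ref
  ref
}

# Mulliken population/charge/spin analysis
.mulliken <- function(D, S, shells, nAtom) {
  ds <- rowSums(D * S)   # diag(D %*% S)
  at <- bfAtoms(shells)
  vapply(seq_len(nAtom), function(a) sum(ds[at == a]), 0)
}

.lowdin <- function(D, S, shells, nAtom) {
  es <- eigen(S, symmetric = TRUE)
  Sh <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  ds <- diag(Sh %*% D %*% Sh)
  at <- bfAtoms(shells)
  vapply(seq_len(nAtom), function(a) sum(ds[at == a]), 0)
}

#' Atomic partial charges
#'
#' @param scf converged \linkS4class{SCFResult}
#' @param method "mulliken" or "lowdin"
#' @return an \linkS4class{AtomicCharges}
#' @export
atomicCharges <- function(scf, method = c("mulliken", "lowdin")) {
  method <- match.arg(method)
  mol <- scf@molecule
  D <- densityMatrix(scf, "total")
  pops <- switch(method,
    mulliken = .mulliken(D, scf@overlap, scf@shells, nAtoms(mol)),
    lowdin = .lowdin(D, scf@overlap, scf@shells, nAtoms(mol)))
  new("AtomicCharges", method = method,
      charges = elementZ(mol@symbols) - pops)
}

# nearest heavy atom of each hydrogen (for condensing H populations)
.heavyPartner <- function(mol) {
  Z <- elementZ(mol@symbols)
  xyz <- mol@coords
  partner <- seq_len(nAtoms(mol))
  for (a in which(Z == 1)) {
    heavy <- which(Z > 1)
    d <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[a, ])^2))
    partner[a] <- heavy[which.min(d)]
  }
  partner
}

#' Parr functions from atomic spin densities of the radical ions
#'
#' Electrophilic Parr functions P+ come from the Mulliken atomic spin
#' density of the radical anion, nucleophilic P- from the radical
#' cation, both as unrestricted single points at the frozen neutral
#' geometry.  By default the per-atom spin populations are reported
#' for every atom (hydrogens typically carry small negative values);
#' with \code{condenseHydrogens = TRUE} hydrogen populations are
#' folded into their bonded heavy atom.  Either way the values sum to
#' 1 (one unit of net spin).
#'
#' @param mol the neutral molecule at its optimised geometry
#' @param level a \linkS4class{LevelOfTheory}
#' @param gridPreset XC quadrature preset
#' @param condenseHydrogens fold H populations into heavy atoms
#' @param s2Warn warn when the radical-ion <S^2> exceeds this value
#' @return a \linkS4class{ParrFunctions}
#' @export
parrFunctions <- function(mol, level = LevelOfTheory(),
                          gridPreset = "default",
                          condenseHydrogens = FALSE, s2Warn = 1.2) {
  ionSpin <- function(dq) {
    ion <- Molecule(mol@symbols, mol@coords, mol@charge + dq, 2L,
                    label = paste0(mol@label, ifelse(dq < 0, "_anion",
                                                     "_cation")))
    scf <- singlePoint(ion, level, gridPreset = gridPreset)
    Ds <- densityMatrix(scf, "spin")
    asd <- .mulliken(Ds, scf@overlap, scf@shells, nAtoms(mol))
    list(asd = asd, s2 = scf@s2)
  }
  an <- ionSpin(-1L)
  ca <- ionSpin(+1L)
  if (an$s2 > s2Warn)
    warning(sprintf("radical anion <S^2> = %.3f: spin contamination", an$s2))
  if (ca$s2 > s2Warn)
    warning(sprintf("radical cation <S^2> = %.3f: spin contamination", ca$s2))
  Z <- elementZ(mol@symbols)
  if (condenseHydrogens) {
    partner <- .heavyPartner(mol)
    keep <- which(Z > 1)
    condense <- function(asd) {
      out <- vapply(keep, function(a) sum(asd[partner == a]), 0)
      names(out) <- paste0(mol@symbols[keep], keep)
      out
    }
  } else {
    keep <- seq_len(nAtoms(mol))
    condense <- function(asd) {
      names(asd) <- paste0(mol@symbols, keep)
      asd
    }
  }
  new("ParrFunctions", pPlus = condense(an$asd), pMinus = condense(ca$asd),
      atoms = as.integer(keep), source = "mulliken",
      s2Anion = an$s2, s2Cation = ca$s2)
}

#' Local electrophilicity and nucleophilicity indices
#'
#' omega_k = omega * P+_k and N_k = N * P-_k, elementwise over the
#' heavy atoms.
#'
#' @param g a \linkS4class{GlobalIndices}
#' @param p a \linkS4class{ParrFunctions}
#' @return a \linkS4class{LocalIndices}
#' @export
localIndices <- function(g, p) {
  if (length(p@pPlus) != length(p@pMinus))
    stop("Parr function length mismatch")
  new("LocalIndices", omegaK = g@omega * p@pPlus,
      nK = g@nucleophilicity * p@pMinus, atoms = p@atoms)
}
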