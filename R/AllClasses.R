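#' @import methods
NULL

# ---------------------------------------------------------------------
# Molecule
# ---------------------------------------------------------------------

#' Molecular structure
#'
#' The universal input record of the package: element symbols, Cartesian
#' coordinates in Angstrom, total charge and spin multiplicity (2S+1).
#'
#' @slot label short human-readable name
#' @slot symbols character vector of element symbols
#' @slot coords numeric N x 3 matrix, Angstrom
#' @slot charge integer total charge, elementary charges
#' @slot multiplicity integer spin multiplicity (2S+1)
#'
#' @examples
#' m <- builtinMolecule("butadiene_s_trans")
#' nAtoms(m)
#' countElectrons(m)
#' @export
setClass("Molecule",
  representation(label = "character", symbols = "character",
                 coords = "matrix", charge = "integer",
                 multiplicity = "integer"))

setValidity("Molecule", function(object) {
  msg <- character()
  if (nrow(object@coords) != length(object@symbols))
    msg <- c(msg, "coords rows must match number of symbols")
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must be N x 3")
  if (object@multiplicity < 1L) msg <- c(msg, "multiplicity must be >= 1")
  z <- tryCatch(elementZ(object@symbols), error = function(e) NULL)
  if (is.null(z)) {
    msg <- c(msg, paste("unknown element symbol among:",
                        paste(unique(object@symbols), collapse = " ")))
  } else {
    nel <- sum(z) - object@charge
    if (nel < 0) msg <- c(msg, "negative electron count")
    # parity: n_unpaired = multiplicity - 1 must share parity with nel
    if ((nel %% 2L) != ((object@multiplicity - 1L) %% 2L))
      msg <- c(msg, sprintf(
        "electron count %d inconsistent with multiplicity %d",
        nel, object@multiplicity))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Molecule
#'
#' @param symbols element symbols
#' @param coords N x 3 matrix of coordinates in Angstrom
#' @param charge total charge
#' @param multiplicity spin multiplicity 2S+1
#' @param label optional name
#' @return a \linkS4class{Molecule}
#' @export
Molecule <- function(symbols, coords, charge = 0L, multiplicity = 1L,
                     label = "molecule") {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  new("Molecule", label = label, symbols = as.character(symbols),
      coords = coords, charge = as.integer(charge),
      multiplicity = as.integer(multiplicity))
}

# ---------------------------------------------------------------------
# Level of theory
# ---------------------------------------------------------------------

#' Electronic-structure model specification
#'
#' @slot functional "b3lyp" (Gaussian-program correlation convention,
#'   i.e. VWN functional III in the local correlation part) or "hf"
#' @slot basis "6-31g(d)" or "sto-3g" (Cartesian d functions)
#' @export
setClass("LevelOfTheory",
  representation(functional = "character", basis = "character"))

#' @param functional exchange-correlation model
#' @param basis basis-set name
#' @rdname LevelOfTheory-class
#' @export
LevelOfTheory <- function(functional = "b3lyp", basis = "6-31g(d)") {
  functional <- tolower(functional)
  basis <- tolower(basis)
  if (!functional %in% c("b3lyp", "hf"))
    stop("unsupported functional: ", functional)
  if (!basis %in% c("6-31g(d)", "sto-3g"))
    stop("unsupported basis: ", basis)
  new("LevelOfTheory", functional = functional, basis = basis)
}

# ---------------------------------------------------------------------
# SCF result
# ---------------------------------------------------------------------

#' Converged self-consistent-field snapshot
#'
#' Holds the converged Kohn-Sham (or Hartree-Fock) state: total energy,
#' per-spin orbital energies, coefficients and occupations, plus the
#' basis-set description needed to evaluate density-derived quantities
#' at arbitrary points in space.
#'
#' @slot molecule the \linkS4class{Molecule} (geometry in Angstrom)
#' @slot level the \linkS4class{LevelOfTheory}
#' @slot energy total electronic energy, Hartree
#' @slot converged logical
#' @slot niter SCF iterations used
#' @slot restricted logical; TRUE for closed-shell runs
#' @slot coefA,coefB MO coefficient matrices per spin
#' @slot epsA,epsB orbital energies per spin, Hartree, nondecreasing
#' @slot occA,occB occupation vectors per spin (0/1)
#' @slot nAlpha,nBeta electron counts per spin
#' @slot shells basis shell list (internal layout)
#' @slot overlap AO overlap matrix
#' @slot s2 expectation value of S^2 (open shell; NA for restricted)
#' @export
setClass("SCFResult",
  representation(molecule = "Molecule", level = "LevelOfTheory",
                 energy = "numeric", converged = "logical",
                 niter = "integer", restricted = "logical",
                 coefA = "matrix", coefB = "matrix",
                 epsA = "numeric", epsB = "numeric",
                 occA = "numeric", occB = "numeric",
                 nAlpha = "integer", nBeta = "integer",
                 shells = "list", overlap = "matrix", s2 = "numeric"))

setValidity("SCFResult", function(object) {
  msg <- character()
  if (abs(sum(object@occA) - object@nAlpha) > 1e-8)
    msg <- c(msg, "alpha occupations do not sum to nAlpha")
  if (abs(sum(object@occB) - object@nBeta) > 1e-8)
    msg <- c(msg, "beta occupations do not sum to nBeta")
  if (is.unsorted(object@epsA, strictly = FALSE) ||
      is.unsorted(object@epsB, strictly = FALSE))
    msg <- c(msg, "orbital energies must be nondecreasing")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------
# Thermochemistry
# ---------------------------------------------------------------------

#' Rigid-rotor harmonic-oscillator thermochemical record
#'
#' @slot eElec electronic energy, Hartree
#' @slot zpe zero-point vibrational energy, Hartree
#' @slot hCorr thermal enthalpy correction (incl. ZPE), Hartree
#' @slot gCorr thermal Gibbs correction, Hartree
#' @slot s298 total entropy, Hartree/K
#' @slot nImaginary number of imaginary frequencies
#' @slot frequencies harmonic frequencies, cm^-1
#' @slot temperature K
#' @export
setClass("ThermoRecord",
  representation(eElec = "numeric", zpe = "numeric", hCorr = "numeric",
                 gCorr = "numeric", s298 = "numeric",
                 nImaginary = "integer", frequencies = "numeric",
                 temperature = "numeric"))

setValidity("ThermoRecord", function(object) {
  dev <- abs(object@gCorr - (object@hCorr - object@temperature * object@s298))
  if (dev > 1e-8) return(sprintf("G/H/S identity violated by %.2e Hartree", dev))
  TRUE
})

# ---------------------------------------------------------------------
# Scalar fields
# ---------------------------------------------------------------------

#' Regular 3D grid specification (Bohr)
#'
#' @slot origin 3-vector, Bohr
#' @slot axes 3 x 3 matrix of step vectors (rows), Bohr
#' @slot shape integer 3-vector of point counts
#' @export
setClass("GridSpec",
  representation(origin = "numeric", axes = "matrix", shape = "integer"))

setValidity("GridSpec", function(object) {
  if (any(object@shape < 2L)) return("shape must be >= 2 in each direction")
  if (abs(det(object@axes)) < 1e-14) return("axes are singular")
  TRUE
})

#' Scalar field on a regular grid
#'
#' @slot grid a \linkS4class{GridSpec}
#' @slot quantity one of rho, elf, rdg, signed_rho, mep, other
#' @slot values numeric array with dim == grid shape
#' @export
setClass("ScalarField",
  representation(grid = "GridSpec", quantity = "character",
                 values = "array"))

setValidity("ScalarField", function(object) {
  if (!all(dim(object@values) == object@grid@shape))
    return("values dimension does not match grid shape")
  TRUE
})

#' NCI scatter data: sign(lambda2)*rho vs reduced density gradient
#'
#' @slot signedRho a.u., restricted to |x| <= window
#' @slot s dimensionless reduced density gradient
#' @slot window a.u. cutoff applied to signedRho
#' @export
setClass("NciScatter",
  representation(signedRho = "numeric", s = "numeric", window = "numeric"))

# ---------------------------------------------------------------------
# ELF basins
# ---------------------------------------------------------------------

#' Set of ELF basins with integrated electron populations
#'
#' @slot basins data.frame: one row per basin with attractor position
#'   (Bohr), attractor ELF value, kind (core/valence), synaptic label,
#'   atom indices, electron population
#' @slot totalPopulation electrons over all basins
#' @slot gridProvenance the \linkS4class{GridSpec} used
#' @export
setClass("BasinSet",
  representation(basins = "data.frame", totalPopulation = "numeric",
                 gridProvenance = "GridSpec"))

# ---------------------------------------------------------------------
# Conceptual-DFT records
# ---------------------------------------------------------------------

#' Global conceptual-DFT reactivity indices (eV)
#'
#' @slot eHomo,eLumo frontier orbital energies, eV
#' @slot gap eLumo - eHomo, eV
#' @slot mu electronic chemical potential (eHomo+eLumo)/2, eV
#' @slot eta chemical hardness eLumo - eHomo, eV
#' @slot softness 1/eta, 1/eV
#' @slot electronegativity -mu, eV
#' @slot omega global electrophilicity mu^2/(2 eta), eV
#' @slot nucleophilicity N = eHomo - eHomo(reference), eV
#' @slot homoReference reference HOMO (tetracyanoethylene), eV
#' @export
setClass("GlobalIndices",
  representation(eHomo = "numeric", eLumo = "numeric", gap = "numeric",
                 mu = "numeric", eta = "numeric", softness = "numeric",
                 electronegativity = "numeric", omega = "numeric",
                 nucleophilicity = "numeric", homoReference = "numeric"))

#' Parr functions from atomic spin densities of the radical ions
#'
#' @slot pPlus electrophilic Parr values per heavy atom (H condensed)
#' @slot pMinus nucleophilic Parr values per heavy atom
#' @slot atoms heavy-atom indices into the molecule
#' @slot source charge-partitioning scheme used
#' @slot s2Anion,s2Cation S^2 expectation values of the radical ions
#' @export
setClass("ParrFunctions",
  representation(pPlus = "numeric", pMinus = "numeric", atoms = "integer",
                 source = "character", s2Anion = "numeric",
                 s2Cation = "numeric"))

#' Local (per-atom) electrophilicity and nucleophilicity indices, eV
#' @slot omegaK,nK per heavy atom, eV
#' @slot atoms heavy-atom indices
#' @export
setClass("LocalIndices",
  representation(omegaK = "numeric", nK = "numeric", atoms = "integer"))

#' Per-atom partial charges
#' @slot method mulliken or lowdin
#' @slot charges elementary charges, one per atom
#' @export
setClass("AtomicCharges",
  representation(method = "character", charges = "numeric"))

# ---------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------

setMethod("show", "Molecule", function(object) {
  z <- elementZ(object@symbols)
  cat(sprintf("Molecule '%s': %d atoms, charge %+d, multiplicity %d, %d electrons\n",
              object@label, length(object@symbols), object@charge,
              object@multiplicity, sum(z) - object@charge))
  f <- table(object@symbols)
  cat("  formula:", paste0(names(f), ifelse(f > 1, f, ""), collapse = ""), "\n")
})

setMethod("show", "SCFResult", function(object) {
  cat(sprintf("SCFResult: %s/%s  E = %.8f Hartree  (%s, %d iterations)\n",
              object@level@functional, object@level@basis, object@energy,
              if (object@converged) "converged" else "NOT converged",
              object@niter))
  cat(sprintf("  HOMO %.4f eV   LUMO %.4f eV\n",
              homoEnergy(object), lumoEnergy(object)))
})

setMethod("show", "GlobalIndices", function(object) {
  cat("Global reactivity indices (eV):\n")
  cat(sprintf("  HOMO %7.2f   LUMO %7.2f   gap %6.2f\n",
              object@eHomo, object@eLumo, object@gap))
  cat(sprintf("  mu   %7.2f   eta  %7.2f   X   %6.2f\n",
              object@mu, object@eta, object@electronegativity))
  cat(sprintf("  omega %6.2f   N    %7.2f   S   %6.3f eV^-1\n",
              object@omega, object@nucleophilicity, object@softness))
})

setMethod("show", "BasinSet", function(object) {
  cat(sprintf("BasinSet: %d basins, total population %.4f e\n",
              nrow(object@basins), object@totalPopulation))
  b <- object@basins
  b$population <- round(b$population, 3)
  print(utils::head(b[order(-b$population),
                      c("label", "kind", "population", "elf")], 12))
})

setMethod("show", "ThermoRecord", function(object) {
  cat(sprintf("ThermoRecord at %.2f K: E %.6f  ZPE %.6f  Hcorr %.6f  Gcorr %.6f Hartree\n",
              object@temperature, object@eElec, object@zpe, object@hCorr,
              object@gCorr))
  if (object@nImaginary > 0)
    cat(sprintf("  WARNING: %d imaginary frequencies\n", object@nImaginary))
})
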