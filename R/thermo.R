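# Harmonic frequencies (numerical differentiation of analytic
# gradients), rigid-rotor harmonic-oscillator thermochemistry, reaction
# energetics for the dehydro-acetylation decomposition, and a dihedral
# rotamer scan.

#' Numerical Cartesian Hessian from analytic gradients
#'
#' Central differences with a 0.005 Bohr step; the converged density of
#' the reference point seeds every displaced SCF.
#'
#' @param mol molecule at a stationary geometry
#' @param level level of theory
#' @param step displacement, Bohr
#' @param gridPreset XC quadrature preset
#' @param scheme "central" differences (default) or "forward" (3N+1
#'   instead of 6N gradient evaluations)
#' @return (3N x 3N) symmetrised Hessian, Hartree/Bohr^2, atom-major
#' @export
numericalHessian <- function(mol, level = LevelOfTheory(), step = 5e-3,
                             gridPreset = "default",
                             scheme = c("central", "forward")) {
  scheme <- match.arg(scheme)
  scf0 <- singlePoint(mol, level, gridPreset = gridPreset)
  guess <- list(Da = densityMatrix(scf0, "alpha"),
                Db = densityMatrix(scf0, "beta"))
  g0 <- NULL
  if (scheme == "forward")
    g0 <- as.numeric(t(scfGradient(scf0, gridPreset = gridPreset)))
  xyz <- mol@coords * .const$ang2bohr
  n <- nAtoms(mol); n3 <- 3 * n
  H <- matrix(0, n3, n3)
  for (a in seq_len(n)) for (d in 1:3) {
    col <- 3 * (a - 1) + d
    gradAt <- function(sgn) {
      x <- xyz
      x[a, d] <- x[a, d] + sgn * step
      m <- setCoords(mol, x * .const$bohr2ang)
      scf <- singlePoint(m, level, gridPreset = gridPreset, guess = guess)
      as.numeric(t(scfGradient(scf, gridPreset = gridPreset)))
    }
    if (scheme == "central") {
      H[, col] <- (gradAt(1) - gradAt(-1)) / (2 * step)
    } else {
      H[, col] <- (gradAt(1) - g0) / step
    }
  }
  (H + t(H)) / 2
}

#' Harmonic vibrational frequencies
#'
#' Mass-weights the Hessian, projects out overall translation and
#' rotation, and diagonalises.  Imaginary modes are reported as
#' negative wavenumbers.
#'
#' @param mol molecule at a stationary geometry
#' @param hessian optional precomputed Cartesian Hessian
#' @param level,gridPreset forwarded to \code{numericalHessian}
#' @return list(frequencies (cm^-1, ascending), nImaginary)
#' @export
harmonicFrequencies <- function(mol, level = LevelOfTheory(),
                                hessian = NULL, gridPreset = "default",
                                hessianScheme = "central") {
  if (is.null(hessian))
    hessian <- numericalHessian(mol, level, gridPreset = gridPreset,
                                scheme = hessianScheme)
  n <- nAtoms(mol)
  mass <- rep(elementMass(mol@symbols), each = 3) * .const$amu2au
  Hm <- hessian / sqrt(outer(mass, mass))
  # projector built from mass-weighted translation/rotation vectors
  P <- .mwProjector(mol)
  Hp <- P %*% Hm %*% P
  ev <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE)$values
  ev <- sort(ev)
  # drop the 5/6 projected-out null modes (closest to zero)
  nnull <- if (.isLinear(mol)) 5L else 6L
  ord <- order(abs(ev))
  keep <- sort(setdiff(seq_along(ev), ord[seq_len(nnull)]))
  ev <- ev[keep]
  freqs <- sign(ev) * sqrt(abs(ev)) * .const$hartree2cm
  list(frequencies = sort(freqs), nImaginary = sum(freqs < -10))
}

.isLinear <- function(mol, tol = 1e-4) {
  if (nAtoms(mol) <= 2) return(TRUE)
  x <- scale(mol@coords, scale = FALSE)
  s <- svd(x)$d
  s[2] < tol * max(s[1], 1)
}

.mwProjector <- function(mol) {
  n <- nAtoms(mol)
  mass <- elementMass(mol@symbols) * .const$amu2au
  xyz <- mol@coords * .const$ang2bohr
  ctr <- colSums(xyz * mass) / sum(mass)
  x <- sweep(xyz, 2, ctr)
  V <- matrix(0, 3 * n, 6)
  for (a in seq_len(n)) {
    sm <- sqrt(mass[a])
    V[3 * (a - 1) + 1, 1] <- sm
    V[3 * (a - 1) + 2, 2] <- sm
    V[3 * (a - 1) + 3, 3] <- sm
    V[3 * (a - 1) + (1:3), 4] <- sm * c(0, -x[a, 3], x[a, 2])
    V[3 * (a - 1) + (1:3), 5] <- sm * c(x[a, 3], 0, -x[a, 1])
    V[3 * (a - 1) + (1:3), 6] <- sm * c(-x[a, 2], x[a, 1], 0)
  }
  qr_ <- qr(V)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  diag(3 * n) - tcrossprod(Q)
}

#' Rigid-rotor harmonic-oscillator thermochemistry
#'
#' Ideal-gas statistical thermodynamics at the given temperature and
#' pressure with unscaled harmonic frequencies.  A structure with
#' imaginary modes is rejected when \code{checkMinimum} is TRUE, since
#' thermochemistry is only meaningful for true minima (positive-definite
#' internal Hessian).
#'
#' @param mol optimised molecule
#' @param level level of theory
#' @param scf optional converged SCFResult at this geometry
#' @param hessian optional precomputed Hessian
#' @param temperature K (default 298.15)
#' @param pressure atm
#' @param sigma rotational symmetry number
#' @param checkMinimum error on imaginary frequencies
#' @param gridPreset XC quadrature preset
#' @param hessianScheme "central" (accurate) or "forward" (half the
#'   gradient evaluations; adequate for survey thermochemistry)
#' @param vibrational include the vibrational analysis (ZPE and
#'   vibrational thermal terms); FALSE gives the rigid-body record
#'   (translation + rotation + pV only), for isomer rankings where
#'   vibrational differences largely cancel
#' @return a \linkS4class{ThermoRecord}
#' @export
harmonicThermo <- function(mol, level = LevelOfTheory(), scf = NULL,
                           hessian = NULL, temperature = 298.15,
                           pressure = 1, sigma = 1, checkMinimum = TRUE,
                           gridPreset = "default",
                           hessianScheme = "central",
                           vibrational = TRUE) {
  if (is.null(scf)) scf <- singlePoint(mol, level, gridPreset = gridPreset)
  if (vibrational) {
    fr <- harmonicFrequencies(mol, level, hessian = hessian,
                              gridPreset = gridPreset,
                              hessianScheme = hessianScheme)
    if (checkMinimum && fr$nImaginary > 0)
      stop(sprintf("structure has %d imaginary frequencies; not a minimum",
                   fr$nImaginary))
  } else {
    # rigid-body mode: translational + rotational + pV terms only.
    # ZPE and vibrational entropy are omitted; meaningful for isomer
    # rankings where vibrational differences largely cancel.
    fr <- list(frequencies = numeric(0), nImaginary = 0L)
  }
  freqs <- fr$frequencies[fr$frequencies > 10]  # real modes only
  kT <- .const$kB_hartree * temperature
  # vibrational
  theta <- freqs * 1.4387768775  # cm-1 -> K
  zpe <- sum(freqs) / (2 * .const$hartree2cm)
  x <- theta / temperature
  evib <- kT * sum(x / (exp(x) - 1))
  svib <- .const$kB_hartree * sum(x / (exp(x) - 1) - log(1 - exp(-x)))
  # translational (atomic units; 1 atm in au pressure)
  Mau <- sum(elementMass(mol@symbols)) * .const$amu2au
  Pau <- pressure * 101325 / 2.9421912e13
  qtrans <- (Mau * kT / (2 * pi))^1.5 * (kT / Pau)
  strans <- .const$kB_hartree * (log(qtrans) + 2.5)
  etrans <- 1.5 * kT
  # rotational
  mass <- elementMass(mol@symbols) * .const$amu2au
  xyz <- mol@coords * .const$ang2bohr
  ctr <- colSums(xyz * mass) / sum(mass)
  x0 <- sweep(xyz, 2, ctr)
  Imat <- matrix(0, 3, 3)
  for (a in seq_len(nAtoms(mol))) {
    r <- x0[a, ]
    Imat <- Imat + mass[a] * (diag(sum(r^2), 3) - outer(r, r))
  }
  Ieig <- sort(eigen(Imat, symmetric = TRUE)$values)
  if (nAtoms(mol) == 1) {
    qrot <- 1; erot <- 0; srot <- 0
  } else if (.isLinear(mol)) {
    I <- Ieig[3]
    qrot <- 2 * I * kT / sigma
    erot <- kT
    srot <- .const$kB_hartree * (log(qrot) + 1)
  } else {
    qrot <- sqrt(pi * prod(Ieig)) * (2 * kT)^1.5 / sigma
    erot <- 1.5 * kT
    srot <- .const$kB_hartree * (log(qrot) + 1.5)
  }
  hCorr <- zpe + evib + etrans + erot + kT
  sTot <- svib + strans + srot
  gCorr <- hCorr - temperature * sTot
  new("ThermoRecord", eElec = energy(scf), zpe = zpe, hCorr = hCorr,
      gCorr = gCorr, s298 = sTot, nImaginary = fr$nImaginary,
      frequencies = fr$frequencies, temperature = temperature)
}

#' Gibbs free energy of a ThermoRecord (Hartree)
#' @param x a ThermoRecord
#' @export
gibbsEnergy <- function(x) x@eElec + x@gCorr

#' Enthalpy of a ThermoRecord (Hartree)
#' @param x a ThermoRecord
#' @export
enthalpy <- function(x) x@eElec + x@hCorr

#' Reaction energetics of the dehydro-acetylation decomposition
#'
#' Thermodynamics of  ester -> diene + 2 CH3COOH  at 298.15 K, 1 atm:
#' product-minus-reactant enthalpy, Gibbs energy and entropy from RRHO
#' records of the three species at a common level of theory.
#'
#' @param esterThermo,dieneThermo,acohThermo \linkS4class{ThermoRecord}s
#' @param esterIsomer,dieneIsomer labels carried into the result
#' @return data.frame with dH (kcal/mol), dG (kcal/mol), dS (cal/mol/K)
#' @export
reactionEnergetics <- function(esterThermo, dieneThermo, acohThermo,
                               esterIsomer = "", dieneIsomer = "") {
  T <- esterThermo@temperature
  dH <- (enthalpy(dieneThermo) + 2 * enthalpy(acohThermo) -
         enthalpy(esterThermo)) * .const$hartree2kcal
  dG <- (gibbsEnergy(dieneThermo) + 2 * gibbsEnergy(acohThermo) -
         gibbsEnergy(esterThermo)) * .const$hartree2kcal
  dS <- (dH - dG) / T * 1000
  data.frame(ester = esterIsomer, diene = dieneIsomer,
             dH_kcal = dH, dG_kcal = dG, dS_cal = dS,
             stringsAsFactors = FALSE)
}

#' Full decomposition table over ester diastereomers and diene isomers
#'
#' Optimises every species, runs frequencies, and tabulates the
#' reaction thermodynamics for each (ester, diene) combination.
#'
#' @param level level of theory for all species
#' @param preset optimisation convergence preset
#' @param gridPreset XC quadrature preset
#' @param hessianScheme forwarded to \code{harmonicThermo}
#' @param optimize optimise each species first (TRUE) or use the
#'   fixture reference geometries as-is
#' @param vibrational forwarded to \code{harmonicThermo}
#' @param verbose report per-species progress
#' @param esters,dienes fixture ids
#' @return data.frame (one row per combination) with an attribute
#'   "records" holding the ThermoRecords
#' @export
decompositionTable <- function(level = LevelOfTheory(), preset = "default",
                               gridPreset = "default",
                               hessianScheme = "central",
                               optimize = TRUE, vibrational = TRUE,
                               verbose = FALSE,
                               esters = c("diacetoxy_dinitrobutane_RR",
                                          "diacetoxy_dinitrobutane_meso"),
                               dienes = c("dinitrobutadiene_EE",
                                          "dinitrobutadiene_EZ",
                                          "dinitrobutadiene_ZZ")) {
  thermoOf <- function(id) {
    t0 <- Sys.time()
    if (optimize) {
      opt <- optimizeGeometry(builtinMolecule(id), level, preset = preset,
                              gridPreset = gridPreset)
      mol <- opt$molecule; scf <- opt$scf
      if (verbose)
        message(sprintf("%s: optimised in %d cycles (%.1f min)", id,
                        opt$cycles,
                        as.numeric(Sys.time() - t0, units = "mins")))
    } else {
      mol <- builtinMolecule(id)
      scf <- singlePoint(mol, level, gridPreset = gridPreset)
    }
    th <- harmonicThermo(mol, level, scf = scf,
                         checkMinimum = FALSE, gridPreset = gridPreset,
                         hessianScheme = hessianScheme,
                         vibrational = vibrational)
    if (verbose)
      message(sprintf("%s: thermo done (%.1f min total)", id,
                      as.numeric(Sys.time() - t0, units = "mins")))
    th
  }
  recs <- list()
  for (id in c(esters, dienes, "acetic_acid")) recs[[id]] <- thermoOf(id)
  out <- NULL
  for (e in esters) for (d in dienes)
    out <- rbind(out, reactionEnergetics(recs[[e]], recs[[d]],
                                         recs[["acetic_acid"]], e, d))
  attr(out, "records") <- recs
  out
}

#' Lowest-energy rotamer over a dihedral scan
#'
#' Rotates the fragment on the far side of the j-k bond to n evenly
#' spaced starting dihedrals, optimises each, and returns the lowest.
#'
#' @param mol starting molecule
#' @param dihedralAtoms integer 4-vector (i, j, k, l)
#' @param nSteps number of starting points (1 = plain optimisation)
#' @param level,preset,gridPreset forwarded to the optimiser
#' @return list(molecule, scf, energies of all scanned starts)
#' @export
rotamerScan <- function(mol, dihedralAtoms, nSteps = 3,
                        level = LevelOfTheory(), preset = "default",
                        gridPreset = "default") {
  stopifnot(length(dihedralAtoms) == 4, nSteps >= 1)
  i <- dihedralAtoms[1]; j <- dihedralAtoms[2]
  k <- dihedralAtoms[3]; l <- dihedralAtoms[4]
  best <- NULL
  energies <- numeric(nSteps)
  offsets <- seq(0, 360, length.out = nSteps + 1)[seq_len(nSteps)]
  for (s in seq_len(nSteps)) {
    m <- if (offsets[s] == 0) mol else
      .rotateDihedral(mol, i, j, k, offsets[s])
    opt <- optimizeGeometry(m, level, preset = preset,
                            gridPreset = gridPreset)
    energies[s] <- energy(opt$scf)
    if (is.null(best) || energies[s] < energy(best$scf)) best <- opt
  }
  list(molecule = best$molecule, scf = best$scf, energies = energies)
}

# rotate all atoms on the k-side of bond j-k by angle (degrees)
.rotateDihedral <- function(mol, i, j, k, angle) {
  n <- nAtoms(mol)
  bonds <- .bondList(mol)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    bi <- bonds[b, 1]; bj <- bonds[b, 2]
    adj[[bi]] <- c(adj[[bi]], bj); adj[[bj]] <- c(adj[[bj]], bi)
  }
  # atoms reachable from k without crossing j
  seen <- rep(FALSE, n); seen[j] <- TRUE
  stack <- k
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[cur]) next
    seen[cur] <- TRUE
    stack <- c(stack, adj[[cur]])
  }
  moving <- setdiff(which(seen), c(j))
  xyz <- mol@coords
  axis <- xyz[k, ] - xyz[j, ]
  axis <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  for (a in moving)
    xyz[a, ] <- as.numeric(R %*% (xyz[a, ] - xyz[j, ])) + xyz[j, ]
  setCoords(mol, xyz)
}
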