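# Self-consistent-field driver: restricted/unrestricted Kohn-Sham
# (B3LYP, Gaussian correlation convention) and Hartree-Fock in
# contracted Cartesian Gaussian bases, with DIIS acceleration.

.gridPresets <- list(
  coarse  = list(nrad = 35, ntheta = 10),
  default = list(nrad = 50, ntheta = 14),
  fine    = list(nrad = 75, ntheta = 18)
)

.functionalSpec <- function(functional) {
  switch(functional,
    b3lyp = list(cx = 0.20, coef = c(0.80, 0.72, 0.19, 0.81)),
    hf    = list(cx = 1.00, coef = c(0, 0, 0, 0)),
    stop("unknown functional ", functional))
}

#' @keywords internal
.spinCounts <- function(mol) {
  nel <- countElectrons(mol)
  nun <- mol@multiplicity - 1L
  if ((nel - nun) %% 2L != 0L || nel < nun)
    stop("charge/multiplicity inconsistent with electron count")
  nb <- (nel - nun) %/% 2L
  c(alpha = nb + nun, beta = nb)
}

#' Single-point SCF calculation
#'
#' Runs a restricted (singlet) or unrestricted (open-shell) SCF at the
#' given level of theory and returns the converged state.  Convergence
#' is on both the energy change and the maximum element of the DIIS
#' error (orbital-gradient) matrix; an unconverged SCF is an error,
#' never a silently returned result.
#'
#' @param mol a \linkS4class{Molecule}
#' @param level a \linkS4class{LevelOfTheory}
#' @param gridPreset exchange-correlation quadrature: "coarse",
#'   "default" or "fine"
#' @param convE energy convergence, Hartree
#' @param convErr max orbital-gradient convergence, a.u.
#' @param maxiter maximum SCF cycles
#' @param guess optional list(Da, Db) starting density matrices
#' @param verbose print per-iteration energies
#' @return an \linkS4class{SCFResult}
#' @examples
#' \donttest{
#' h2 <- builtinMolecule("h2")
#' scf <- singlePoint(h2, LevelOfTheory("hf", "sto-3g"))
#' energy(scf)
#' }
#' @export
singlePoint <- function(mol, level = LevelOfTheory(),
                        gridPreset = "default", convE = 1e-8,
                        convErr = 1e-5, maxiter = 200, guess = NULL,
                        verbose = FALSE) {
  validObject(mol)
  fs <- .functionalSpec(level@functional)
  shells <- buildShells(mol, level@basis)
  nbf <- nbfOf(shells)
  xyzB <- mol@coords * .const$ang2bohr
  Z <- elementZ(mol@symbols)
  ints <- .cpp_int1e_ovl_kin(shells)
  S <- ints$S
  H <- ints$T + .cpp_int1e_nuc(shells, xyzB, as.numeric(Z))
  Enuc <- .cpp_nuc_rep(xyzB, as.numeric(Z))$E
  eri <- .cpp_eri_build(shells, 1e-10)
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > 1e-7
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  ns <- .spinCounts(mol)
  na <- ns[["alpha"]]; nb <- ns[["beta"]]
  restricted <- (mol@multiplicity == 1L)
  useXC <- fs$cx < 1
  grid <- NULL
  if (useXC) {
    gp <- .gridPresets[[gridPreset]]
    if (is.null(gp)) stop("unknown grid preset ", gridPreset)
    grid <- .cpp_becke_grid(xyzB, elementBragg(mol@symbols) * .const$ang2bohr,
                            gp$nrad, gp$ntheta)
  }
  # superposition of atomic densities (block-diagonal guess)
  sadGuess <- function() {
    groundMult <- c(H = 2L, C = 3L, N = 4L, O = 3L)
    Dg <- matrix(0, nbf, nbf)
    at <- bfAtoms(shells)
    nbfsh <- vapply(shells, function(s) (s$l + 1L) * (s$l + 2L) / 2L, 1)
    for (a in seq_len(nAtoms(mol))) {
      sym <- mol@symbols[a]
      key <- paste("sad", sym, level@basis)
      if (is.null(.pkgenv[[key]])) {
        mult <- groundMult[[sym]]
        if (is.null(mult)) return(NULL)
        atomMol <- Molecule(sym, matrix(0, 1, 3), 0L, mult,
                            label = paste0("atom_", sym))
        res <- tryCatch(
          singlePoint(atomMol, LevelOfTheory("hf", level@basis),
                      convE = 1e-6, convErr = 1e-3, maxiter = 120),
          error = function(e) NULL)
        if (is.null(res)) return(NULL)
        blk <- densityMatrix(res, "alpha") + densityMatrix(res, "beta")
        # spherically average: keep only same-l couplings, isotropic
        # within p/d component sets
        ash <- buildShells(atomMol, level@basis)
        ls <- vapply(ash, `[[`, 1L, "l")
        offs <- cumsum(c(0L, vapply(ash, function(s)
          (s$l + 1L) * (s$l + 2L) %/% 2L, 1L)))
        sph <- matrix(0, nrow(blk), ncol(blk))
        for (i in seq_along(ash)) for (j in seq_along(ash)) {
          if (ls[i] != ls[j]) next
          bi <- (offs[i] + 1L):offs[i + 1L]
          bj <- (offs[j] + 1L):offs[j + 1L]
          sub <- blk[bi, bj, drop = FALSE]
          sph[bi, bj] <- diag(mean(diag(sub)), length(bi))
        }
        .pkgenv[[key]] <- sph
      }
      blk <- .pkgenv[[key]]
      idx <- which(at == a)
      Dg[idx, idx] <- blk
    }
    Dg
  }
  solveF <- function(F) {
    Fp <- crossprod(X, F %*% X)
    ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ef$values)
    list(eps = ef$values[ord], C = X %*% ef$vectors[, ord, drop = FALSE])
  }
  densOf <- function(C, nocc) {
    if (nocc == 0) return(matrix(0, nbf, nbf))
    Co <- C[, seq_len(nocc), drop = FALSE]
    tcrossprod(Co)
  }
  # initial guess: supplied densities, else superposition of atomic
  # densities, else generalised Wolfsberg-Helmholz on the core
  # Hamiltonian
  startedCold <- is.null(guess)
  if (is.null(guess) && nAtoms(mol) > 1) {
    Dg <- sadGuess()
    if (!is.null(Dg)) guess <- list(Da = Dg / 2, Db = Dg / 2)
  }
  if (is.null(guess)) {
    hd <- diag(H)
    F0 <- 0.875 * S * outer(hd, hd, "+")
    diag(F0) <- hd
    sa <- solveF(F0)
    Ca <- Cb <- sa$C
    Da <- densOf(Ca, na); Db <- densOf(Cb, nb)
  } else {
    Da <- guess$Da; Db <- guess$Db
  }
  diisF <- list(); diisE <- list(); maxdiis <- 10
  Eold <- 0; conv <- FALSE; niter <- 0L
  epsA <- epsB <- NULL; Ca <- Cb <- NULL; Etot <- NA_real_
  for (it in seq_len(maxiter)) {
    niter <- it
    Dt <- Da + Db
    jk <- .cpp_build_jk(eri, Dt, if (restricted) list(Da) else list(Da, Db))
    J <- jk$J
    Ka <- jk$K[[1]]
    Kb <- if (restricted) Ka else jk$K[[2]]
    Exc <- 0; Va <- Vb <- 0
    if (useXC) {
      xc <- .cpp_xc_int(shells, Da, Db, grid$points, grid$weights,
                        fs$coef, TRUE, FALSE, nAtoms(mol))
      Exc <- xc$Exc; Va <- xc$Va; Vb <- xc$Vb
    }
    Fa <- H + J - fs$cx * Ka + Va
    Fb <- H + J - fs$cx * Kb + Vb
    Etot <- sum(Dt * H) + 0.5 * sum(Dt * J) -
      0.5 * fs$cx * (sum(Da * Ka) + sum(Db * Kb)) + Exc + Enuc
    # DIIS error: X^T (F D S - S D F) X per spin
    erra <- crossprod(X, (Fa %*% Da %*% S - S %*% Da %*% Fa) %*% X)
    errb <- crossprod(X, (Fb %*% Db %*% S - S %*% Db %*% Fb) %*% X)
    err <- max(abs(erra), abs(errb))
    if (verbose)
      message(sprintf("  iter %3d  E = %.10f  dE = %9.2e  err = %8.2e",
                      it, Etot, Etot - Eold, err))
    if (abs(Etot - Eold) < convE && err < convErr && it > 1) {
      conv <- TRUE
      sa <- solveF(Fa); epsA <- sa$eps; Ca <- sa$C
      if (restricted) { epsB <- epsA; Cb <- Ca }
      else { sb <- solveF(Fb); epsB <- sb$eps; Cb <- sb$C }
      break
    }
    Eold <- Etot
    # DIIS extrapolation
    diisF[[length(diisF) + 1]] <- list(Fa, Fb)
    diisE[[length(diisE) + 1]] <- c(erra, errb)
    if (length(diisF) > maxdiis) {
      diisF <- diisF[-1]; diisE <- diisE[-1]
    }
    nd <- length(diisF)
    if (nd >= 2) {
      B <- matrix(0, nd + 1, nd + 1)
      for (i in seq_len(nd)) for (j in seq_len(i)) {
        B[i, j] <- B[j, i] <- sum(diisE[[i]] * diisE[[j]])
      }
      B[nd + 1, seq_len(nd)] <- B[seq_len(nd), nd + 1] <- -1
      rhs <- c(rep(0, nd), -1)
      cw <- tryCatch(solve(B, rhs)[seq_len(nd)], error = function(e) NULL)
      if (!is.null(cw) && all(is.finite(cw))) {
        Fa <- Reduce(`+`, Map(function(f, w) w * f[[1]], diisF, cw))
        Fb <- Reduce(`+`, Map(function(f, w) w * f[[2]], diisF, cw))
      }
    }
    sa <- solveF(Fa)
    epsA <- sa$eps; Ca <- sa$C
    if (restricted) {
      epsB <- epsA; Cb <- Ca
    } else {
      sb <- solveF(Fb); epsB <- sb$eps; Cb <- sb$C
    }
    Danew <- densOf(Ca, na); Dbnew <- densOf(Cb, nb)
    if (it <= 2 && startedCold) {  # light damping at startup
      Da <- 0.7 * Danew + 0.3 * Da
      Db <- 0.7 * Dbnew + 0.3 * Db
    } else {
      Da <- Danew; Db <- Dbnew
    }
  }
  if (!conv)
    stop(sprintf(
      "SCF failed to converge in %d iterations (last E = %.8f, err = %.2e)",
      maxiter, Etot, err))
  s2 <- NA_real_
  if (!restricted) {
    Sab <- crossprod(Ca[, seq_len(na), drop = FALSE],
                     S %*% Cb[, seq_len(nb), drop = FALSE])
    sz <- (na - nb) / 2
    s2 <- sz * (sz + 1) + nb - sum(Sab^2)
  }
  res <- new("SCFResult", molecule = mol, level = level, energy = Etot,
             converged = TRUE, niter = niter, restricted = restricted,
             coefA = Ca, coefB = Cb, epsA = epsA, epsB = epsB,
             occA = c(rep(1, na), rep(0, nbf - na))[seq_len(ncol(Ca))],
             occB = c(rep(1, nb), rep(0, nbf - nb))[seq_len(ncol(Cb))],
             nAlpha = as.integer(na), nBeta = as.integer(nb),
             shells = shells, overlap = S, s2 = s2)
  attr(res, "eriStore") <- eri
  attr(res, "gridPreset") <- gridPreset
  res
}

#' Analytic nuclear gradient of the SCF energy
#'
#' Assembles the Hellmann-Feynman + Pulay one-electron terms, the
#' two-electron derivative contraction, the exchange-correlation grid
#' term (fixed-grid approximation: quadrature-weight derivatives are
#' neglected) and nuclear repulsion.
#'
#' @param scf a converged \linkS4class{SCFResult}
#' @param gridPreset quadrature preset for the XC derivative term
#' @return nAtoms x 3 matrix, Hartree/Bohr
#' @export
scfGradient <- function(scf, gridPreset = NULL) {
  stopifnot(is(scf, "SCFResult"), scf@converged)
  mol <- scf@molecule
  fs <- .functionalSpec(scf@level@functional)
  shells <- scf@shells
  xyzB <- mol@coords * .const$ang2bohr
  Z <- elementZ(mol@symbols)
  Da <- densityMatrix(scf, "alpha")
  Db <- densityMatrix(scf, "beta")
  Dt <- Da + Db
  # energy-weighted density
  wmat <- function(C, eps, occ) {
    o <- which(occ > 0)
    if (!length(o)) return(matrix(0, nrow(C), nrow(C)))
    Co <- C[, o, drop = FALSE]
    Co %*% (diag(eps[o], length(o)) %*% t(Co))
  }
  W <- wmat(scf@coefA, scf@epsA, scf@occA) + wmat(scf@coefB, scf@epsB, scf@occB)
  g <- .cpp_grad_1e(shells, Dt, W, xyzB, as.numeric(Z), nAtoms(mol))
  g <- g + .cpp_eri_grad(shells, Dt, list(Da, Db), fs$cx, nAtoms(mol), 1e-10)
  if (fs$cx < 1) {
    if (is.null(gridPreset))
      gridPreset <- attr(scf, "gridPreset") %||% "default"
    gp <- .gridPresets[[gridPreset]]
    grid <- .cpp_becke_grid(xyzB, elementBragg(mol@symbols) * .const$ang2bohr,
                            gp$nrad, gp$ntheta)
    xc <- .cpp_xc_int(shells, Da, Db, grid$points, grid$weights,
                      fs$coef, FALSE, TRUE, nAtoms(mol))
    g <- g + xc$grad
  }
  g + .cpp_nuc_rep(xyzB, as.numeric(Z))$grad
}

`%||%` <- function(a, b) if (is.null(a)) b else a
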