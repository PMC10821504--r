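# Geometry optimisation: rational-function-optimisation steps in
# Cartesian coordinates with a Lindh-type model starting Hessian built
# from redundant internals, BFGS updates and a trust radius.

.bondList <- function(mol, scale = 1.30) {
  xyz <- mol@coords
  rc <- elementRcov(mol@symbols)
  n <- nAtoms(mol)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r < scale * (rc[i] + rc[j])) out <- rbind(out, c(i, j, r))
  }
  # connect disjoint fragments through their closest atom pair
  repeat {
    comp <- .components(n, out)
    if (max(comp) == 1) break
    best <- NULL; bestr <- Inf
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (comp[i] != comp[j]) {
        r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (r < bestr) { bestr <- r; best <- c(i, j, r) }
      }
    }
    out <- rbind(out, best)
  }
  out
}

.components <- function(n, bonds) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    if (!is.null(bonds)) for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[i] <- comp[j] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

.internalCoords <- function(mol) {
  bonds <- .bondList(mol)
  n <- nAtoms(mol)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  angles <- NULL
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2)
      for (a in seq_len(length(nb) - 1)) for (b in seq(a + 1, length(nb)))
        angles <- rbind(angles, c(nb[a], j, nb[b]))
  }
  dihedrals <- NULL
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j))
      if (i != l) dihedrals <- rbind(dihedrals, c(i, j, k, l))
  }
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

# Lindh exponential pair weight (coordinates in Bohr)
.lindhRho <- function(zi, zj, r2) {
  per <- function(z) if (z <= 2) 1L else if (z <= 10) 2L else 3L
  pr <- c(per(zi), per(zj))
  key <- paste(sort(pr), collapse = "")
  ref <- switch(key, "11" = 1.35, "12" = 2.10, "22" = 2.53,
                "13" = 2.53, "23" = 2.87, "33" = 3.40)
  al <- switch(key, "11" = 1.0000, "12" = 0.3949, "22" = 0.2800,
               "13" = 0.3949, "23" = 0.2800, "33" = 0.2800)
  exp(al * (ref * ref - r2))
}

.bondLen <- function(x, i, j) sqrt(sum((x[i, ] - x[j, ])^2))
.bondAngle <- function(x, i, j, k) {
  u <- x[i, ] - x[j, ]; v <- x[k, ] - x[j, ]
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}
.dihedralAngle <- function(x, i, j, k, l) {
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  n1 <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3], b1[1]*b2[2]-b1[2]*b2[1])
  n2 <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3], b2[1]*b3[2]-b2[2]*b3[1])
  m1 <- c(n1[2]*b2[3]-n1[3]*b2[2], n1[3]*b2[1]-n1[1]*b2[3], n1[1]*b2[2]-n1[2]*b2[1])
  nb2 <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / nb2, sum(n1 * n2))
}

# model Hessian in Cartesian coordinates (Bohr)
.lindhHessian <- function(mol) {
  xyz <- mol@coords * .const$ang2bohr
  Z <- elementZ(mol@symbols)
  ic <- .internalCoords(mol)
  n3 <- 3 * nAtoms(mol)
  H <- diag(0.005, n3)
  addB <- function(k, qfun, atoms) {
    h <- 1e-5
    B <- numeric(n3)
    q0 <- qfun(xyz)
    for (a in atoms) for (d in 1:3) {
      xp <- xyz; xp[a, d] <- xp[a, d] + h
      xm <- xyz; xm[a, d] <- xm[a, d] - h
      dq <- qfun(xp) - qfun(xm)
      dq <- atan2(sin(dq), cos(dq))  # unwrap for angular coordinates
      B[3 * (a - 1) + d] <- dq / (2 * h)
    }
    H <<- H + k * outer(B, B)
    invisible(q0)
  }
  bl <- ic$bonds
  for (b in seq_len(nrow(bl))) {
    i <- bl[b, 1]; j <- bl[b, 2]
    r2 <- sum((xyz[i, ] - xyz[j, ])^2)
    rho <- .lindhRho(Z[i], Z[j], r2)
    addB(0.45 * rho, function(x) .bondLen(x, i, j), c(i, j))
  }
  if (!is.null(ic$angles)) for (a in seq_len(nrow(ic$angles))) {
    v <- ic$angles[a, ]
    rho1 <- .lindhRho(Z[v[1]], Z[v[2]], sum((xyz[v[1], ] - xyz[v[2], ])^2))
    rho2 <- .lindhRho(Z[v[3]], Z[v[2]], sum((xyz[v[3], ] - xyz[v[2], ])^2))
    addB(0.15 * rho1 * rho2,
         function(x) .bondAngle(x, v[1], v[2], v[3]), v)
  }
  if (!is.null(ic$dihedrals)) for (t in seq_len(nrow(ic$dihedrals))) {
    v <- ic$dihedrals[t, ]
    a1 <- .bondAngle(xyz, v[1], v[2], v[3])
    a2 <- .bondAngle(xyz, v[2], v[3], v[4])
    if (min(abs(sin(a1)), abs(sin(a2))) < 0.1) next
    rho1 <- .lindhRho(Z[v[1]], Z[v[2]], sum((xyz[v[1], ] - xyz[v[2], ])^2))
    rho2 <- .lindhRho(Z[v[2]], Z[v[3]], sum((xyz[v[2], ] - xyz[v[3], ])^2))
    rho3 <- .lindhRho(Z[v[3]], Z[v[4]], sum((xyz[v[3], ] - xyz[v[4], ])^2))
    addB(0.005 * rho1 * rho2 * rho3,
         function(x) .dihedralAngle(x, v[1], v[2], v[3], v[4]), v)
  }
  H
}

# projector removing overall translation and rotation
.trProjector <- function(xyz) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2, ctr)
  V <- matrix(0, 3 * n, 6)
  for (a in seq_len(n)) {
    V[3 * (a - 1) + 1, 1] <- 1
    V[3 * (a - 1) + 2, 2] <- 1
    V[3 * (a - 1) + 3, 3] <- 1
    V[3 * (a - 1) + (1:3), 4] <- c(0, -x[a, 3], x[a, 2])
    V[3 * (a - 1) + (1:3), 5] <- c(x[a, 3], 0, -x[a, 1])
    V[3 * (a - 1) + (1:3), 6] <- c(-x[a, 2], x[a, 1], 0)
  }
  qr_ <- qr(V)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  diag(3 * n) - tcrossprod(Q)
}

.optPresets <- list(
  default = list(gmax = 4.5e-4, grms = 3.0e-4),
  fast    = list(gmax = 2.0e-3, grms = 1.3e-3)
)

#' Optimise a molecular geometry
#'
#' Minimises the SCF energy with RFO/BFGS steps from a Lindh-type model
#' Hessian.  Convergence is on the maximum and root-mean-square
#' Cartesian force; the "default" preset uses thresholds of
#' 4.5e-4 / 3e-4 Hartree/Bohr, the "fast" preset relaxes them for
#' desk-scale survey work.
#'
#' @param mol starting \linkS4class{Molecule}
#' @param level \linkS4class{LevelOfTheory}
#' @param preset "default" or "fast" convergence preset
#' @param maxCycles maximum optimisation steps
#' @param gridPreset XC quadrature used during optimisation
#' @param verbose print per-step energies
#' @return list(molecule, scf, energies, cycles, converged, gmax)
#' @export
optimizeGeometry <- function(mol, level = LevelOfTheory(),
                             preset = "default", maxCycles = 60,
                             gridPreset = "default", verbose = FALSE) {
  thr <- .optPresets[[preset]]
  if (is.null(thr)) stop("unknown optimisation preset ", preset)
  xyz <- mol@coords * .const$ang2bohr
  n3 <- length(xyz)
  H <- .lindhHessian(mol)
  trust <- 0.3
  guess <- NULL
  Eprev <- NA; gprev <- NULL; xprev <- NULL
  energies <- numeric()
  scf <- NULL
  conv <- FALSE
  gmax <- NA
  predicted <- NA
  for (cycle in seq_len(maxCycles)) {
    m <- setCoords(mol, xyz * .const$bohr2ang)
    scf <- singlePoint(m, level, gridPreset = gridPreset, guess = guess)
    guess <- list(Da = densityMatrix(scf, "alpha"),
                  Db = densityMatrix(scf, "beta"))
    g <- scfGradient(scf, gridPreset = gridPreset)
    E <- energy(scf)
    energies <- c(energies, E)
    P <- .trProjector(xyz)
    gv <- P %*% as.numeric(t(g))
    gmax <- max(abs(gv)); grms <- sqrt(mean(gv^2))
    if (verbose)
      message(sprintf("opt cycle %2d  E = %.8f  gmax = %.2e  grms = %.2e",
                      cycle, E, gmax, grms))
    if (gmax < thr$gmax && grms < thr$grms) { conv <- TRUE; break }
    # trust-radius feedback
    if (!is.na(Eprev) && !is.na(predicted) && predicted < 0) {
      ratio <- (E - Eprev) / predicted
      if (ratio > 0.75 && ratio < 1.25) trust <- min(0.5, trust * 1.3)
      else if (ratio < 0.25 || E > Eprev) trust <- max(0.02, trust * 0.5)
    }
    # BFGS update
    if (!is.null(gprev)) {
      s <- as.numeric(t(xyz) - t(xprev))
      y <- as.numeric(gv - gprev)
      sy <- sum(s * y)
      if (sy > 1e-8) {
        Hs <- H %*% s
        H <- H + outer(y, y) / sy -
          (Hs %*% t(Hs)) / as.numeric(crossprod(s, Hs))
      }
    }
    Hp <- P %*% H %*% P + 1000 * (diag(n3) - P)
    Hp <- (Hp + t(Hp)) / 2
    # RFO step
    A <- rbind(cbind(Hp, gv), c(as.numeric(gv), 0))
    ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
    v <- ev$vectors[, which.min(ev$values)]
    step <- v[seq_len(n3)] / v[n3 + 1]
    sn <- sqrt(sum(step^2))
    if (sn > trust) step <- step * trust / sn
    predicted <- sum(gv * step) + 0.5 * sum(step * (Hp %*% step))
    xprev <- xyz; gprev <- gv; Eprev <- E
    xyz <- xyz + matrix(step, nAtoms(mol), 3, byrow = TRUE)
  }
  if (!conv)
    warning(sprintf("geometry not converged after %d cycles (gmax %.1e)",
                    maxCycles, gmax))
  list(molecule = setCoords(mol, xyz * .const$bohr2ang), scf = scf,
       energies = energies, cycles = length(energies), converged = conv,
       gmax = gmax)
}
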