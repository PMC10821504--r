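# Scalar fields on regular 3D grids: electron density, ELF, NCI
# (reduced density gradient and sign(lambda2)*rho), molecular
# electrostatic potential; Gaussian cube file I/O; analytic test fields.

#' Construct an axis-aligned grid enclosing a molecule
#'
#' @param mol a \linkS4class{Molecule}
#' @param spacing grid step, Bohr
#' @param padding margin added around the nuclear bounding box, Bohr
#' @return a \linkS4class{GridSpec}
#' @export
makeGrid <- function(mol, spacing = 0.1, padding = 4.0) {
  if (spacing <= 0) stop("spacing must be positive")
  if (padding < 0) stop("padding must be nonnegative")
  xyz <- mol@coords * .const$ang2bohr
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  new("GridSpec", origin = lo, axes = diag(spacing, 3), shape = shape)
}

.evalOnGrid <- function(scf, grid, what) {
  pts <- gridPoints(grid)
  Da <- densityMatrix(scf, "alpha")
  Db <- densityMatrix(scf, "beta")
  .cpp_field_eval(scf@shells, Da, Db, pts,
                  "grad2" %in% what, "tau" %in% what,
                  "spin" %in% what, "lambda2" %in% what)
}

.asField <- function(vals, grid, quantity) {
  new("ScalarField", grid = grid, quantity = quantity,
      values = array(vals, grid@shape))
}

#' Electron density on a grid
#'
#' The trapezoidal integral of the result approximates the electron
#' count (a conservation test available via \code{fieldIntegral}).
#'
#' @param scf converged \linkS4class{SCFResult}
#' @param grid a \linkS4class{GridSpec}
#' @return \linkS4class{ScalarField} of quantity "rho"
#' @export
densityField <- function(scf, grid) {
  if (!scf@converged) stop("SCF result is not converged")
  ev <- .evalOnGrid(scf, grid, character())
  .asField(pmax(ev$rho, 0), grid, "rho")
}

#' Integral of a scalar field over its grid
#' @param field a ScalarField
#' @export
fieldIntegral <- function(field) sum(field@values) * voxelVolume(field@grid)

#' ELF kernel from density, squared density gradient and kinetic density
#'
#' Becke-Edgecombe construction: ELF = 1/(1 + (D/Dh)^2) with
#' D = tau - |grad rho|^2/(8 rho) and the uniform-gas reference
#' Dh = (3/10)(3 pi^2)^(2/3) rho^(5/3).  tau is 1/2 sum_i f_i
#' |grad psi_i|^2.  A density floor avoids NaN in vacuum; the Pauli
#' kinetic term D is clamped at zero.
#'
#' @param rho electron density, a.u.
#' @param grad2 squared density gradient
#' @param tau kinetic energy density
#' @param rhoFloor densities below this give ELF = 0
#' @return ELF values in [0, 1]
#' @export
elfKernel <- function(rho, grad2, tau, rhoFloor = 1e-12) {
  D <- pmax(tau - grad2 / (8 * pmax(rho, rhoFloor)), 0)
  Dh <- 0.3 * (3 * pi^2)^(2 / 3) * pmax(rho, rhoFloor)^(5 / 3)
  elf <- 1 / (1 + (D / Dh)^2)
  elf[rho < rhoFloor] <- 0
  pmin(pmax(elf, 0), 1)
}

#' ELF on a grid
#' @inheritParams densityField
#' @return \linkS4class{ScalarField} of quantity "elf"
#' @export
elfField <- function(scf, grid) {
  if (!scf@converged) stop("SCF result is not converged")
  ev <- .evalOnGrid(scf, grid, c("grad2", "tau"))
  .asField(elfKernel(ev$rho, ev$grad2, ev$tau), grid, "elf")
}

#' Reduced density gradient from density and squared gradient
#'
#' s = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3)).
#'
#' @inheritParams elfKernel
#' @export
rdgKernel <- function(rho, grad2, rhoFloor = 1e-12) {
  r <- pmax(rho, rhoFloor)
  sqrt(pmax(grad2, 0)) / (2 * (3 * pi^2)^(1 / 3) * r^(4 / 3))
}

#' Non-covalent interaction fields and scatter data
#'
#' Computes the reduced density gradient s and sign(lambda2)*rho
#' (lambda2 = middle eigenvalue of the density Hessian) on the grid and
#' assembles the NCI scatter restricted to |sign(lambda2)*rho| <=
#' window.  Covalent/nuclear regions (rho > covalentRho) are excluded
#' from interaction detection.
#'
#' @inheritParams densityField
#' @param window abscissa window, a.u.
#' @param covalentRho density above which a point is considered
#'   covalent/core, a.u.
#' @param sMax RDG threshold defining a low-gradient interaction point
#' @return list(rdg, signedRho (ScalarFields), scatter (NciScatter),
#'   interactions (data.frame of low-gradient points))
#' @export
nciFields <- function(scf, grid, window = 0.05, covalentRho = 0.1,
                      sMax = 0.5) {
  if (!scf@converged) stop("SCF result is not converged")
  ev <- .evalOnGrid(scf, grid, c("grad2", "lambda2"))
  s <- rdgKernel(ev$rho, ev$grad2)
  sr <- sign(ev$lambda2) * ev$rho
  keep <- abs(sr) <= window & ev$rho > 1e-8
  scatter <- new("NciScatter", signedRho = sr[keep], s = s[keep],
                 window = window)
  low <- which(keep & s < sMax & ev$rho < covalentRho)
  inter <- data.frame(index = low, signedRho = sr[low], s = s[low],
                      rho = ev$rho[low])
  list(rdg = .asField(s, grid, "rdg"),
       signedRho = .asField(sr, grid, "signed_rho"),
       scatter = scatter, interactions = inter)
}

#' Molecular electrostatic potential on a grid
#'
#' V(r) = sum_A Z_A/|r - R_A| - int rho(r')/|r - r'| dr', evaluated
#' with analytic one-electron Coulomb integrals per grid point.  Points
#' closer than \code{maskRadius} to a nucleus are set NA (the nuclear
#' singularity).  MEP evaluation is expensive per point; coarse grids
#' (0.3-0.5 Bohr) are recommended.
#'
#' @inheritParams densityField
#' @param maskRadius Bohr
#' @return \linkS4class{ScalarField} of quantity "mep"
#' @export
mepField <- function(scf, grid, maskRadius = 0.3) {
  if (!scf@converged) stop("SCF result is not converged")
  pts <- gridPoints(grid)
  mol <- scf@molecule
  xyzB <- mol@coords * .const$ang2bohr
  Z <- elementZ(mol@symbols)
  Dt <- densityMatrix(scf, "total")
  vel <- .cpp_esp_points(scf@shells, Dt, pts)
  vnuc <- numeric(nrow(pts))
  mind <- rep(Inf, nrow(pts))
  for (a in seq_len(nAtoms(mol))) {
    d <- sqrt((pts[, 1] - xyzB[a, 1])^2 + (pts[, 2] - xyzB[a, 2])^2 +
              (pts[, 3] - xyzB[a, 3])^2)
    mind <- pmin(mind, d)
    vnuc <- vnuc + Z[a] / pmax(d, 1e-12)
  }
  v <- vnuc - vel
  v[mind < maskRadius] <- NA_real_
  .asField(v, grid, "mep")
}

#' Electrostatic potential at arbitrary points (Bohr)
#' @param scf converged SCFResult
#' @param pts n x 3 matrix of points, Bohr
#' @return potential in a.u.
#' @export
espAtPoints <- function(scf, pts) {
  mol <- scf@molecule
  xyzB <- mol@coords * .const$ang2bohr
  Z <- elementZ(mol@symbols)
  Dt <- densityMatrix(scf, "total")
  vel <- .cpp_esp_points(scf@shells, Dt, pts)
  vnuc <- numeric(nrow(pts))
  for (a in seq_len(nAtoms(mol))) {
    d <- sqrt((pts[, 1] - xyzB[a, 1])^2 + (pts[, 2] - xyzB[a, 2])^2 +
              (pts[, 3] - xyzB[a, 3])^2)
    vnuc <- vnuc + Z[a] / pmax(d, 1e-12)
  }
  vnuc - vel
}

# ---------------------------------------------------------------------
# Analytic test fields
# ---------------------------------------------------------------------

#' Analytic scalar fields for testing grid machinery
#'
#' "gaussian_density": a normalised 3D Gaussian
#' A exp(-|r-c|^2/(2 w^2)) with A = (2 pi w^2)^(-3/2) (amplitude can be
#' overridden); "uniform_gas": a constant density.
#'
#' @param kind "gaussian_density" or "uniform_gas"
#' @param grid a \linkS4class{GridSpec}
#' @param width Gaussian width w, Bohr (must be positive)
#' @param center 3-vector, Bohr
#' @param amplitude overrides the normalised amplitude if given
#' @param value constant for "uniform_gas"
#' @return \linkS4class{ScalarField} of quantity "rho"
#' @export
analyticDensity <- function(kind = c("gaussian_density", "uniform_gas"),
                            grid, width = 1.0, center = c(0, 0, 0),
                            amplitude = NULL, value = 0.01) {
  kind <- match.arg(kind)
  pts <- gridPoints(grid)
  if (kind == "gaussian_density") {
    if (width <= 0) stop("width must be positive")
    if (is.null(amplitude)) amplitude <- (2 * pi * width^2)^(-3 / 2)
    r2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
      (pts[, 3] - center[3])^2
    vals <- amplitude * exp(-r2 / (2 * width^2))
  } else {
    if (value < 0) stop("density must be nonnegative")
    vals <- rep(value, nrow(pts))
  }
  .asField(vals, grid, "rho")
}

#' Closed-form RDG of the normalised Gaussian density
#'
#' For rho = A exp(-r^2/(2w^2)), |grad rho| = rho * r/w^2, so
#' s = (r/w^2) / (2 (3 pi^2)^(1/3) rho^(1/3)).  Used as the analytic
#' oracle for the NCI machinery.
#'
#' @param r distance from the Gaussian centre, Bohr
#' @param width w, Bohr
#' @param amplitude A
#' @export
gaussianRDG <- function(r, width = 1.0,
                        amplitude = (2 * pi * width^2)^(-3 / 2)) {
  rho <- amplitude * exp(-r^2 / (2 * width^2))
  (rho * r / width^2) / (2 * (3 * pi^2)^(1 / 3) * rho^(4 / 3))
}

# ---------------------------------------------------------------------
# Gaussian cube file I/O
# ---------------------------------------------------------------------

#' Write a scalar field as a Gaussian cube file
#'
#' Standard cube dialect: Bohr units, positive atom count, values with
#' the z index fastest.
#'
#' @param field a \linkS4class{ScalarField}
#' @param mol the molecule the field belongs to
#' @param con file path or connection
#' @export
writeCube <- function(field, mol, con) {
  g <- field@grid
  xyzB <- mol@coords * .const$ang2bohr
  Z <- elementZ(mol@symbols)
  hdr <- c(sprintf("MolDFT cube: %s", field@quantity),
           sprintf("molecule: %s", mol@label),
           sprintf("%5d %11.6f %11.6f %11.6f", nAtoms(mol),
                   g@origin[1], g@origin[2], g@origin[3]),
           sprintf("%5d %11.6f %11.6f %11.6f", g@shape[1],
                   g@axes[1, 1], g@axes[1, 2], g@axes[1, 3]),
           sprintf("%5d %11.6f %11.6f %11.6f", g@shape[2],
                   g@axes[2, 1], g@axes[2, 2], g@axes[2, 3]),
           sprintf("%5d %11.6f %11.6f %11.6f", g@shape[3],
                   g@axes[3, 1], g@axes[3, 2], g@axes[3, 3]),
           sprintf("%5d %11.6f %11.6f %11.6f %11.6f", Z, as.numeric(Z),
                   xyzB[, 1], xyzB[, 2], xyzB[, 3]))
  # cube order: x slowest, z fastest
  v <- aperm(field@values, c(3, 2, 1))  # now [z, y, x]; flatten x-major
  v <- as.numeric(v)                     # z fastest within each (x, y)
  nz <- g@shape[3]
  lines <- character()
  # emit per (x,y) row: nz values, 6 per line
  vm <- matrix(v, nrow = nz)
  rows <- apply(vm, 2, function(col) {
    paste(vapply(split(col, ceiling(seq_along(col) / 6)),
                 function(ch) paste(sprintf("%13.5e", ch), collapse = " "),
                 ""), collapse = "\n")
  })
  writeLines(c(hdr, rows), con)
  invisible(field)
}

#' Read a Gaussian cube file
#'
#' @param con file path or connection
#' @return list(field = ScalarField, molecule = Molecule)
#' @export
readCube <- function(con) {
  lines <- readLines(con)
  if (length(lines) < 7) stop("truncated cube file: missing header")
  p3 <- strsplit(trimws(lines[3]), "[[:space:]]+")[[1]]
  natoms <- as.integer(p3[1])
  hasDset <- natoms < 0   # dataset-id convention uses negative count
  natoms <- abs(natoms)
  origin <- as.numeric(p3[2:4])
  axes <- matrix(0, 3, 3)
  shape <- integer(3)
  for (i in 1:3) {
    p <- strsplit(trimws(lines[3 + i]), "[[:space:]]+")[[1]]
    shape[i] <- as.integer(p[1])
    axes[i, ] <- as.numeric(p[2:4])
  }
  if (any(is.na(shape))) stop("malformed cube header")
  atomLines <- lines[7:(6 + natoms)]
  if (length(atomLines) < natoms || anyNA(atomLines))
    stop("truncated cube file: missing atom block")
  at <- t(vapply(strsplit(trimws(atomLines), "[[:space:]]+"),
                 function(x) as.numeric(x[1:5]), numeric(5)))
  sym <- .elements$symbol[match(as.integer(at[, 1]), .elements$Z)]
  mol <- Molecule(sym, at[, 3:5] * .const$bohr2ang, label = trimws(lines[2]))
  dstart <- 7 + natoms
  if (hasDset) dstart <- dstart + 1  # skip the dataset-id line
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[dstart:length(lines)]), "[[:space:]]+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(shape))
    stop(sprintf("truncated cube file: %d values, expected %d",
                 length(vals), prod(shape)))
  # stored z fastest, x slowest -> our layout x fastest
  arr <- aperm(array(vals, rev(shape)), c(3, 2, 1))
  g <- new("GridSpec", origin = origin, axes = axes, shape = shape)
  list(field = new("ScalarField", grid = g, quantity = "other",
                   values = arr),
       molecule = mol)
}
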