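# Molecule construction: built-in fixture geometries, an internal
# Z-matrix builder, and XYZ file input/output.

# NeRF placement: position atom given bond ref j (distance r), angle
# ref k (angle theta, degrees) and dihedral ref l (phi, degrees).
.zmatPlace <- function(xyz, j, r, k = NA, theta = NA, l = NA, phi = NA) {
  if (is.na(k)) return(xyz[j, ] + c(r, 0, 0))
  th <- theta * pi / 180
  if (is.na(l)) {
    # place in xy-plane
    u <- xyz[j, ] - xyz[k, ]
    u <- u / sqrt(sum(u^2))
    # perpendicular in plane
    m <- c(-u[2], u[1], 0)
    if (sum(m^2) < 1e-12) m <- c(0, 1, 0)
    m <- m / sqrt(sum(m^2))
    return(xyz[j, ] - r * cos(th) * u + r * sin(th) * m)
  }
  ph <- phi * pi / 180
  u <- xyz[j, ] - xyz[k, ]
  u <- u / sqrt(sum(u^2))
  v <- xyz[k, ] - xyz[l, ]
  n <- c(v[2] * u[3] - v[3] * u[2],
         v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("collinear dihedral reference atoms")
  n <- n / nn
  m <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  xyz[j, ] - r * cos(th) * u + r * sin(th) * (cos(ph) * m + sin(ph) * n)
}

# rows: sym, j, r, k, theta, l, phi (NA where unused)
.fromZmat <- function(zm, charge = 0L, multiplicity = 1L, label = "molecule") {
  n <- nrow(zm)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (i == 1) next
    xyz[i, ] <- .zmatPlace(xyz, zm$j[i], zm$r[i],
                           if (i >= 3) zm$k[i] else NA, zm$theta[i],
                           if (i >= 4) zm$l[i] else NA, zm$phi[i])
  }
  Molecule(zm$sym, xyz, charge, multiplicity, label)
}

.zrow <- function(sym, j = NA, r = NA, k = NA, theta = NA, l = NA, phi = NA) {
  data.frame(sym = sym, j = j, r = r, k = k, theta = theta, l = l, phi = phi,
             stringsAsFactors = FALSE)
}

# s-trans backbone of a 1,3-diene: returns zmat rows for C1..C4;
# defaults are typical B3LYP/6-31G(d) equilibrium values
.dieneBackbone <- function(rDouble = 1.3406, rSingle = 1.457,
                           ang = 124.25) {
  rbind(.zrow("C"),
        .zrow("C", 1, rDouble),
        .zrow("C", 2, rSingle, 1, ang),
        .zrow("C", 3, rDouble, 2, ang, 1, 180))
}

.fixtureBuilders <- list(
  h2 = function() {
    Molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)), label = "h2")
  },
  water = function() {
    zm <- rbind(.zrow("O"), .zrow("H", 1, 0.96),
                .zrow("H", 1, 0.96, 2, 104.5))
    .fromZmat(zm, label = "water")
  },
  butadiene_s_trans = function() {
    zm <- rbind(.dieneBackbone(),
      .zrow("H", 1, 1.0880, 2, 121.52, 3, 0),    # cis to C3
      .zrow("H", 1, 1.0858, 2, 121.83, 3, 180),
      .zrow("H", 2, 1.0907, 1, 119.49, 3, 180),
      .zrow("H", 3, 1.0907, 4, 119.49, 2, 180),
      .zrow("H", 4, 1.0880, 3, 121.52, 2, 0),
      .zrow("H", 4, 1.0858, 3, 121.83, 2, 180))
    .fromZmat(zm, label = "butadiene_s_trans")
  },
  dinitrobutadiene_EE = function() .nitroDiene(180, 180, "dinitrobutadiene_EE"),
  dinitrobutadiene_EZ = function() .nitroDiene(180, 0, "dinitrobutadiene_EZ"),
  dinitrobutadiene_ZZ = function() .nitroDiene(0, 0, "dinitrobutadiene_ZZ"),
  tce = function() {
    zm <- rbind(
      .zrow("C"),
      .zrow("C", 1, 1.372),
      .zrow("C", 1, 1.4296, 2, 121.47),
      .zrow("C", 1, 1.4296, 2, 121.47, 3, 180),
      .zrow("C", 2, 1.4296, 1, 121.47, 3, 0),
      .zrow("C", 2, 1.4296, 1, 121.47, 3, 180),
      .zrow("N", 3, 1.1629, 1, 179.03, 2, 180),
      .zrow("N", 4, 1.1629, 1, 179.03, 2, 180),
      .zrow("N", 5, 1.1629, 2, 179.03, 1, 180),
      .zrow("N", 6, 1.1629, 2, 179.03, 1, 180))
    .fromZmat(zm, label = "tce")
  },
  acetic_acid = function() {
    zm <- rbind(
      .zrow("C"),                                # methyl C
      .zrow("C", 1, 1.503),                      # carboxyl C
      .zrow("O", 2, 1.210, 1, 126),              # carbonyl O
      .zrow("O", 2, 1.357, 1, 111.5, 3, 180),    # hydroxyl O
      .zrow("H", 4, 0.972, 2, 106, 3, 0),        # OH, syn
      .zrow("H", 1, 1.090, 2, 109.6, 3, 0),
      .zrow("H", 1, 1.092, 2, 109.6, 3, 121),
      .zrow("H", 1, 1.092, 2, 109.6, 3, -121))
    .fromZmat(zm, label = "acetic_acid")
  },
  diacetoxy_dinitrobutane_RR = function()
    .diacetoxyDinitrobutane(60, -60, "diacetoxy_dinitrobutane_RR"),
  diacetoxy_dinitrobutane_meso = function()
    .diacetoxyDinitrobutane(60, 60, "diacetoxy_dinitrobutane_meso")
)

# 1,4-dinitro-1,3-butadiene; tau1/tau2 are the N-C1-C2-C3 and
# N-C4-C3-C2 dihedrals: 180 = E at that double bond, 0 = Z.
# Parameters at typical B3LYP/6-31G(d) equilibrium values for the
# conjugated nitroalkene fragment.
.nitroDiene <- function(tau1, tau2, label) {
  hd1 <- if (tau1 == 180) 0 else 180   # H completes the sp2 centre
  hd2 <- if (tau2 == 180) 0 else 180
  zm <- rbind(.dieneBackbone(1.3400, 1.4468, 122.07),
    .zrow("N", 1, 1.4565, 2, 120.98, 3, tau1),
    .zrow("H", 1, 1.0822, 2, 126.42, 3, hd1),
    .zrow("H", 2, 1.0867, 1, 118.35, 3, 180),
    .zrow("H", 3, 1.0867, 4, 118.35, 2, 180),
    .zrow("N", 4, 1.4565, 3, 120.98, 2, tau2),
    .zrow("H", 4, 1.0822, 3, 126.42, 2, hd2),
    .zrow("O", 5, 1.2311, 1, 118.86, 2, 0),
    .zrow("O", 5, 1.2317, 1, 115.46, 2, 180),
    .zrow("O", 9, 1.2311, 4, 118.86, 3, 0),
    .zrow("O", 9, 1.2317, 4, 115.46, 3, 180))
  .fromZmat(zm, label = label)
}

# 2,3-diacetoxy-1,4-dinitrobutane.  The two acetoxy dihedrals
# (O-C2-C3-C4 and O-C3-C2-C1) have equal sign for the meso form
# (internal inversion over the anti backbone) and opposite signs for
# the C2-symmetric (R,R) form.
.diacetoxyDinitrobutane <- function(d2, d3, label) {
  zm <- rbind(
    .zrow("C"),                                   # 1  C1 (CH2NO2)
    .zrow("C", 1, 1.530),                         # 2  C2 (CHOAc)
    .zrow("C", 2, 1.540, 1, 111),                 # 3  C3 (CHOAc)
    .zrow("C", 3, 1.530, 2, 111, 1, 180),         # 4  C4 (CH2NO2)
    .zrow("N", 1, 1.500, 2, 112, 3, 180),         # 5
    .zrow("N", 4, 1.500, 3, 112, 2, 180),         # 6
    .zrow("O", 5, 1.220, 1, 117, 2, 0),           # 7
    .zrow("O", 5, 1.220, 1, 117, 2, 180),         # 8
    .zrow("O", 6, 1.220, 4, 117, 3, 0),           # 9
    .zrow("O", 6, 1.220, 4, 117, 3, 180),         # 10
    .zrow("O", 2, 1.430, 3, 108, 4, d2),          # 11 ester O on C2
    .zrow("O", 3, 1.430, 2, 108, 1, d3),          # 12 ester O on C3
    .zrow("C", 11, 1.360, 2, 116, 3, 150),        # 13 carbonyl C
    .zrow("C", 12, 1.360, 3, 116, 2, 150),        # 14 carbonyl C
    .zrow("O", 13, 1.200, 11, 123, 2, 0),         # 15 C=O
    .zrow("O", 14, 1.200, 12, 123, 3, 0),         # 16 C=O
    .zrow("C", 13, 1.495, 11, 111, 15, 180),      # 17 methyl C
    .zrow("C", 14, 1.495, 12, 111, 16, 180),      # 18 methyl C
    .zrow("H", 1, 1.090, 5, 107, 2, 119),         # H on C1
    .zrow("H", 1, 1.090, 5, 107, 2, -119),
    .zrow("H", 4, 1.090, 6, 107, 3, 119),         # H on C4
    .zrow("H", 4, 1.090, 6, 107, 3, -119),
    .zrow("H", 2, 1.092, 3, 109.5, 4, -d2),       # completes C2 tetrahedron
    .zrow("H", 3, 1.092, 2, 109.5, 1, -d3),       # completes C3 tetrahedron
    .zrow("H", 17, 1.090, 13, 110, 11, 180),
    .zrow("H", 17, 1.090, 13, 110, 11, 60),
    .zrow("H", 17, 1.090, 13, 110, 11, -60),
    .zrow("H", 18, 1.090, 14, 110, 12, 180),
    .zrow("H", 18, 1.090, 14, 110, 12, 60),
    .zrow("H", 18, 1.090, 14, 110, 12, -60))
  .fromZmat(zm, label = label)
}

#' Built-in fixture molecules
#'
#' Programmatic construction of every structure the characterisation
#' pipeline needs: the s-trans diene backbone molecules, the diacetoxy
#' ester diastereomers, acetic acid and the tetracyanoethylene
#' nucleophilicity reference, plus small helper molecules (h2, water)
#' used by the test suite.  Geometries are idealised starting structures
#' (standard bond lengths and planar sp2 frames) intended to be refined
#' by \code{\link{optimizeGeometry}}.
#'
#' @param name fixture id; see \code{listFixtures()}
#' @return a \linkS4class{Molecule} with charge 0 and multiplicity 1
#' @examples
#' listFixtures()
#' builtinMolecule("tce")
#' @export
builtinMolecule <- function(name) {
  b <- .fixtureBuilders[[name]]
  if (is.null(b))
    stop("unknown fixture '", name, "'; valid ids: ",
         paste(listFixtures(), collapse = ", "))
  b()
}

#' @rdname builtinMolecule
#' @export
listFixtures <- function() names(.fixtureBuilders)

# ---------------------------------------------------------------------
# XYZ input/output
# ---------------------------------------------------------------------

#' Read a molecule from an XYZ file
#'
#' Standard dialect: atom count line, comment line, then one
#' "symbol x y z" row per atom in Angstrom.
#'
#' @param con file path or connection
#' @param charge,multiplicity electronic state assigned to the result
#' @return a \linkS4class{Molecule}
#' @export
readXYZ <- function(con, charge = 0L, multiplicity = 1L) {
  lines <- readLines(con)
  lines <- lines[seq_len(length(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("first line of XYZ file must be the atom count")
  label <- if (length(lines) >= 2) trimws(lines[2]) else ""
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("XYZ file declares ", n, " atoms but lists ", length(body))
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(vapply(toks, length, 1L) < 4)
  if (length(bad)) stop("unparseable XYZ row: ", body[bad[1]])
  sym <- vapply(toks, `[[`, "", 1)
  xyz <- t(vapply(toks, function(t) {
    v <- suppressWarnings(as.numeric(t[2:4]))
    if (anyNA(v)) stop("unparseable coordinate in row: ",
                       paste(t, collapse = " "))
    v
  }, numeric(3)))
  elementZ(sym)  # errors on unknown elements
  Molecule(sym, xyz, charge, multiplicity,
           label = if (nzchar(label)) label else "xyz")
}

#' Write a molecule to an XYZ file
#'
#' @param mol a \linkS4class{Molecule}
#' @param con file path or connection
#' @param digits coordinate precision (default 8 decimals)
#' @export
writeXYZ <- function(mol, con, digits = 8) {
  fmt <- paste0("%-3s %", digits + 6, ".", digits, "f %",
                digits + 6, ".", digits, "f %", digits + 6, ".", digits, "f")
  lines <- c(as.character(nAtoms(mol)), mol@label,
             sprintf(fmt, mol@symbols, mol@coords[, 1], mol@coords[, 2],
                     mol@coords[, 3]))
  writeLines(lines, con)
  invisible(mol)
}

# replace coordinates (Angstrom), keeping everything else
#' @keywords internal
setCoords <- function(mol, xyz) {
  mol@coords <- xyz
  mol
}
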