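# Basis-set handling: parsing the plain-text tables shipped with the
# package and constructing normalised contracted Cartesian shells.

.pkgenv <- new.env(parent = emptyenv())

.basisFile <- function(name) {
  fname <- switch(name,
    "sto-3g" = "sto-3g.dat",
    "6-31g(d)" = "6-31gd.dat",
    stop("unknown basis set: ", name))
  system.file("extdata", "basis", fname, package = "MolDFT", mustWork = TRUE)
}

# parse into list: elem -> list of shells, each list(type, mat)
.parseBasis <- function(name) {
  key <- paste0("basis:", name)
  if (!is.null(.pkgenv[[key]])) return(.pkgenv[[key]])
  lines <- readLines(.basisFile(name))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    stopifnot(startsWith(lines[i], "elem "))
    elem <- sub("^elem +", "", lines[i])
    i <- i + 1
    shells <- list()
    while (lines[i] != "end") {
      type <- lines[i]
      i <- i + 1
      rows <- list()
      while (i <= length(lines) && grepl("^[-0-9.]", lines[i])) {
        rows[[length(rows) + 1]] <-
          as.numeric(strsplit(lines[i], "[[:space:]]+")[[1]])
        i <- i + 1
      }
      shells[[length(shells) + 1]] <-
        list(type = type, mat = do.call(rbind, rows))
    }
    i <- i + 1
    out[[elem]] <- shells
  }
  .pkgenv[[key]] <- out
  out
}

.dfact <- function(n) if (n <= 1) 1 else prod(seq(2 * n - 1, 1, by = -2))

# normalised shell for angular momentum l from exponents/coefficients
.makeShell <- function(l, atom, center, alpha, coef) {
  nprim <- (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) / sqrt(.dfact(l))
  cc <- coef * nprim
  p <- outer(alpha, alpha, "+")
  sself <- sum(outer(cc, cc) * (pi / p)^1.5 * .dfact(l) / (2 * p)^l)
  cc <- cc / sqrt(sself)
  comps <- .cartComponents(l)
  scale <- apply(comps, 1, function(ijk)
    sqrt(.dfact(l) / prod(vapply(ijk, .dfact, 1))))
  list(l = as.integer(l), atom = as.integer(atom),
       center = as.numeric(center), alpha = as.numeric(alpha),
       coef = as.numeric(cc), scale = as.numeric(scale))
}

.cartComponents <- function(l) {
  out <- NULL
  for (i in seq(l, 0)) for (j in seq(l - i, 0))
    out <- rbind(out, c(i, j, l - i - j))
  out
}

#' Build the contracted-Gaussian shell list for a molecule
#'
#' Coordinates are converted to Bohr at this boundary; everything the
#' integral engine sees is in atomic units.
#'
#' @param mol a \linkS4class{Molecule}
#' @param basis basis name ("6-31g(d)" or "sto-3g")
#' @return list of shells (internal layout) with attribute "nbf"
#' @keywords internal
buildShells <- function(mol, basis) {
  tab <- .parseBasis(basis)
  xyz <- mol@coords * .const$ang2bohr
  shells <- list()
  for (a in seq_along(mol@symbols)) {
    sym <- mol@symbols[a]
    bs <- tab[[sym]]
    if (is.null(bs))
      stop("basis ", basis, " has no entry for element ", sym)
    for (s in bs) {
      m <- s$mat
      if (s$type == "S") {
        shells[[length(shells) + 1]] <- .makeShell(0, a, xyz[a, ], m[, 1], m[, 2])
      } else if (s$type == "P") {
        shells[[length(shells) + 1]] <- .makeShell(1, a, xyz[a, ], m[, 1], m[, 2])
      } else if (s$type == "SP") {
        shells[[length(shells) + 1]] <- .makeShell(0, a, xyz[a, ], m[, 1], m[, 2])
        shells[[length(shells) + 1]] <- .makeShell(1, a, xyz[a, ], m[, 1], m[, 3])
      } else if (s$type == "D") {
        shells[[length(shells) + 1]] <- .makeShell(2, a, xyz[a, ], m[, 1], m[, 2])
      } else stop("unknown shell type ", s$type)
    }
  }
  nbf <- sum(vapply(shells, function(s) (s$l + 1) * (s$l + 2) / 2, 1))
  attr(shells, "nbf") <- as.integer(nbf)
  shells
}

#' @keywords internal
nbfOf <- function(shells) attr(shells, "nbf")

# atom index per basis function
#' @keywords internal
bfAtoms <- function(shells) {
  unlist(lapply(shells, function(s)
    rep(s$atom, (s$l + 1) * (s$l + 2) / 2)))
}
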