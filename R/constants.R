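# Physical constants and element data used throughout the package.

#' @keywords internal
.const <- list(
  bohr2ang   = 0.529177210903,
  ang2bohr   = 1.8897259886,
  hartree2ev = 27.211386,
  hartree2kcal = 627.5095,
  hartree2cm = 219474.6313632,
  amu2au     = 1822.888486209,
  kB_hartree = 3.166811563e-6,   # Boltzmann constant, Hartree/K
  R_kcal     = 1.987204259e-3    # gas constant, kcal/(mol K)
)

# Z, standard atomic weight (amu), covalent radius (Angstrom),
# Bragg-Slater radius (Angstrom) for the elements the engine supports
# plus a few common ones for parsing.
.elements <- data.frame(
  symbol = c("H", "He", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br"),
  Z      = c(1L, 2L, 5L, 6L, 7L, 8L, 9L, 15L, 16L, 17L, 35L),
  mass   = c(1.00794, 4.0026, 10.811, 12.011, 14.007, 15.999, 18.998,
             30.974, 32.06, 35.45, 79.904),
  rcov   = c(0.31, 0.28, 0.84, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02,
             1.20),
  bragg  = c(0.35, 0.31, 0.85, 0.70, 0.65, 0.60, 0.50, 1.00, 1.00, 1.00,
             1.15),
  stringsAsFactors = FALSE
)

#' @keywords internal
elementZ <- function(symbols) {
  idx <- match(symbols, .elements$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  .elements$Z[idx]
}

#' @keywords internal
elementMass <- function(symbols) .elements$mass[match(symbols, .elements$symbol)]

#' @keywords internal
elementRcov <- function(symbols) .elements$rcov[match(symbols, .elements$symbol)]

#' @keywords internal
elementBragg <- function(symbols) .elements$bragg[match(symbols, .elements$symbol)]
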