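# Generics and accessors.  Slot access from user code goes through
# these functions.

#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @describeIn Molecule-class number of atoms
#' @param x object
#' @export
setMethod("nAtoms", "Molecule", function(x) length(x@symbols))

#' @export
setGeneric("symbols", function(x) standardGeneric("symbols"))
#' @describeIn Molecule-class element symbols
#' @export
setMethod("symbols", "Molecule", function(x) x@symbols)

#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @describeIn Molecule-class coordinates, Angstrom
#' @export
setMethod("coords", "Molecule", function(x) x@coords)

#' @export
setGeneric("charge", function(x) standardGeneric("charge"))
#' @describeIn Molecule-class total charge
#' @export
setMethod("charge", "Molecule", function(x) x@charge)

#' @export
setGeneric("multiplicity", function(x) standardGeneric("multiplicity"))
#' @describeIn Molecule-class spin multiplicity
#' @export
setMethod("multiplicity", "Molecule", function(x) x@multiplicity)

#' Total number of electrons
#' @param x a Molecule
#' @export
countElectrons <- function(x) {
  stopifnot(is(x, "Molecule"))
  sum(elementZ(x@symbols)) - x@charge
}

#' @export
setGeneric("energy", function(x) standardGeneric("energy"))
#' @describeIn SCFResult-class total energy, Hartree
#' @param x object
#' @export
setMethod("energy", "SCFResult", function(x) x@energy)
#' @describeIn ThermoRecord-class electronic energy, Hartree
#' @export
setMethod("energy", "ThermoRecord", function(x) x@eElec)

#' Frontier orbital energies in eV
#'
#' HOMO is the highest occupied orbital energy and LUMO the lowest
#' unoccupied one (alpha channel for open shells), converted with
#' 1 Hartree = 27.211386 eV.
#'
#' @param x an \linkS4class{SCFResult}
#' @return energy in eV
#' @export
homoEnergy <- function(x) {
  stopifnot(is(x, "SCFResult"))
  occ <- which(x@occA > 0)
  x@epsA[max(occ)] * .const$hartree2ev
}

#' @rdname homoEnergy
#' @export
lumoEnergy <- function(x) {
  stopifnot(is(x, "SCFResult"))
  virt <- which(x@occA == 0)
  x@epsA[min(virt)] * .const$hartree2ev
}

#' Orbital energies (Hartree) per spin channel
#' @param x an SCFResult
#' @param spin "alpha" or "beta"
#' @export
orbitalEnergies <- function(x, spin = c("alpha", "beta")) {
  spin <- match.arg(spin)
  if (spin == "alpha") x@epsA else x@epsB
}

#' Density matrices of an SCF result
#'
#' @param x an SCFResult
#' @param which "total", "alpha", "beta" or "spin" (alpha - beta)
#' @return a square matrix in the AO basis
#' @export
densityMatrix <- function(x, which = c("total", "alpha", "beta", "spin")) {
  which <- match.arg(which)
  Da <- x@coefA[, x@occA > 0, drop = FALSE] %*% t(x@coefA[, x@occA > 0, drop = FALSE])
  Db <- x@coefB[, x@occB > 0, drop = FALSE] %*% t(x@coefB[, x@occB > 0, drop = FALSE])
  switch(which, total = Da + Db, alpha = Da, beta = Db, spin = Da - Db)
}

#' @export
setGeneric("basins", function(x) standardGeneric("basins"))
#' @describeIn BasinSet-class the per-basin table
#' @param x object
#' @export
setMethod("basins", "BasinSet", function(x) x@basins)

#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @describeIn ScalarField-class the value array
#' @param x object
#' @export
setMethod("fieldValues", "ScalarField", function(x) x@values)

#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))
#' @describeIn ScalarField-class the grid
#' @param x object
#' @export
setMethod("gridSpec", "ScalarField", function(x) x@grid)

#' Voxel volume of a grid (Bohr^3)
#' @param g a GridSpec
#' @export
voxelVolume <- function(g) abs(det(g@axes))

#' Grid point coordinates (Bohr), fastest index first
#' @param g a GridSpec
#' @return matrix (prod(shape) x 3)
#' @export
gridPoints <- function(g) {
  ii <- expand.grid(i = seq_len(g@shape[1]) - 1L,
                    j = seq_len(g@shape[2]) - 1L,
                    k = seq_len(g@shape[3]) - 1L)
  pts <- as.matrix(ii) %*% g@axes
  sweep(pts, 2, g@origin, "+")
}
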