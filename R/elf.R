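# ELF topological analysis: watershed partition of the grid into
# basins of ELF attractors, synapticity classification and electron
# population integration.

#' Partition space into ELF basins and integrate their populations
#'
#' Every grid voxel (above a density floor) is assigned to an ELF local
#' maximum by near-grid steepest ascent (26-neighbour watershed).
#' Attractors closer than \code{mergeDist} with ELF values within
#' \code{mergeElf} are merged (grid noise splits flat attractors).
#' Populations are integrated from the electron density; the partition
#' is exhaustive and disjoint, so the summed populations equal the grid
#' density integral of the assigned region exactly.
#'
#' @param elf \linkS4class{ScalarField} of quantity "elf"
#' @param rho \linkS4class{ScalarField} of quantity "rho" on one grid
#' @param mol the molecule (for core/valence classification)
#' @param rhoMin voxels below this density stay unassigned
#' @param mergeDist attractor merge radius, Bohr
#' @param mergeElf maximum ELF difference for merging
#' @param basinSep adjacent basins separated by an ELF valley
#'   shallower than this are merged (plateau fragments; V/V' splits)
#' @param minPopulation basins below this electron count are dropped
#'   (vacuum-tail artefacts)
#' @param coreRadius attractor-to-nucleus distance defining core
#'   basins, Bohr
#' @return a \linkS4class{BasinSet}
#' @export
partitionBasins <- function(elf, rho, mol, rhoMin = 1e-8,
                            mergeDist = 0.5, mergeElf = 0.02,
                            basinSep = 0.002, minPopulation = 5e-3,
                            coreRadius = 0.7) {
  g <- elf@grid
  if (!isTRUE(all.equal(g@shape, rho@grid@shape)) ||
      max(abs(g@origin - rho@grid@origin)) > 1e-10)
    stop("elf and rho fields must share one grid")
  lab <- .cpp_watershed(as.numeric(elf@values), as.numeric(rho@values),
                        g@shape, rhoMin)
  dV <- voxelVolume(g)
  vox2xyz <- function(ix) {
    ix0 <- ix - 1L
    i <- ix0 %% g@shape[1]
    j <- (ix0 %/% g@shape[1]) %% g@shape[2]
    k <- ix0 %/% (g@shape[1] * g@shape[2])
    cbind(i, j, k) %*% g@axes + matrix(g@origin, length(ix), 3, byrow = TRUE)
  }
  att <- sort(unique(lab[lab > 0]))
  attPos <- vox2xyz(att)
  attVal <- elf@values[att]
  nA <- length(att)
  # provisional labels 1..nA per voxel
  labmap0 <- integer(max(att))
  labmap0[att] <- seq_len(nA)
  vlab0 <- ifelse(lab > 0, labmap0[pmax(lab, 1L)], 0L)
  # saddle heights between adjacent provisional basins
  arr <- array(vlab0, g@shape)
  ev <- elf@values
  pairKey <- character(0); pairVal <- numeric(0)
  collect <- function(aIdx, bIdx) {
    la <- arr[aIdx]; lb <- arr[bIdx]
    sel <- la > 0 & lb > 0 & la != lb
    if (!any(sel)) return()
    va <- pmin(ev[aIdx][sel], ev[bIdx][sel])
    k <- paste(pmin(la[sel], lb[sel]), pmax(la[sel], lb[sel]))
    agg <- tapply(va, k, max)
    pairKey <<- c(pairKey, names(agg))
    pairVal <<- c(pairVal, as.numeric(agg))
  }
  nx <- g@shape[1]; ny <- g@shape[2]; nz <- g@shape[3]
  idxArr <- array(seq_along(vlab0), g@shape)
  collect(idxArr[-nx, , ], idxArr[-1, , ])
  collect(idxArr[, -ny, ], idxArr[, -1, ])
  collect(idxArr[, , -nz], idxArr[, , -1])
  saddle <- tapply(pairVal, pairKey, max)
  # union-find merge: (a) attractors close in space and ELF value
  # (grid noise splitting flat maxima), (b) adjacent basins whose
  # dividing valley is shallower than basinSep (plateau fragments and
  # the grid-sensitive V/V\' sub-basin splittings)
  parent <- seq_len(nA)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    pi_ <- findp(i); pj <- findp(j)
    if (pi_ != pj) parent[max(pi_, pj)] <<- min(pi_, pj)
  }
  for (i in seq_len(nA)) for (j in seq_len(i - 1)) {
    if (sqrt(sum((attPos[i, ] - attPos[j, ])^2)) < mergeDist &&
        abs(attVal[i] - attVal[j]) < mergeElf) unite(i, j)
  }
  if (length(saddle)) {
    pk <- strsplit(names(saddle), " ")
    for (q in seq_along(saddle)) {
      i <- as.integer(pk[[q]][1]); j <- as.integer(pk[[q]][2])
      depth <- min(attVal[i], attVal[j]) - saddle[[q]]
      if (depth < basinSep) unite(i, j)
    }
  }
  group <- vapply(seq_len(nA), findp, 1L)
  groups <- unique(group)
  gid <- match(group, groups)
  labmap <- integer(max(att))
  labmap[att] <- gid
  vlab <- ifelse(lab > 0, labmap[pmax(lab, 1L)], 0L)
  nb <- length(groups)
  pop <- vapply(seq_len(nb), function(k)
    sum(rho@values[vlab == k]) * dV, 0)
  rep_ <- vapply(seq_len(nb), function(k) {
    cand <- which(gid == k)
    cand[which.max(attVal[cand])]
  }, 1L)
  pos <- attPos[rep_, , drop = FALSE]
  val <- attVal[rep_]
  # drop dust basins (vacuum-tail artefacts with negligible charge)
  keep <- pop >= minPopulation
  relab <- integer(nb)
  relab[keep] <- seq_len(sum(keep))
  vlab <- ifelse(vlab > 0 & keep[pmax(vlab, 1L)], relab[pmax(vlab, 1L)], 0L)
  pop <- pop[keep]; pos <- pos[keep, , drop = FALSE]; val <- val[keep]
  nb <- sum(keep)
  # refine populations with fractional boundary weights (Yu-Trinkle
  # flux partitioning): removes the O(h) bias of whole-voxel assignment
  if (nb > 0)
    pop <- as.numeric(.cpp_yt_populations(as.numeric(elf@values),
                                          as.numeric(rho@values),
                                          g@shape, vlab, nb, dV))
  # classification
  xyzB <- mol@coords * .const$ang2bohr
  Z <- elementZ(mol@symbols)
  kind <- character(nb); coreAtom <- integer(nb)
  for (k in seq_len(nb)) {
    d <- sqrt(colSums((t(xyzB) - pos[k, ])^2))
    a <- which.min(d)
    if (d[a] < coreRadius && Z[a] > 2) {
      kind[k] <- "core"; coreAtom[k] <- a
    } else {
      kind[k] <- "valence"; coreAtom[k] <- NA_integer_
    }
  }
  syn <- .synapticity(vlab, g, mol, kind, coreAtom, rhoMin)
  basins <- data.frame(
    x = pos[, 1], y = pos[, 2], z = pos[, 3], elf = val, kind = kind,
    label = syn$label, atoms = I(syn$atoms), population = pop,
    stringsAsFactors = FALSE)
  new("BasinSet", basins = basins, totalPopulation = sum(pop),
      gridProvenance = g)
}

# determine synaptic order of valence basins from adjacency to core
# basins and from hydrogen nuclei contained in the basin
.synapticity <- function(vlab, g, mol, kind, coreAtom, rhoMin) {
  nb <- max(vlab)
  shape <- g@shape
  arr <- array(vlab, shape)
  adj <- matrix(FALSE, nb, nb)
  markAdj <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      pr <- unique(cbind(a[sel], b[sel]))
      adj[pr] <<- TRUE
      adj[pr[, 2:1, drop = FALSE]] <<- TRUE
    }
  }
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  markAdj(arr[-nx, , ], arr[-1, , ])
  markAdj(arr[, -ny, ], arr[, -1, ])
  markAdj(arr[, , -nz], arr[, , -1])
  xyzB <- mol@coords * .const$ang2bohr
  Z <- elementZ(mol@symbols)
  # basin containing each nucleus
  inv <- solve(g@axes)
  nucLab <- integer(nAtoms(mol))
  for (a in seq_len(nAtoms(mol))) {
    ijk <- round((xyzB[a, ] - g@origin) %*% inv)
    ijk <- pmin(pmax(ijk, 0), shape - 1)
    nucLab[a] <- arr[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1]
  }
  label <- character(nb)
  atoms <- vector("list", nb)
  for (k in seq_len(nb)) {
    if (kind[k] == "core") {
      label[k] <- sprintf("C(%s%d)", mol@symbols[coreAtom[k]], coreAtom[k])
      atoms[[k]] <- coreAtom[k]
      next
    }
    core_nbrs <- which(adj[k, ] & kind == "core")
    ats <- coreAtom[core_nbrs]
    # protonated basins: hydrogens whose nucleus lies in this basin
    hyd <- which(Z == 1 & nucLab == k)
    ats <- sort(unique(c(ats, hyd)))
    atoms[[k]] <- ats
    if (length(ats) == 0) {
      label[k] <- "V(?)"
    } else {
      label[k] <- sprintf("V(%s)", paste0(mol@symbols[ats], ats,
                                          collapse = ","))
    }
  }
  list(label = label, atoms = atoms)
}

#' Summed population of the disynaptic basins between two atoms
#'
#' Sums all valence basins whose synaptic atom set is exactly
#' \{a, b\} (the V + V' convention for multiple bonds).
#'
#' @param basinSet a \linkS4class{BasinSet}
#' @param a,b 1-based atom indices
#' @return electrons; 0 with a warning when no such basin exists
#' @export
bondPopulation <- function(basinSet, a, b) {
  b_ <- basinSet@basins
  sel <- vapply(seq_len(nrow(b_)), function(i) {
    b_$kind[i] == "valence" && length(b_$atoms[[i]]) == 2 &&
      setequal(b_$atoms[[i]], c(a, b))
  }, TRUE)
  if (!any(sel)) {
    warning(sprintf("no disynaptic basin between atoms %d and %d", a, b))
    return(0)
  }
  sum(b_$population[sel])
}

#' Synaptic order of each basin (number of connected atomic centres)
#' @param basinSet a BasinSet
#' @export
synapticOrders <- function(basinSet) {
  vapply(basinSet@basins$atoms, length, 1L)
}

#' One-pass ELF basin analysis
#'
#' Evaluates density, density gradient and kinetic density on the grid
#' in a single sweep, forms the ELF, and partitions basins — avoiding
#' the duplicate grid evaluation of calling \code{densityField} and
#' \code{elfField} separately.
#'
#' @param scf converged \linkS4class{SCFResult}
#' @param grid a \linkS4class{GridSpec}
#' @param ... forwarded to \code{\link{partitionBasins}}
#' @return list(rho, elf (ScalarFields), basins (a BasinSet))
#' @export
elfBasinAnalysis <- function(scf, grid, ...) {
  if (!scf@converged) stop("SCF result is not converged")
  ev <- .evalOnGrid(scf, grid, c("grad2", "tau"))
  rho <- .asField(pmax(ev$rho, 0), grid, "rho")
  elf <- .asField(elfKernel(ev$rho, ev$grad2, ev$tau), grid, "elf")
  list(rho = rho, elf = elf,
       basins = partitionBasins(elf, rho, scf@molecule, ...))
}
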