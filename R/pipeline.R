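# Orchestration: run the full characterisation for a fixture or user
# structure, with per-stage error capture, session caching and a
# JSON-serialisable report.

#' Pipeline configuration
#'
#' Defaults reproduce the study settings: B3LYP/6-31G(d), gas phase,
#' 298.15 K.  Field grids default to 0.1 Bohr spacing with 4 Bohr
#' padding (0.2 Bohr in the fast profile); the MEP uses a coarser grid
#' since its per-point cost is much higher.
#'
#' @param functional,basis level of theory
#' @param optPreset optimiser convergence preset
#' @param gridPreset XC quadrature preset
#' @param fieldSpacing grid step for ELF/NCI fields, Bohr
#' @param fieldPadding grid margin, Bohr
#' @param mepSpacing grid step for the MEP, Bohr
#' @param stages which analysis stages to run
#' @param cache reuse cached SCF/optimisation results in this session
#' @return a list of settings (class "PipelineConfig")
#' @export
pipelineConfig <- function(functional = "b3lyp", basis = "6-31g(d)",
                           optPreset = "default", gridPreset = "default",
                           fieldSpacing = 0.1, fieldPadding = 4.0,
                           mepSpacing = 0.4,
                           stages = c("optimize", "cdft", "elf", "nci",
                                      "mep", "druglike"),
                           cache = TRUE) {
  cfg <- list(functional = functional, basis = basis,
              optPreset = optPreset, gridPreset = gridPreset,
              fieldSpacing = fieldSpacing, fieldPadding = fieldPadding,
              mepSpacing = mepSpacing, stages = stages, cache = cache)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

# tiny FNV-style hash for cache keys (no external digest dependency);
# arithmetic kept below 2^31 so bitwXor never leaves integer range
.hashKey <- function(...) {
  raw <- serialize(list(...), NULL)
  h <- 84696351L
  idx <- seq(1, length(raw), by = max(1, length(raw) %/% 2048))
  for (b in as.integer(raw[idx])) {
    h <- bitwXor(h, b)
    h <- as.integer((as.double(h) * 16777619) %% 2147483647)
  }
  sprintf("%08x-%d", h, length(raw))
}

#' Cached geometry optimisation
#'
#' Wraps \code{\link{optimizeGeometry}} with a session cache keyed on
#' geometry, level and preset.
#'
#' @inheritParams optimizeGeometry
#' @param cache logical
#' @export
cachedOptimize <- function(mol, level, preset = "default",
                           gridPreset = "default", cache = TRUE) {
  key <- paste("opt", .hashKey(round(mol@coords, 9), mol@symbols,
                               mol@charge, mol@multiplicity,
                               level@functional, level@basis, preset,
                               gridPreset))
  if (cache && !is.null(.pkgenv[[key]])) return(.pkgenv[[key]])
  res <- optimizeGeometry(mol, level, preset = preset,
                          gridPreset = gridPreset)
  if (cache) .pkgenv[[key]] <- res
  res
}

#' Run the characterisation pipeline
#'
#' Optimises the structure and runs the requested stages (conceptual
#' DFT indices with Parr functions, ELF basin analysis, NCI, MEP,
#' drug-likeness).  Stage failures are caught and reported per stage;
#' the pipeline continues.
#'
#' @param target fixture id (see \code{\link{listFixtures}}), an XYZ
#'   file path, or a \linkS4class{Molecule}
#' @param config from \code{\link{pipelineConfig}}
#' @return a report list (class "PipelineReport") with one entry per
#'   completed stage plus provenance
#' @export
runPipeline <- function(target, config = pipelineConfig()) {
  mol <- if (is(target, "Molecule")) target
         else if (is.character(target) && file.exists(target)) readXYZ(target)
         else if (is.character(target) && target %in% listFixtures())
           builtinMolecule(target)
         else stop("target must be a Molecule, fixture id or XYZ path")
  level <- LevelOfTheory(config$functional, config$basis)
  report <- list(provenance = list(
    package = "MolDFT",
    version = as.character(utils::packageVersion("MolDFT")),
    molecule = mol@label,
    functional = config$functional, basis = config$basis,
    nAtoms = nAtoms(mol), stages = config$stages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  failed <- character()
  runStage <- function(name, fun) {
    if (!name %in% config$stages) return()
    report[[name]] <<- tryCatch(fun(), error = function(e) {
      failed <<- c(failed, name)
      list(error = conditionMessage(e))
    })
  }
  opt <- NULL
  scf <- NULL
  if ("optimize" %in% config$stages) {
    opt <- cachedOptimize(mol, level, config$optPreset, config$gridPreset,
                          config$cache)
    mol <- opt$molecule
    scf <- opt$scf
    report$optimize <- list(
      energy_hartree = energy(scf), cycles = opt$cycles,
      converged = opt$converged, gmax = opt$gmax,
      coordinates_angstrom = unname(mol@coords), symbols = mol@symbols)
  } else {
    scf <- singlePoint(mol, level, gridPreset = config$gridPreset)
  }
  runStage("cdft", function() {
    ref <- tceReference(level, config$optPreset, config$gridPreset)
    g <- globalIndices(scf, ref)
    p <- parrFunctions(mol, level, config$gridPreset)
    l <- localIndices(g, p)
    ch <- atomicCharges(scf, "mulliken")
    list(global = list(
           homo_eV = g@eHomo, lumo_eV = g@eLumo, gap_eV = g@gap,
           mu_eV = g@mu, eta_eV = g@eta, softness_inv_eV = g@softness,
           electronegativity_eV = g@electronegativity,
           omega_eV = g@omega, nucleophilicity_eV = g@nucleophilicity,
           tce_homo_reference_eV = ref),
         parr = list(atoms = p@atoms, p_plus = unname(p@pPlus),
                     p_minus = unname(p@pMinus)),
         local = list(omega_k_eV = unname(l@omegaK),
                      n_k_eV = unname(l@nK)),
         mulliken_charges = ch@charges)
  })
  runStage("elf", function() {
    grid <- makeGrid(mol, config$fieldSpacing, config$fieldPadding)
    ana <- elfBasinAnalysis(scf, grid)
    bs <- ana$basins
    b <- bs@basins
    list(total_population = bs@totalPopulation,
         density_integral = fieldIntegral(ana$rho),
         basins = lapply(seq_len(nrow(b)), function(i) list(
           label = b$label[i], kind = b$kind[i],
           population = b$population[i], elf = b$elf[i],
           position_bohr = c(b$x[i], b$y[i], b$z[i]))))
  })
  runStage("nci", function() {
    grid <- makeGrid(mol, max(config$fieldSpacing, 0.15),
                     config$fieldPadding)
    nci <- nciFields(scf, grid)
    inter <- nci$interactions
    list(n_scatter = length(nci$scatter@s),
         n_interaction_points = nrow(inter),
         signed_rho_range = if (nrow(inter)) range(inter$signedRho)
                            else c(NA_real_, NA_real_),
         attractive_points = sum(inter$signedRho < -0.01),
         repulsive_points = sum(inter$signedRho > 0.01))
  })
  runStage("mep", function() {
    grid <- makeGrid(mol, config$mepSpacing, config$fieldPadding)
    mep <- mepField(scf, grid)
    v <- mep@values
    list(v_min_au = min(v, na.rm = TRUE), v_max_au = max(v, na.rm = TRUE))
  })
  runStage("druglike", function() druglikeReport(mol))
  report$failed <- failed
  class(report) <- c("PipelineReport", "list")
  report
}

#' Serialise a pipeline report to JSON (lossless numeric precision)
#' @param report a PipelineReport
#' @param path output file
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Read a pipeline report back
#' @param path JSON file
#' @export
readReport <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(r) <- c("PipelineReport", "list")
  r
}
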