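# Drug-likeness rule engine: physicochemical descriptors (computed
# through OpenBabel via ChemmineOB), the five classic filter rule sets
# (Lipinski, Ghose, Veber, Egan, Muegge), structural alerts, a small
# PAINS screen and the bioavailability radar axes.

# convert input (SMILES string or Molecule) to an OpenBabel molecule
# handle plus a canonical SMILES
.obParse <- function(x) {
  if (is(x, "Molecule")) {
    if (nAtoms(x) == 0) stop("empty molecule")
    tmp <- tempfile(fileext = ".xyz")
    on.exit(unlink(tmp))
    writeXYZ(x, tmp)
    txt <- paste(c(readLines(tmp), ""), collapse = "\n")
    smi <- ChemmineOB::convertFormat("XYZ", "SMI", txt)
    smi <- strsplit(trimws(smi), "[[:space:]]+")[[1]][1]
    if (is.na(smi) || !nzchar(smi)) stop("bond perception from 3D failed")
  } else if (is.character(x) && length(x) == 1) {
    if (!nzchar(trimws(x))) stop("empty structure input")
    smi <- x
  } else stop("input must be a SMILES string or a Molecule")
  mols <- ChemmineOB::forEachMol("SMILES", smi, identity)
  if (length(mols) == 0) stop("unparseable structure input")
  list(ob = mols, smiles = smi)
}

.smartsCount <- function(ob, smarts) {
  # smartsSearch_OB expects the list of molecule handles
  res <- ChemmineOB::smartsSearch_OB(ob, smarts)
  as.numeric(res)
}

# atom counts from a molecular formula string like "C4H4N2O4"
.formulaCounts <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  out <- integer()
  for (t in toks) {
    sym <- gsub("[0-9]", "", t)
    n <- suppressWarnings(as.integer(gsub("[^0-9]", "", t)))
    if (is.na(n)) n <- 1L
    out[sym] <- (if (is.na(out[sym])) 0L else out[sym]) + n
  }
  out
}

#' Physicochemical descriptor panel
#'
#' Computes the descriptor set used by the drug-likeness filters:
#' molecular weight, atom counts, fraction of sp3 carbons, rotatable
#' bonds, Lipinski H-bond acceptors (N+O) and donors (NH+OH), Ertl
#' topological polar surface area, Wildman-Crippen molar refractivity
#' and logP (the OpenBabel implementations), ring count, and an
#' ESOL-type water solubility estimate (Delaney regression).  The logP
#' estimator name is recorded in the output.
#'
#' @param x a SMILES string or a \linkS4class{Molecule} (bonds are
#'   perceived from the 3D structure)
#' @return a named list of descriptors (class "DescriptorSet")
#' @examples
#' d <- computeDescriptors("C(=C[N+](=O)[O-])C=C[N+](=O)[O-]")
#' d$mw; d$tpsa
#' @export
computeDescriptors <- function(x) {
  p <- .obParse(x)
  props <- ChemmineOB::prop_OB(p$ob[[1]])
  fc <- .formulaCounts(props$formula)
  cnt <- function(sym) if (is.na(fc[sym])) 0L else unname(fc[sym])
  nC <- cnt("C"); nH <- cnt("H"); nN <- cnt("N"); nO <- cnt("O")
  nTot <- sum(fc, na.rm = TRUE)
  nHeavy <- nTot - nH
  # rotatable bonds: non-ring single bonds between non-terminal heavy
  # atoms, excluding triple-bond-adjacent; amide C-N excluded per the
  # usual definition
  nRot <- .smartsCount(p$ob,
    "[!$(*#*)&!D1&!$(C(F)(F)F)&!$(C(Cl)(Cl)Cl)&!$(C(Br)(Br)Br)&!$(C([CH3])([CH3])[CH3])]-!@[!$(*#*)&!D1&!$(C(F)(F)F)&!$(C(Cl)(Cl)Cl)&!$(C(Br)(Br)Br)&!$(C([CH3])([CH3])[CH3])]")
  nCsp3 <- .smartsCount(p$ob, "[CX4]")
  nHBD <- .smartsCount(p$ob, "[#7,#8;!H0]")
  # ring count: cyclomatic number from an SDF rendering
  sdf <- ChemmineOB::convertFormat("SMILES", "SDF", paste0(p$smiles, "\n"))
  cl <- strsplit(sdf, "\n")[[1]]
  counts <- cl[4]
  nAtomsSdf <- as.integer(substr(counts, 1, 3))
  nBondsSdf <- as.integer(substr(counts, 4, 6))
  nRings <- max(0L, nBondsSdf - nAtomsSdf + 1L)
  nHet <- nHeavy - nC
  logp <- props$logP
  esol <- 0.16 - 0.63 * logp - 0.0062 * props$MW + 0.066 * nRot -
    0.74 * .smartsCount(p$ob, "[a]") / max(nHeavy, 1)
  out <- list(
    smiles = p$smiles,
    formula = props$formula,
    mw = props$MW,
    nAtomsTotal = as.integer(nTot),
    nHeavy = as.integer(nHeavy),
    nCarbon = as.integer(nC),
    nHetero = as.integer(nHet),
    fracCsp3 = if (nC > 0) nCsp3 / nC else 0,
    nRotBonds = as.integer(nRot),
    nHBA = as.integer(nN + nO),
    nHBD = as.integer(nHBD),
    tpsa = props$TPSA,
    molarRefractivity = props$MR,
    logp = logp,
    logpEstimator = "Wildman-Crippen atom contributions (OpenBabel logP)",
    esolLogS = esol,
    nRings = as.integer(nRings))
  class(out) <- c("DescriptorSet", "list")
  out
}

# one filter verdict
.verdict <- function(rule, violations, maxViolations = 0) {
  list(rule = rule, passed = length(violations) <= maxViolations,
       violations = violations)
}

.chk <- function(cond, msg) if (cond) character() else msg

#' Apply the five drug-likeness filters
#'
#' Rule thresholds follow the original publications; every comparison
#' is inclusive at the bound.  Lipinski passes with at most one
#' violation (the original rule-of-five convention); the other filters
#' require all conditions.
#'
#' @param d a descriptor set from \code{\link{computeDescriptors}}
#' @return named list of verdicts, each list(rule, passed, violations)
#' @export
applyFilters <- function(d) {
  need <- c("mw", "logp", "nHBA", "nHBD", "tpsa", "nRotBonds",
            "molarRefractivity", "nAtomsTotal", "nCarbon", "nHetero",
            "nRings")
  miss <- need[!need %in% names(d) | vapply(d[need], function(v)
    is.null(v) || is.na(v), TRUE)]
  if (length(miss)) stop("missing descriptor(s): ",
                         paste(miss, collapse = ", "))
  v <- list()
  v$lipinski <- .verdict("lipinski", c(
    .chk(d$mw <= 500, sprintf("MW %.2f > 500", d$mw)),
    .chk(d$logp <= 5, sprintf("logP %.2f > 5", d$logp)),
    .chk(d$nHBD <= 5, sprintf("HBD %d > 5", d$nHBD)),
    .chk(d$nHBA <= 10, sprintf("HBA %d > 10", d$nHBA))),
    maxViolations = 1)
  v$ghose <- .verdict("ghose", c(
    .chk(d$mw >= 160, sprintf("MW %.2f < 160", d$mw)),
    .chk(d$mw <= 480, sprintf("MW %.2f > 480", d$mw)),
    .chk(d$logp >= -0.4, sprintf("logP %.2f < -0.4", d$logp)),
    .chk(d$logp <= 5.6, sprintf("logP %.2f > 5.6", d$logp)),
    .chk(d$molarRefractivity >= 40,
         sprintf("MR %.1f < 40", d$molarRefractivity)),
    .chk(d$molarRefractivity <= 130,
         sprintf("MR %.1f > 130", d$molarRefractivity)),
    .chk(d$nAtomsTotal >= 20, sprintf("atoms %d < 20", d$nAtomsTotal)),
    .chk(d$nAtomsTotal <= 70, sprintf("atoms %d > 70", d$nAtomsTotal))))
  v$veber <- .verdict("veber", c(
    .chk(d$nRotBonds <= 10, sprintf("rotatable bonds %d > 10", d$nRotBonds)),
    .chk(d$tpsa <= 140, sprintf("TPSA %.1f > 140", d$tpsa))))
  v$egan <- .verdict("egan", c(
    .chk(d$logp <= 5.88, sprintf("logP %.2f > 5.88", d$logp)),
    .chk(d$tpsa <= 131.6, sprintf("TPSA %.1f > 131.6", d$tpsa))))
  v$muegge <- .verdict("muegge", c(
    .chk(d$mw >= 200, sprintf("MW %.2f < 200", d$mw)),
    .chk(d$mw <= 600, sprintf("MW %.2f > 600", d$mw)),
    .chk(d$logp >= -2, sprintf("logP %.2f < -2", d$logp)),
    .chk(d$logp <= 5, sprintf("logP %.2f > 5", d$logp)),
    .chk(d$tpsa <= 150, sprintf("TPSA %.1f > 150", d$tpsa)),
    .chk(d$nRings <= 7, sprintf("rings %d > 7", d$nRings)),
    .chk(d$nCarbon > 4, sprintf("carbons %d <= 4", d$nCarbon)),
    .chk(d$nHetero > 1, sprintf("heteroatoms %d <= 1", d$nHetero)),
    .chk(d$nRotBonds <= 15, sprintf("rotatable bonds %d > 15", d$nRotBonds)),
    .chk(d$nHBA <= 10, sprintf("HBA %d > 10", d$nHBA)),
    .chk(d$nHBD <= 5, sprintf("HBD %d > 5", d$nHBD))))
  v
}

# small documented PAINS subset (none of the study compounds match)
.painsPatterns <- c(
  quinone_A  = "O=C1C=CC(=O)C=C1",
  catechol_A = "c1ccc(O)c(O)c1",
  azo_A      = "cN=Nc",
  hzone_phenol_A = "c1cc(O)ccc1C=N",
  mannich_A  = "c1ccccc1N(C)CN")

# structural alert patterns (Brenk-style fragments relevant here)
.alertPatterns <- c(
  nitro_group    = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
  aldehyde       = "[CX3H1](=O)[#6]",
  epoxide        = "C1OC1",
  azo_compound   = "N=N",
  peroxide       = "OO",
  thiol          = "[SH]",
  acyl_halide    = "C(=O)[F,Cl,Br,I]")

#' Structural alerts and PAINS screen
#'
#' Screens the structure against a small, documented set of
#' pan-assay-interference (PAINS) substructures and a fragment alert
#' list.  The absence of any ring is itself an alert ("no organic
#' ring").
#'
#' @param x a SMILES string or \linkS4class{Molecule}
#' @return list(painsHits, structuralAlerts) of character vectors
#' @export
structuralAlerts <- function(x) {
  p <- .obParse(x)
  d <- computeDescriptors(x)
  pains <- names(.painsPatterns)[vapply(.painsPatterns, function(sm)
    .smartsCount(p$ob, sm) > 0, TRUE)]
  alerts <- names(.alertPatterns)[vapply(.alertPatterns, function(sm)
    .smartsCount(p$ob, sm) > 0, TRUE)]
  if (d$nRings == 0) alerts <- c(alerts, "no_organic_ring")
  list(painsHits = pains, structuralAlerts = alerts)
}

#' Bioavailability radar axes
#'
#' Six-axis drug-likeness radar: lipophilicity (logP in [-0.7, 5]),
#' size (MW in [150, 500]), polarity (TPSA in [20, 130]), insolubility
#' (ESOL-type logS in [-6, 0]), unsaturation (fraction of sp3 carbons
#' in [0.25, 1]) and flexibility (rotatable bonds in [0, 9]).  Bounds
#' are inclusive.
#'
#' @param d a descriptor set
#' @return data.frame(axis, value, lo, hi, inRange)
#' @export
bioavailabilityRadar <- function(d) {
  axes <- data.frame(
    axis = c("lipophilicity", "size", "polarity", "insolubility",
             "unsaturation", "flexibility"),
    value = c(d$logp, d$mw, d$tpsa, d$esolLogS, d$fracCsp3, d$nRotBonds),
    lo = c(-0.7, 150, 20, -6, 0.25, 0),
    hi = c(5, 500, 130, 0, 1, 9),
    stringsAsFactors = FALSE)
  axes$inRange <- axes$value >= axes$lo & axes$value <= axes$hi
  axes
}

#' Full drug-likeness report for a structure
#'
#' @param x a SMILES string or \linkS4class{Molecule}
#' @return list(descriptors, filters, alerts, radar)
#' @export
druglikeReport <- function(x) {
  d <- computeDescriptors(x)
  list(descriptors = d, filters = applyFilters(d),
       alerts = structuralAlerts(x), radar = bioavailabilityRadar(d))
}
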