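# Conceptual-DFT indices: algebraic identities, regression on the
# published butadiene/nitrodiene index quadruples, Parr functions and
# atomic charges.

test_that("global index identities hold to machine precision", {
  set.seed(3)
  for (trial in 1:20) {
    eH <- runif(1, -12, -4)
    eL <- eH + runif(1, 0.5, 8)
    ref <- runif(1, -11, -8)
    g <- globalIndicesFromEnergies(eH, eL, ref)
    expect_identical(g@gap, eL - eH)
    expect_identical(g@mu, (eH + eL) / 2)
    expect_identical(g@electronegativity, -g@mu)
    expect_equal(g@omega, g@mu^2 / (2 * g@eta), tolerance = 1e-15)
    expect_equal(g@softness, 1 / g@eta, tolerance = 1e-15)
    expect_identical(g@nucleophilicity, eH - ref)
  }
  expect_error(globalIndicesFromEnergies(-5, -6), "hardness")
  # symmetric frontier orbitals: mu and omega vanish
  gs <- globalIndicesFromEnergies(-3, 3, -9)
  expect_equal(gs@mu, 0)
  expect_equal(gs@omega, 0)
})

test_that("printed index quadruples are internally consistent", {
  # the butadiene quadruple: HOMO -6.23, LUMO -0.61 (sign convention:
  # the gap and omega only reproduce with a negative LUMO), gap 5.62,
  # omega 1.04, and N = 2.89 relative to a -9.12 reference
  g1 <- globalIndicesFromEnergies(-6.23, -0.61, -9.12)
  expect_equal(round(g1@gap, 2), 5.62)
  expect_equal(round(g1@omega, 2), 1.04)
  expect_equal(round(g1@nucleophilicity, 2), 2.89)
  # the nitrodiene quadruple: HOMO -8.31, LUMO -3.91, gap 4.40,
  # omega 4.24
  g2 <- globalIndicesFromEnergies(-8.31, -3.91, -9.12)
  expect_equal(round(g2@gap, 2), 4.40)
  expect_equal(round(g2@omega, 2), 4.24)
  expect_equal(round(g2@nucleophilicity, 2), 0.81)
})

test_that("local indices are exact products of the printed factors", {
  gB <- globalIndicesFromEnergies(-8.31, -3.91, -9.12)  # omega = 4.24
  pP <- c(C1 = 0.15, C2 = 0.10, C3 = 0.10, C4 = 0.15)
  pM <- c(C1 = 0.47, C2 = 0.07, C3 = 0.07, C4 = 0.47)
  p <- new("ParrFunctions", pPlus = pP, pMinus = pM, atoms = 1:4,
           source = "mulliken", s2Anion = 0.76, s2Cation = 0.76)
  l <- localIndices(gB, p)
  expect_equal(round(l@omegaK[["C1"]], 2), 0.64)  # 4.24 x 0.15
  gD <- globalIndicesFromEnergies(-6.23, -0.61, -9.12)  # N = 2.89
  l2 <- localIndices(gD, p)
  expect_equal(round(l2@nK[["C1"]], 2), 1.36)     # 2.89 x 0.47
  # zero Parr share gives a zero local index
  p0 <- new("ParrFunctions", pPlus = c(A = 0), pMinus = c(A = 0),
            atoms = 1L, source = "mulliken", s2Anion = 0.75,
            s2Cation = 0.75)
  l0 <- localIndices(gB, p0)
  expect_identical(unname(l0@omegaK), 0)
})

test_that("Parr functions sum to one; condensation puts all spin on the
           single heavy atom", {
  w <- builtinMolecule("water")
  p <- cachedResult("water_parr", function()
    parrFunctions(w, hfSto3g))
  expect_equal(sum(p@pPlus), 1, tolerance = 1e-6)
  expect_equal(sum(p@pMinus), 1, tolerance = 1e-6)
  pc <- cachedResult("water_parr_condensed", function()
    parrFunctions(w, hfSto3g, condenseHydrogens = TRUE))
  expect_length(pc@pPlus, 1L)
  expect_equal(unname(pc@pPlus[1]), 1, tolerance = 1e-6)
})

test_that("Mulliken charges conserve charge and respect symmetry", {
  w <- builtinMolecule("water")
  scf <- cachedResult("water_hf_sto3g", function() singlePoint(w, hfSto3g))
  for (m in c("mulliken", "lowdin")) {
    ch <- atomicCharges(scf, m)
    expect_equal(sum(ch@charges), 0, tolerance = 1e-6)
    expect_lt(abs(ch@charges[2] - ch@charges[3]), 1e-3)  # the two H
    expect_lt(ch@charges[1], 0)  # oxygen negative
  }
  expect_error(atomicCharges(scf, "npa"))
})
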