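# Drug-likeness rule engine

nitrodieneSmiles <- "C(=C/[N+](=O)[O-])\\C=C\\[N+](=O)[O-]"

test_that("nitrodiene descriptors match the known reference values", {
  d <- cachedResult("nitrodiene_desc", function()
    computeDescriptors(nitrodieneSmiles))
  expect_equal(d$nAtomsTotal, 14L)
  expect_equal(d$nCarbon, 4L)
  expect_equal(d$nRings, 0L)
  expect_equal(d$fracCsp3, 0)
  # sum of standard atomic weights for C4H4N2O4
  expect_equal(d$mw, 4 * 12.011 + 4 * 1.008 + 2 * 14.007 + 4 * 15.999,
               tolerance = 0.01)
  # Ertl TPSA: two nitro fragments at 45.82 each
  expect_equal(d$tpsa, 2 * 45.82, tolerance = 0.01)
  expect_equal(d$nHBA, 6L)   # N+O count
  expect_equal(d$nHBD, 0L)
})

test_that("nitrodiene passes Lipinski/Veber/Egan and fails Ghose/Muegge", {
  d <- cachedResult("nitrodiene_desc", function()
    computeDescriptors(nitrodieneSmiles))
  v <- applyFilters(d)
  expect_true(v$lipinski$passed)
  expect_true(v$veber$passed)
  expect_true(v$egan$passed)
  expect_false(v$ghose$passed)
  expect_false(v$muegge$passed)
  # verdicts carry machine-readable named violations
  expect_true(any(grepl("MW", v$ghose$violations)))
  expect_true(any(grepl("carbons", v$muegge$violations)))
})

test_that("filter bounds are inclusive (Lipinski boundary set passes)", {
  d <- cachedResult("nitrodiene_desc", function()
    computeDescriptors(nitrodieneSmiles))
  d$mw <- 500; d$logp <- 5; d$nHBD <- 5L; d$nHBA <- 10L
  v <- applyFilters(d)
  expect_true(v$lipinski$passed)
  expect_length(v$lipinski$violations, 0)
})

test_that("missing descriptors raise an error naming them", {
  d <- cachedResult("nitrodiene_desc", function()
    computeDescriptors(nitrodieneSmiles))
  d$tpsa <- NULL
  expect_error(applyFilters(d), "tpsa")
})

test_that("structural alerts flag exactly nitro + ring absence", {
  a <- structuralAlerts(nitrodieneSmiles)
  expect_length(a$painsHits, 0)
  expect_setequal(a$structuralAlerts, c("nitro_group", "no_organic_ring"))
  expect_length(structuralAlerts("c1ccccc1")$structuralAlerts, 0)
  expect_identical(structuralAlerts("c1ccccc1[N+](=O)[O-]")$structuralAlerts,
                   "nitro_group")
})

test_that("unparseable and empty structures are rejected", {
  expect_error(computeDescriptors(""), "empty")
  expect_error(computeDescriptors(Molecule(character(0),
                                           matrix(0, 0, 3))), "empty")
})

test_that("bioavailability radar flags unsaturation for the nitrodiene", {
  d <- cachedResult("nitrodiene_desc", function()
    computeDescriptors(nitrodieneSmiles))
  r <- bioavailabilityRadar(d)
  unsat <- r[r$axis == "unsaturation", ]
  expect_false(unsat$inRange)
  # a fully saturated fragment is in range, and 0.25 is inclusive
  d2 <- d; d2$fracCsp3 <- 1
  expect_true(bioavailabilityRadar(d2)[5, "inRange"])
  d2$fracCsp3 <- 0.25
  expect_true(bioavailabilityRadar(d2)[5, "inRange"])
})

test_that("descriptors are invariant under SMILES atom reordering", {
  d1 <- computeDescriptors("OCC")          # ethanol
  d2 <- computeDescriptors("CCO")
  for (k in c("mw", "tpsa", "logp", "nRotBonds", "nHBA", "nHBD",
              "fracCsp3", "nRings"))
    expect_equal(d1[[k]], d2[[k]], info = k)
})

test_that("descriptors from a 3D structure agree with the SMILES route", {
  m <- builtinMolecule("dinitrobutadiene_EE")
  d3 <- computeDescriptors(m)
  d <- cachedResult("nitrodiene_desc", function()
    computeDescriptors(nitrodieneSmiles))
  expect_equal(d3$formula, d$formula)
  expect_equal(d3$mw, d$mw, tolerance = 1e-6)
  expect_equal(d3$tpsa, d$tpsa, tolerance = 0.5)
  expect_equal(d3$nRings, 0L)
})
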