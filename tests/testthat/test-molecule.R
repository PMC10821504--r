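# Fixture construction and XYZ input/output

test_that("builtin fixtures have the correct composition", {
  ee <- builtinMolecule("dinitrobutadiene_EE")
  expect_equal(nAtoms(ee), 14L)
  expect_equal(sum(symbols(ee) == "C"), 4L)
  # C4H4N2O4: 4*6 + 4*1 + 2*7 + 4*8 electrons
  expect_equal(countElectrons(ee), 74L)
  bd <- builtinMolecule("butadiene_s_trans")
  expect_equal(nAtoms(bd), 10L)
  expect_equal(sum(symbols(bd) == "C"), 4L)
  expect_equal(sum(symbols(bd) == "H"), 6L)
  expect_equal(countElectrons(bd), 30L)
  tce <- builtinMolecule("tce")
  expect_equal(table(symbols(tce))[["C"]], 6L)
  expect_equal(table(symbols(tce))[["N"]], 4L)
  expect_equal(charge(tce), 0L)
  expect_equal(multiplicity(tce), 1L)
  aa <- builtinMolecule("acetic_acid")
  expect_equal(countElectrons(aa), 32L)
})

test_that("unknown fixture ids raise an informative error", {
  expect_error(builtinMolecule("benzene"), "valid ids")
})

test_that("every fixture passes a bonded-distance sanity check", {
  for (id in listFixtures()) {
    m <- builtinMolecule(id)
    if (nAtoms(m) < 2) next
    xyz <- coords(m)
    dmin <- min(as.matrix(stats::dist(xyz))[upper.tri(diag(nAtoms(m)))])
    expect_gt(dmin, 0.7)
    # every atom has at least one neighbour within covalent range
    dm <- as.matrix(stats::dist(xyz))
    diag(dm) <- Inf
    expect_lt(max(apply(dm, 1, min)), 1.9)
  }
})

test_that("ester diastereomers are genuinely different structures", {
  rr <- builtinMolecule("diacetoxy_dinitrobutane_RR")
  ms <- builtinMolecule("diacetoxy_dinitrobutane_meso")
  expect_equal(nAtoms(rr), 30L)
  expect_equal(countElectrons(rr), countElectrons(ms))
  # sorted interatomic distance spectra differ for diastereomers
  drr <- sort(as.matrix(stats::dist(coords(rr))))
  dms <- sort(as.matrix(stats::dist(coords(ms))))
  expect_gt(max(abs(drr - dms)), 0.05)
})

test_that("molecule validity catches inconsistent electronic state", {
  expect_error(Molecule("C", matrix(0, 1, 3), charge = 0L,
                        multiplicity = 2L), "inconsistent")
  expect_error(Molecule(c("Xx"), matrix(0, 1, 3)), "unknown element")
})

test_that("XYZ write/read round-trips coordinates and symbols", {
  bd <- builtinMolecule("butadiene_s_trans")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(bd, f)
  back <- readXYZ(f)
  expect_equal(symbols(back), symbols(bd))
  expect_lt(max(abs(coords(back) - coords(bd))), 1e-6)
})

test_that("malformed XYZ input is rejected", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "too few atoms", "H 0 0 0", "H 0 0 0.7"), f)
  expect_error(readXYZ(f), "declares 3")
  writeLines(c("2", "bad element", "Xx 0 0 0", "H 0 0 0.7"), f)
  expect_error(readXYZ(f), "unknown element")
  writeLines(c("2", "bad coord", "H 0 zero 0", "H 0 0 0.7"), f)
  expect_error(readXYZ(f), "unparseable")
})
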