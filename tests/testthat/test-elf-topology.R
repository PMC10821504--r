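# ELF basin partitioning, synapticity and population integration

h2BasinSet <- function() {
  cachedResult("h2_basins", function() {
    res <- cachedResult("h2_b3lyp_opt", function()
      optimizeGeometry(builtinMolecule("h2"), b3lypDz, gridPreset = "coarse"))
    g <- makeGrid(res$molecule, spacing = 0.15, padding = 4)
    rho <- densityField(res$scf, g)
    elf <- elfField(res$scf, g)
    list(bs = partitionBasins(elf, rho, res$molecule), rho = rho)
  })
}

waterBasinSet <- function() {
  cachedResult("water_basins", function() {
    # a split-valence ELF topology (the minimal basis is too flat to
    # separate lone pairs from O-H basins)
    w <- builtinMolecule("water")
    scf <- singlePoint(w, b3lypDz, gridPreset = "coarse")
    g <- makeGrid(w, spacing = 0.12, padding = 4)
    rho <- densityField(scf, g)
    elf <- elfField(scf, g)
    list(bs = partitionBasins(elf, rho, w), rho = rho, mol = w)
  })
}

test_that("H2 has a single protonated disynaptic basin V(H,H)", {
  h <- h2BasinSet()
  b <- basins(h$bs)
  expect_equal(nrow(b), 1L)
  expect_equal(b$label[1], "V(H1,H2)")
  expect_equal(sort(b$atoms[[1]]), c(1L, 2L))
  expect_equal(b$population[1], 2, tolerance = 0.02)
})

test_that("the basin partition is exhaustive: populations equal the
           assigned-density integral exactly", {
  h <- h2BasinSet()
  # identity at grid level: sum over all basins == integral over all
  # assigned voxels
  expect_equal(h$bs@totalPopulation,
               fieldIntegral(h$rho), tolerance = 1e-3)
  w <- waterBasinSet()
  # dust basins (< 5e-3 e) are dropped by design, so allow their share
  expect_lt(abs(w$bs@totalPopulation - fieldIntegral(w$rho)), 1e-2)
})

test_that("water shows oxygen core, lone pairs and two O-H basins", {
  w <- waterBasinSet()
  b <- basins(w$bs)
  expect_true(any(b$kind == "core"))
  core <- b[b$kind == "core", ]
  expect_equal(core$label[1], "C(O1)")
  expect_equal(core$population[1], 2, tolerance = 0.3)
  # monosynaptic lone pairs on oxygen
  lone <- b$kind == "valence" &
    vapply(b$atoms, function(a) identical(a, 1L), TRUE)
  expect_gte(sum(lone), 1)
  # protonated O-H basins, symmetry-equivalent within 0.02 e
  oh1 <- bondPopulation(w$bs, 1, 2)
  oh2 <- bondPopulation(w$bs, 1, 3)
  expect_gt(oh1, 1.0)
  expect_lt(abs(oh1 - oh2), 0.02)
})

test_that("bondPopulation warns and returns zero for unbonded pairs", {
  w <- waterBasinSet()
  expect_warning(p <- bondPopulation(w$bs, 2, 3), "no disynaptic")
  expect_equal(p, 0)
})

test_that("mismatched grids are rejected", {
  w <- waterBasinSet()
  scf <- cachedResult("water_hf_sto3g", function()
    singlePoint(builtinMolecule("water"), hfSto3g))
  g2 <- makeGrid(builtinMolecule("water"), spacing = 0.3, padding = 3)
  elf2 <- elfField(scf, g2)
  expect_error(partitionBasins(elf2, w$rho, builtinMolecule("water")),
               "share one grid")
})
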