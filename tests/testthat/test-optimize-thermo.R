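# Geometry optimisation, harmonic frequencies and RRHO thermochemistry

test_that("H2 optimisation reproduces the known bond length", {
  res <- cachedResult("h2_b3lyp_opt", function()
    optimizeGeometry(builtinMolecule("h2"), b3lypDz, gridPreset = "coarse"))
  r <- sqrt(sum((coords(res$molecule)[1, ] - coords(res$molecule)[2, ])^2))
  # B3LYP/6-31G(d) equilibrium ~0.743 Angstrom
  expect_equal(r, 0.743, tolerance = 3e-3)
  expect_true(res$converged)
})

test_that("optimisation from a converged geometry returns immediately", {
  res <- cachedResult("h2_b3lyp_opt", function()
    optimizeGeometry(builtinMolecule("h2"), b3lypDz, gridPreset = "coarse"))
  res2 <- optimizeGeometry(res$molecule, b3lypDz, gridPreset = "coarse")
  expect_equal(res2$cycles, 1L)
  expect_lt(abs(energy(res2$scf) - energy(res$scf)), 1e-7)
})

test_that("H2 ZPE matches an independent energy-curve second derivative", {
  res <- cachedResult("h2_b3lyp_opt", function()
    optimizeGeometry(builtinMolecule("h2"), b3lypDz, gridPreset = "coarse"))
  mol <- res$molecule
  fr <- cachedResult("h2_freqs", function()
    harmonicFrequencies(mol, b3lypDz, gridPreset = "coarse"))
  expect_equal(fr$nImaginary, 0L)
  expect_length(fr$frequencies, 1L)
  # oracle: second derivative of E(R) by central differences, omega =
  # sqrt(k/mu) with the reduced mass, ZPE = omega/2
  r0 <- sqrt(sum((coords(mol)[1, ] - coords(mol)[2, ])^2)) * 1.8897259886
  h <- 0.01
  eAt <- function(rb) {
    m <- Molecule(c("H", "H"), rbind(c(0, 0, 0),
                                     c(rb * 0.529177210903, 0, 0)))
    energy(singlePoint(m, b3lypDz, gridPreset = "coarse", convE = 1e-10))
  }
  k <- (eAt(r0 + h) - 2 * eAt(r0) + eAt(r0 - h)) / h^2
  mu <- 1.00794 * 1822.888486 / 2
  zpeOracle <- 0.5 * sqrt(k / mu)
  zpeGot <- sum(fr$frequencies) / (2 * 219474.6313632)
  expect_equal(zpeGot, zpeOracle, tolerance = 0.02 * zpeOracle)
})

test_that("thermochemistry satisfies the G = H - T S identity", {
  res <- cachedResult("h2_b3lyp_opt", function()
    optimizeGeometry(builtinMolecule("h2"), b3lypDz, gridPreset = "coarse"))
  th <- harmonicThermo(res$molecule, b3lypDz, scf = res$scf,
                       hessian = cachedResult("h2_hess", function()
                         numericalHessian(res$molecule, b3lypDz,
                                          gridPreset = "coarse")),
                       gridPreset = "coarse")
  expect_lt(abs(th@gCorr - (th@hCorr - th@temperature * th@s298)), 1e-8)
  expect_equal(th@nImaginary, 0L)
  expect_gt(th@zpe, 0)
})

test_that("a saddle-point structure is rejected as a minimum", {
  # linear water is a bending saddle point at HF/STO-3G
  linw <- Molecule(c("O", "H", "H"),
                   rbind(c(0, 0, 0), c(0.95, 0, 0), c(-0.95, 0, 0)))
  expect_error(
    harmonicThermo(linw, hfSto3g, checkMinimum = TRUE),
    "imaginary")
})

test_that("reaction energetics obey the dG/dH/dS identity and Hess cycle", {
  mk <- function(e, zpe, h, s) {
    new("ThermoRecord", eElec = e, zpe = zpe, hCorr = h,
        gCorr = h - 298.15 * s, s298 = s, nImaginary = 0L,
        frequencies = numeric(), temperature = 298.15)
  }
  ester <- mk(-900.1, 0.2, 0.21, 1.3e-4)
  acoh <- mk(-229.0, 0.06, 0.065, 0.9e-4)
  dieneA <- mk(-411.02, 0.08, 0.086, 1.0e-4)
  dieneB <- mk(-411.00, 0.08, 0.086, 1.0e-4)
  ra <- reactionEnergetics(ester, dieneA, acoh, "RR", "EE")
  rb <- reactionEnergetics(ester, dieneB, acoh, "RR", "ZZ")
  expect_lt(abs(ra$dG_kcal - (ra$dH_kcal - 298.15 * ra$dS_cal / 1000)), 0.01)
  # Hess cycle: the ester and acid terms cancel in the difference
  expect_equal(ra$dG_kcal - rb$dG_kcal,
               (gibbsEnergy(dieneA) - gibbsEnergy(dieneB)) * 627.5095,
               tolerance = 1e-9)
})

test_that("rotamer scan returns the lowest-energy start and respects n=1", {
  # ethane-like fragment: use hydrogen peroxide (cheap, one dihedral)
  hooh <- Molecule(c("O", "O", "H", "H"),
                   rbind(c(0, 0, 0), c(1.40, 0, 0),
                         c(-0.30, 0.85, 0.3), c(1.70, -0.85, 0.3)))
  scan <- cachedResult("hooh_scan", function()
    rotamerScan(hooh, c(3, 1, 2, 4), nSteps = 3, level = hfSto3g))
  expect_lte(energy(scan$scf), min(scan$energies) + 1e-10)
  one <- rotamerScan(hooh, c(3, 1, 2, 4), nSteps = 1, level = hfSto3g)
  plain <- optimizeGeometry(hooh, hfSto3g)
  expect_equal(energy(one$scf), energy(plain$scf), tolerance = 1e-6)
})
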