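# The SCF engine: Hermite recursions against an independent recursive
# reference, textbook H2/STO-3G values, invariances, and gradients.

test_that("Hermite expansion coefficients match the recursive reference", {
  set.seed(11)
  for (trial in 1:12) {
    p <- runif(1, 0.2, 8)
    PA <- rnorm(1); PB <- rnorm(1)
    i <- sample(0:4, 1); j <- sample(0:4, 1)
    got <- .cpp_etab(5, 5, p, PA, PB, i, j)
    ref <- vapply(0:(i + j), function(t) refE(i, j, t, p, PA, PB), 0)
    expect_lt(max(abs(got - ref)), 1e-11)
  }
})

test_that("Hermite Coulomb tensor matches the recursive reference", {
  set.seed(12)
  for (trial in 1:6) {
    L <- sample(0:7, 1)
    p <- runif(1, 0.2, 5)
    X <- rnorm(1); Y <- rnorm(1); Z <- rnorm(1)
    got <- .cpp_rtab(L, p, X, Y, Z)
    Fv <- refBoys(L, p * (X^2 + Y^2 + Z^2))
    S <- L + 1
    for (t in 0:L) for (u in 0:(L - t)) for (v in 0:(L - t - u)) {
      expect_lt(abs(got[(t * S + u) * S + v + 1] -
                    refR(t, u, v, 0, p, X, Y, Z, Fv)), 1e-9)
    }
  }
})

test_that("H2/STO-3G reproduces the textbook minimal-basis values", {
  # R = 1.4 Bohr; Szabo & Ostrund tabulate S12 = 0.6593, T11 = 0.7600
  # and a converged total energy of -1.1167 Hartree
  h2 <- Molecule(c("H", "H"), rbind(c(0, 0, 0), c(1.4 * 0.529177210903, 0, 0)))
  sh <- MolDFT:::buildShells(h2, "sto-3g")
  ints <- .cpp_int1e_ovl_kin(sh)
  expect_equal(ints$S[1, 2], 0.6593, tolerance = 1e-4)
  expect_equal(ints$T[1, 1], 0.7600, tolerance = 1e-4)
  scf <- singlePoint(h2, hfSto3g)
  expect_equal(energy(scf), -1.1167, tolerance = 1e-4)
  expect_equal(scf@epsA[1], -0.578, tolerance = 1e-3)
})

test_that("overlap is exactly normalised and H2O/HF energy is correct", {
  w <- builtinMolecule("water")
  scf <- cachedResult("water_hf_sto3g", function() singlePoint(w, hfSto3g))
  expect_lt(max(abs(diag(scf@overlap) - 1)), 1e-12)
  # published HF/STO-3G water energies at near-experimental geometries
  # are about -74.96 Hartree
  expect_equal(energy(scf), -74.963, tolerance = 2e-3)
  # restricted singlet: identical spin channels
  expect_identical(scf@epsA, scf@epsB)
  expect_equal(sum(scf@occA), 5)
})

test_that("total energy is invariant under rigid rotation + translation", {
  w <- builtinMolecule("water")
  e1 <- energy(cachedResult("water_hf_sto3g",
                            function() singlePoint(w, hfSto3g)))
  e2 <- energy(singlePoint(rotateMolecule(w), hfSto3g))
  expect_lt(abs(e1 - e2), 1e-7)
})

test_that("open-shell SCF gives a clean doublet for the H atom", {
  h <- Molecule("H", matrix(0, 1, 3), multiplicity = 2L)
  scf <- singlePoint(h, hfSto3g)
  expect_equal(energy(scf), -0.46658, tolerance = 1e-4)  # STO-3G H atom
  expect_equal(scf@s2, 0.75, tolerance = 1e-8)
})

test_that("density integrates to the electron count on a Becke grid", {
  w <- builtinMolecule("water")
  scf <- cachedResult("water_hf_sto3g", function() singlePoint(w, hfSto3g))
  sh <- scf@shells
  xyzB <- coords(w) * 1.8897259886
  grid <- .cpp_becke_grid(xyzB, MolDFT:::elementBragg(symbols(w)) * 1.8897259886,
                          50, 14)
  D <- densityMatrix(scf, "alpha")
  xc <- .cpp_xc_int(sh, D, D, grid$points, grid$weights, c(0.8, 0, 0, 0),
                    FALSE, FALSE, 3)
  expect_equal(xc$nelec, 10, tolerance = 1e-4)
})

test_that("analytic gradients agree with finite differences", {
  h2 <- Molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.76, 0, 0)))
  for (lv in list(hfSto3g, LevelOfTheory("b3lyp", "sto-3g"))) {
    scf <- singlePoint(h2, lv, gridPreset = "coarse", convE = 1e-10)
    ga <- scfGradient(scf, gridPreset = "coarse")
    h <- 1e-3
    num <- matrix(0, 2, 3)
    for (a in 1:2) for (d in 1:3) {
      xp <- coords(h2); xp[a, d] <- xp[a, d] + h * 0.529177210903
      xm <- coords(h2); xm[a, d] <- xm[a, d] - h * 0.529177210903
      ep <- energy(singlePoint(setCoords(h2, xp), lv,
                               gridPreset = "coarse", convE = 1e-10))
      em <- energy(singlePoint(setCoords(h2, xm), lv,
                               gridPreset = "coarse", convE = 1e-10))
      num[a, d] <- (ep - em) / (2 * h)
    }
    expect_lt(max(abs(ga - num)), 5e-5)
  }
})

test_that("SCF refuses to return unconverged results", {
  w <- builtinMolecule("water")
  expect_error(singlePoint(w, hfSto3g, maxiter = 2), "converge")
})
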