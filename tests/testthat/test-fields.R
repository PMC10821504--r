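# Scalar-field machinery: grids, analytic oracles, ELF/RDG kernels,
# cube I/O, density conservation, MEP limits.

test_that("makeGrid encloses the nuclei with the requested padding", {
  atom <- Molecule("H", matrix(0, 1, 3), multiplicity = 2L)
  g <- makeGrid(atom, spacing = 0.1, padding = 4)
  expect_equal(g@shape, rep(81L, 3))
  expect_equal(as.numeric(g@origin), rep(-4, 3))
  bd <- builtinMolecule("butadiene_s_trans")
  g2 <- makeGrid(bd, spacing = 0.1, padding = 4)
  pts <- gridPoints(g2)
  xyzB <- coords(bd) * 1.8897259886
  for (d in 1:3) {
    expect_lte(min(pts[, d]), min(xyzB[, d]) - 4 + 1e-9)
    expect_gte(max(pts[, d]), max(xyzB[, d]) + 4 - 0.1)
  }
  g0 <- makeGrid(bd, spacing = 0.1, padding = 0)
  expect_equal(as.numeric(g0@origin), apply(xyzB, 2, min), tolerance = 1e-9)
  expect_error(makeGrid(bd, spacing = -0.1), "positive")
})

test_that("analytic Gaussian density integrates to one", {
  atom <- Molecule("H", matrix(0, 1, 3), multiplicity = 2L)
  g <- makeGrid(atom, spacing = 0.2, padding = 6)
  f <- analyticDensity("gaussian_density", g, width = 1.0)
  expect_equal(fieldIntegral(f), 1, tolerance = 1e-3)
  expect_error(analyticDensity("gaussian_density", g, width = -1), "positive")
})

test_that("off-centre Gaussian peaks at the grid point nearest its centre", {
  atom <- Molecule("H", matrix(0, 1, 3), multiplicity = 2L)
  g <- makeGrid(atom, spacing = 0.25, padding = 3)
  ctr <- c(0.6, -0.4, 0.9)
  f <- analyticDensity("gaussian_density", g, width = 0.8, center = ctr)
  pts <- gridPoints(g)
  imax <- which.max(as.numeric(f@values))
  d <- sqrt(colSums((t(pts) - ctr)^2))
  expect_equal(imax, which.min(d))
})

test_that("uniform gas field is constant and gives ELF exactly one half", {
  atom <- Molecule("H", matrix(0, 1, 3), multiplicity = 2L)
  g <- makeGrid(atom, spacing = 0.5, padding = 2)
  f <- analyticDensity("uniform_gas", g, value = 0.02)
  expect_true(all(f@values == 0.02))
  rho <- as.numeric(f@values)
  tauH <- 0.3 * (3 * pi^2)^(2 / 3) * rho^(5 / 3)  # homogeneous gas
  elf <- elfKernel(rho, rep(0, length(rho)), tauH)
  expect_equal(elf, rep(0.5, length(rho)), tolerance = 1e-12)
})

test_that("ELF kernel is clamped and NaN-free for degenerate input", {
  elf <- elfKernel(c(1e-14, 0, 1e-3), c(0, 0, 1e-3), c(0, 0, 1e-4))
  expect_false(anyNA(elf))
  expect_true(all(elf >= 0 & elf <= 1))
  expect_equal(elf[1:2], c(0, 0))
})

test_that("RDG of an analytic Gaussian matches the closed form", {
  w <- 0.9
  A <- (2 * pi * w^2)^(-3 / 2)
  r <- c(0.3, 0.8, 1.6, 2.5)
  rho <- A * exp(-r^2 / (2 * w^2))
  grad2 <- (rho * r / w^2)^2
  expect_equal(rdgKernel(rho, grad2), gaussianRDG(r, w), tolerance = 1e-9)
})

test_that("H2 has a strongly localised ELF maximum at the bond midpoint", {
  res <- cachedResult("h2_b3lyp_opt", function()
    optimizeGeometry(builtinMolecule("h2"), b3lypDz, gridPreset = "coarse"))
  mid <- colMeans(coords(res$molecule)) * 1.8897259886
  ev <- .cpp_field_eval(res$scf@shells,
                        densityMatrix(res$scf, "alpha"),
                        densityMatrix(res$scf, "beta"),
                        rbind(mid), TRUE, TRUE, FALSE, FALSE)
  elf <- elfKernel(ev$rho, ev$grad2, ev$tau)
  expect_gt(elf, 0.9)
})

test_that("grid density integral conserves the electron count within 1%", {
  w <- builtinMolecule("water")
  scf <- cachedResult("water_hf_sto3g", function() singlePoint(w, hfSto3g))
  g <- makeGrid(w, spacing = 0.15, padding = 4.5)
  rho <- densityField(scf, g)
  expect_equal(fieldIntegral(rho), 10, tolerance = 0.01)
})

test_that("cube files round-trip within format precision", {
  w <- builtinMolecule("water")
  scf <- cachedResult("water_hf_sto3g", function() singlePoint(w, hfSto3g))
  g <- makeGrid(w, spacing = 0.4, padding = 2)
  f <- elfField(scf, g)
  path <- withr::local_tempfile(fileext = ".cube")
  writeCube(f, w, path)
  back <- readCube(path)
  expect_equal(back$field@grid@shape, g@shape)
  expect_lt(max(abs(back$field@values - f@values)), 1e-5)
  expect_equal(symbols(back$molecule), symbols(w))
  expect_lt(max(abs(coords(back$molecule) - coords(w))), 1e-5)
})

test_that("cube dialect with negative atom count is handled", {
  w <- builtinMolecule("water")
  scf <- cachedResult("water_hf_sto3g", function() singlePoint(w, hfSto3g))
  g <- makeGrid(w, spacing = 0.8, padding = 1.5)
  f <- densityField(scf, g)
  path <- withr::local_tempfile(fileext = ".cube")
  writeCube(f, w, path)
  lines <- readLines(path)
  p3 <- strsplit(trimws(lines[3]), "[[:space:]]+")[[1]]
  lines[3] <- sprintf("%5d %11.6f %11.6f %11.6f", -as.integer(p3[1]),
                      as.numeric(p3[2]), as.numeric(p3[3]),
                      as.numeric(p3[4]))
  # dataset-id line after the atom block, per the convention
  nat <- as.integer(p3[1])
  lines <- append(lines, "    1    1", after = 6 + nat)
  writeLines(lines, path)
  back <- readCube(path)
  expect_lt(max(abs(back$field@values - f@values)), 1e-5)
})

test_that("truncated cube files raise errors naming the missing part", {
  path <- withr::local_tempfile(fileext = ".cube")
  writeLines(c("a", "b", "   1 0 0 0"), path)
  expect_error(readCube(path), "truncated")
})

test_that("MEP has the correct far-field limits", {
  w <- builtinMolecule("water")
  scf <- cachedResult("water_hf_sto3g", function() singlePoint(w, hfSto3g))
  far <- rbind(c(20, 0, 0), c(0, 20, 5), c(-14, -14, 0))
  v <- espAtPoints(scf, far)
  expect_lt(max(abs(v)), 0.01)  # neutral molecule
  # cation: monopole limit V ~ 1/r
  hw <- Molecule(c("O", "H", "H"), coords(w), charge = 1L,
                 multiplicity = 2L)
  scfc <- singlePoint(hw, hfSto3g)
  ctr <- colMeans(coords(hw)) * 1.8897259886
  pt <- rbind(ctr + c(20, 0, 0))
  vc <- as.numeric(espAtPoints(scfc, pt))
  expect_equal(vc, 1 / 20, tolerance = 0.05)
})

test_that("field values are invariant under atom relabelling", {
  w <- builtinMolecule("water")
  perm <- c(2, 1, 3)  # swap the hydrogens with the oxygen first
  wp <- Molecule(symbols(w)[perm], coords(w)[perm, ], label = "permuted")
  scf1 <- cachedResult("water_hf_sto3g", function() singlePoint(w, hfSto3g))
  scf2 <- singlePoint(wp, hfSto3g)
  pts <- rbind(c(0.3, 0.2, 0.1), c(1.1, -0.4, 0.6), c(0, 0, 1.4))
  e1 <- .cpp_field_eval(scf1@shells, densityMatrix(scf1, "alpha"),
                        densityMatrix(scf1, "beta"), pts, TRUE, TRUE,
                        FALSE, FALSE)
  e2 <- .cpp_field_eval(scf2@shells, densityMatrix(scf2, "alpha"),
                        densityMatrix(scf2, "beta"), pts, TRUE, TRUE,
                        FALSE, FALSE)
  expect_lt(max(abs(e1$rho - e2$rho)), 1e-6)
  expect_lt(max(abs(e1$tau - e2$tau)), 1e-6)
})
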