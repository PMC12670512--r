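test_that("XYZ files parse with unit conversion and clear errors", {
  path <- tempfile(fileext = ".xyz")
  on.exit(unlink(path))
  writeLines(c("1", "one hydrogen", "H 0 0 0"), path)
  mol <- read_xyz(path)
  expect_equal(mol$Z, 1)
  expect_equal(mol$nelec, 1L)
  expect_equal(unname(mol$coords[, 1]), c(0, 0, 0))

  writeLines(c("2", "H2 at equilibrium", "H 0 0 0", "H 0 0 0.7414"), path)
  h2 <- read_xyz(path)
  expect_equal(h2$coords[3, 2] - h2$coords[3, 1], 0.7414 * 1.8897259886,
               tolerance = 1e-10)

  writeLines(c("not_a_count", "x", "H 0 0 0"), path)
  expect_error(read_xyz(path), "count line 1")
  writeLines(c("1", "c", "Xx 0 0 0"), path)
  expect_error(read_xyz(path), "unknown element")
})

test_that("nuclear repulsion follows the Coulomb formula", {
  h2 <- mw_molecule(c("H", "H"), matrix(c(0, 0, 0, 0, 0, 1.4), 3, 2))
  expect_equal(nuclear_repulsion(h2), 1 / 1.4, tolerance = 1e-12)
})

test_that("smoothed nuclear potential is Coulombic away from nuclei", {
  b <- tiny_basis(6L)
  p <- 1e-5
  mol <- mw_molecule("H", matrix(0, 3, 1))
  v <- nuclear_potential(mol, b, p, L = 16)
  got <- mw_eval(v, 1, 0, 0)
  expect_lt(abs(got + 1), 1e-5)
  expect_true(all(mw_eval(v, c(0.05, 0.2, 1, 3), c(0, 0, 0, 0), c(0, 0, 0, 0)) < 0))
  # additivity of two nuclei
  mol2 <- mw_molecule(c("H", "H"), matrix(c(0, 0, -1, 0, 0, 1), 3, 2))
  v2 <- nuclear_potential(mol2, b, p, L = 16)
  pts <- rbind(c(0.3, 0.1, 0), c(0, 0, 2.5), c(1, 1, 1))
  va <- mw_eval(v2, pts[, 1], pts[, 2], pts[, 3])
  r1 <- sqrt(rowSums(sweep(pts, 2, c(0, 0, -1))^2))
  r2 <- sqrt(rowSums(sweep(pts, 2, c(0, 0, 1))^2))
  expect_lt(max(abs(va + 1 / r1 + 1 / r2)), 1e-3)
  # nucleus too close to the boundary is refused
  molb <- mw_molecule("H", matrix(c(0, 0, 15.999), 3, 1))
  expect_error(nuclear_potential(molb, b, p, L = 16), "boundary")
})

test_that("hydrogenic expectation of the smoothed potential is -Z", {
  b <- tiny_basis(7L)
  p <- 1e-5
  mol <- mw_molecule("H", matrix(0, 3, 1))
  v <- nuclear_potential(mol, b, p, L = 16)
  phi <- suppressWarnings(mw_project(hydrogenic_1s(1), b, p, L = 16,
                                     guide = matrix(0, 3, 1)))
  vphi <- mw_multiply(v, phi, prec = p)
  expect_lt(abs(mw_inner(phi, vphi) + 1), 10 * p)
})
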