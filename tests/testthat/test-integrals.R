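# Orbital-basis integrals against hydrogenic closed forms, symmetry and
# transformation properties, and FCIDUMP interchange.

make_hydrogenic <- function(Z, k = 7L, p = 1e-5, L = 16) {
  b <- tiny_basis(k)
  phi <- suppressWarnings(mw_project(hydrogenic_1s(Z), b, p, L = L,
                                     guide = matrix(0, 3, 1)))
  mw_orbitals(list(phi))
}

test_that("hydrogenic one-body integral equals -Z^2/2", {
  p <- 1e-5
  for (Z in c(1, 2)) {
    orbs <- make_hydrogenic(Z)
    mol <- mw_molecule(c("H", "He")[Z], matrix(0, 3, 1))
    v <- nuclear_potential(mol, orbs$orb[[1]]$basis, p, L = 16)
    h <- mw_one_body(orbs, v)
    expect_lt(abs(h[1, 1] + Z^2 / 2), 5e-5)
  }
})

test_that("an orbital far from the nuclei sees only its kinetic energy", {
  b <- tiny_basis(6L)
  p <- 1e-4
  al <- 1.5
  R0 <- c(9, 0, 0)
  phi <- mw_project(gauss3(al, R0), b, p, L = 16,
                    guide = matrix(R0, 3, 1))
  orbs <- mw_orbitals(list(phi))
  mol <- mw_molecule("H", matrix(c(-9, 0, 0), 3, 1))
  v <- nuclear_potential(mol, b, p, L = 16)
  h <- mw_one_body(orbs, v)
  # kinetic part is 3 alpha / 2; the Coulomb tail at 18 bohr is ~ 1/18
  expect_lt(abs((h[1, 1] + 1 / 18) - 1.5 * al), 2e-3)
})

test_that("pair potentials are symmetric with the right monopole", {
  orbs0 <- make_hydrogenic(1)
  orbs <- mw_orbitals(list(orbs0$orb[[1]], orbs0$orb[[1]]))
  b <- orbs$orb[[1]]$basis
  pois <- mw_poisson_op(b, 16, 1e-5)
  g12 <- mw_pair_potential(orbs, 1, 2, pois)
  g21 <- mw_pair_potential(orbs, 2, 1, pois)
  pts <- c(0.5, 2, 5)
  expect_lt(max(abs(mw_eval(g12, pts, pts * 0, pts * 0) -
                    mw_eval(g21, pts, pts * 0, pts * 0))), 1e-5)
  # far field of a unit-norm orbital density: ghat -> 1/r
  for (r in c(6, 10)) {
    expect_lt(abs(mw_eval(g12, r, 0, 0) - 1 / r), 2e-4)
  }
})

test_that("hydrogenic self-repulsion equals 5Z/8", {
  p <- 1e-5
  for (Z in c(1, 2)) {
    orbs <- make_hydrogenic(Z)
    pois <- mw_poisson_op(orbs$orb[[1]]$basis, 16, p)
    g <- mw_two_body(orbs, pois)
    expect_lt(abs(g[1, 1, 1, 1] - 5 * Z / 8), 1e-4)
  }
})

test_that("two-body tensor has the 8-fold symmetry and PSD supermatrix", {
  b <- tiny_basis(5L)
  p <- 1e-4
  f1 <- mw_project(gauss3(1.0), b, p, L = 16, guide = matrix(0, 3, 1))
  f2 <- mw_project(function(x, y, z) x * gauss3(0.8)(x, y, z), b, p, L = 16,
                   guide = matrix(0, 3, 1))
  orbs <- mw_lowdin(mw_orbitals(list(f1, f2)))
  pois <- mw_poisson_op(b, 16, p)
  g <- mw_two_body(orbs, pois)
  M <- 2
  for (i in 1:M) for (j in 1:M) for (k in 1:M) for (l in 1:M) {
    v <- g[i, j, k, l]
    expect_lt(abs(g[k, j, i, l] - v), 1e-9)
    expect_lt(abs(g[i, l, k, j] - v), 1e-9)
    expect_lt(abs(g[j, i, l, k] - v), 1e-9)
  }
  # Coulomb supermatrix over pair densities (ik),(jl) is PSD
  S <- matrix(0, M^2, M^2)
  for (i in 1:M) for (k in 1:M) for (j in 1:M) for (l in 1:M) {
    S[(i - 1) * M + k, (j - 1) * M + l] <- g[i, j, k, l]
  }
  expect_gt(min(eigen((S + t(S)) / 2, symmetric = TRUE)$values), -1e-6)
  # Cauchy-Schwarz bound on off-diagonal elements
  for (i in 1:M) for (j in 1:M) {
    expect_lte(abs(g[i, j, i, j]),
               sqrt(g[i, i, i, i] * g[j, j, j, j]) + 1e-6)
  }
})

test_that("integrals transform consistently under orbital rotation", {
  b <- tiny_basis(5L)
  p <- 1e-4
  f1 <- mw_project(gauss3(1.2), b, p, L = 16, guide = matrix(0, 3, 1))
  f2 <- mw_project(gauss3(0.4), b, p, L = 16, guide = matrix(0, 3, 1))
  orbs <- mw_lowdin(mw_orbitals(list(f1, f2)))
  mol <- mw_molecule("He", matrix(0, 3, 1))
  v <- nuclear_potential(mol, b, p, L = 16)
  pois <- mw_poisson_op(b, 16, p)
  h <- mw_one_body(orbs, v)
  g <- mw_two_body(orbs, pois)
  th <- pi / 5
  U <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  orbs2 <- mw_rotate(orbs, U)
  h2 <- mw_one_body(orbs2, v)
  g2 <- mw_two_body(orbs2, pois)
  expect_lt(max(abs(h2 - U %*% h %*% t(U))), 50 * p)
  expect_lt(max(abs(g2 - rotate_two_body(g, U))), 50 * p)
})

test_that("FCIDUMP round trip is exact and symmetry-expanding", {
  M <- 3
  inst <- rand_hg(5, M)
  # make g exactly 8-fold symmetric in the real-orbital sense
  g <- inst$g
  path <- tempfile(fileext = ".fcidump")
  on.exit(unlink(path))
  fcidump_write(inst$h, g, 1 / 1.4, 4L, path)
  back <- fcidump_read(path)
  expect_equal(back$norb, M)
  expect_equal(back$nelec, 4L)
  expect_equal(back$ecore, 1 / 1.4, tolerance = 1e-15)
  expect_lt(max(abs(back$h - inst$h)), 1e-14)
  expect_lt(max(abs(back$g - g)), 1e-14)
})
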