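# Symmetrization, multipliers, rotation, Loewdin, and the per-orbital
# Helmholtz update.

test_that("gradient symmetrization has the stated fixed points", {
  M <- 3L
  set.seed(51)
  A <- matrix(rnorm(M * M), M)
  sym <- (A + t(A)) / 2
  anti <- (A - t(A)) / 2
  B <- rand_hg(52, M)$g
  raw_sym <- structure(list(dE_dh = sym, dE_dg = B), class = "mw_gradients")
  sg <- symmetrize_gradients(raw_sym)
  expect_equal(sg$dE1, sym, tolerance = 1e-14)
  expect_equal(sg$dE2, B / 2, tolerance = 1e-14)  # already fully symmetric
  raw_anti <- structure(list(dE_dh = anti, dE_dg = B), class = "mw_gradients")
  expect_lt(max(abs(symmetrize_gradients(raw_anti)$dE1)), 1e-14)
  # the energy contraction is unchanged because (h, g) share the symmetries
  inst <- rand_hg(53, M)
  rawr <- structure(list(dE_dh = A, dE_dg = B), class = "mw_gradients")
  sgr <- symmetrize_gradients(rawr)
  e_raw <- sum(inst$h * A) + 0.5 * sum(inst$g * B)
  e_sym <- sum(inst$h * sgr$dE1) + 0.5 * sum(inst$g * (2 * sgr$dE2))
  expect_lt(abs(e_raw - e_sym), 1e-10)
})

test_that("multiplier matrix closed forms and symmetry", {
  # M = 1, N = 2: eps_bar = 2 h + Gamma g = 2h + 2g (the Hartree-Fock
  # 2*epsilon; see the methods vignette for the factor convention)
  h <- matrix(-1, 1, 1)
  g <- array(0.5, c(1, 1, 1, 1))
  sg <- symmetrize_gradients(structure(
    list(dE_dh = matrix(2, 1, 1), dE_dg = array(2, c(1, 1, 1, 1))),
    class = "mw_gradients"))
  expect_equal(multipliers(sg, h, g)[1, 1], 2 * (-1) + 2 * 0.5,
               tolerance = 1e-14)
  # M = 1, N = 1: Gamma = 0 so eps_bar = h
  sg1 <- symmetrize_gradients(structure(
    list(dE_dh = matrix(1, 1, 1), dE_dg = array(0, c(1, 1, 1, 1))),
    class = "mw_gradients"))
  expect_equal(multipliers(sg1, h, g)[1, 1], -1, tolerance = 1e-14)
  # random inputs give a symmetric matrix
  M <- 3L
  inst <- rand_hg(54, M)
  raw <- structure(list(dE_dh = diag(3) + 0.1, dE_dg = inst$g),
                   class = "mw_gradients")
  eb <- multipliers(symmetrize_gradients(raw), inst$h, inst$g)
  expect_lt(max(abs(eb - t(eb))), 1e-13)
})

test_that("rotation diagonalizes the one-body gradient, preserving trace", {
  b <- tiny_basis(5L)
  p <- 1e-4
  f1 <- mw_project(gauss3(1.2), b, p, L = 16, guide = matrix(0, 3, 1))
  f2 <- mw_project(function(x, y, z) z * gauss3(0.6)(x, y, z), b, p, L = 16,
                   guide = matrix(0, 3, 1))
  orbs <- mw_lowdin(mw_orbitals(list(f1, f2)))
  dE1 <- matrix(c(1.8, 0.15, 0.15, 0.2), 2, 2)
  sg <- list(dE1 = dE1, dE2 = rand_hg(55, 2)$g / 2)
  eb <- matrix(c(-2, 0.3, 0.3, -0.5), 2, 2)
  h <- matrix(c(-1.5, 0.1, 0.1, -0.3), 2, 2)
  rot <- diagonalize_rotate(sg, eb, h, orbs)
  expect_lt(max(abs(rot$U %*% t(rot$U) - diag(2))), 1e-12)
  D <- rot$U %*% sg$dE1 %*% t(rot$U)
  expect_lt(max(abs(D - diag(rot$Lambda))), 1e-10)
  expect_true(all(diff(rot$Lambda) <= 0))
  expect_equal(sum(rot$Lambda), sum(diag(dE1)), tolerance = 1e-12)
  # an already-diagonal gradient leaves the orbitals unchanged (up to sign)
  sgd <- list(dE1 = diag(c(1.9, 0.1)), dE2 = sg$dE2)
  rotd <- diagonalize_rotate(sgd, eb, h, orbs)
  expect_lt(max(abs(abs(rotd$U) - diag(2))), 1e-12)
  # degenerate-to-zero occupations are refused
  sg0 <- list(dE1 = diag(c(2, 0)), dE2 = sg$dE2)
  expect_error(diagonalize_rotate(sg0, eb, h, orbs), "unoccupied")
})

test_that("Loewdin orthonormalization is exact, idempotent, span-preserving", {
  b <- tiny_basis(5L)
  p <- 1e-4
  f1 <- mw_project(gauss3(1.0), b, p, L = 16, guide = matrix(0, 3, 1))
  f2 <- mw_project(gauss3(0.5), b, p, L = 16, guide = matrix(0, 3, 1))
  orbs <- mw_orbitals(list(f1, f2))
  on <- mw_lowdin(orbs)
  s <- mw_overlap(on)
  expect_lt(max(abs(s - diag(2))), 10 * p)
  # already-orthonormal sets are (nearly) unchanged
  on2 <- mw_lowdin(on)
  d <- mw_norm(mw_add(list(on$orb[[1]], on2$orb[[1]]), c(1, -1)))
  expect_lt(d, 10 * p)
  # a scaled orthogonal set is just renormalized
  sc <- mw_orbitals(list(mw_add(list(on$orb[[1]]), 2.5, prune = FALSE),
                         on$orb[[2]]))
  onsc <- mw_lowdin(sc)
  expect_lt(abs(mw_norm(onsc$orb[[1]]) - 1), 10 * p)
  # span preservation: the projector onto the span acts identically
  probe <- mw_project(gauss3(0.8, c(0.5, 0, 0)), b, p, L = 16,
                      guide = matrix(c(0.5, 0, 0), 3, 1))
  pr <- function(set) {
    acc <- 0
    for (i in 1:2) acc <- acc + mw_inner(set$orb[[i]], probe)^2
    acc
  }
  # compare |P probe|^2 computed in two orthonormal bases of the same span
  expect_lt(abs(pr(on) - pr(on2)), 50 * p)
  # linear dependence is refused
  dep <- mw_orbitals(list(f1, f1))
  expect_error(mw_lowdin(dep), "singular")
})

test_that("the Helmholtz update fixes the exact hydrogen ground state", {
  b <- tiny_basis(6L)
  p <- 1e-4
  L <- 32
  mol <- mw_molecule("H", matrix(0, 3, 1))
  vtree <- nuclear_potential(mol, b, p, L)
  phi <- suppressWarnings(mw_project(hydrogenic_1s(1), b, p, L = L,
                                     guide = matrix(0, 3, 1)))
  orbs <- mw_orbitals(list(phi))
  # N = 1: Lambda = 1, eps' = h = -0.5, no two-body term
  sg <- list(dE1 = matrix(1, 1, 1), dE2 = array(0, c(1, 1, 1, 1)))
  rot <- list(U = matrix(1, 1, 1), Lambda = 1,
              eps_prime = matrix(-0.5, 1, 1), orbs_rot = orbs)
  up <- update_orbital(1L, rot, sg, orbs, vtree, list(), p)
  expect_false(up$fallback)
  expect_equal(up$coeff, -0.5, tolerance = 1e-12)
  res <- mw_norm(mw_add(list(up$tree, phi), c(1, -1)))
  expect_lt(res, 20 * p)
  # a perturbed input contracts toward the fixed point
  pert <- mw_lowdin(mw_orbitals(list(mw_add(list(
    phi, mw_project(gauss3(0.9), b, p, L = L, guide = matrix(0, 3, 1))),
    c(1, 0.3)))))
  rot2 <- list(U = matrix(1, 1, 1), Lambda = 1,
               eps_prime = matrix(-0.5, 1, 1), orbs_rot = pert)
  up2 <- update_orbital(1L, rot2, sg, pert, vtree, list(), p)
  d_before <- mw_norm(mw_add(list(pert$orb[[1]], phi), c(1, -1)))
  nrm <- mw_norm(up2$tree)
  d_after <- mw_norm(mw_add(list(up2$tree, phi), c(1 / nrm, -1)))
  expect_lt(d_after, d_before)
})

test_that("the update reduces to -2 G[v phi] without two-body/off-diagonal", {
  b <- tiny_basis(5L)
  p <- 1e-4
  L <- 16
  mol <- mw_molecule("H", matrix(0, 3, 1))
  vtree <- nuclear_potential(mol, b, p, L)
  phi <- mw_project(gauss3(0.8), b, p, L = L, guide = matrix(0, 3, 1))
  orbs <- mw_orbitals(list(phi))
  sg <- list(dE1 = matrix(1, 1, 1), dE2 = array(0, c(1, 1, 1, 1)))
  cc <- -0.45  # on the snap grid or not, both paths must agree
  rot <- list(U = matrix(1, 1, 1), Lambda = 1,
              eps_prime = matrix(cc, 1, 1), orbs_rot = orbs)
  up <- update_orbital(1L, rot, sg, orbs, vtree, list(), p)
  G <- mw_bsh_op(mwdmrg:::snap_round(cc), b, L, p, is_coeff = TRUE)
  vphi <- mw_multiply(vtree, phi, prec = p)
  direct <- mw_add(list(mw_apply(G, mw_add(list(vphi, phi),
                                           c(1, mwdmrg:::snap_round(cc) - cc)))),
                   -2, prune = FALSE)
  d <- mw_norm(mw_add(list(up$tree, direct), c(1, -1)))
  expect_lt(d, 1e-10)
})
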