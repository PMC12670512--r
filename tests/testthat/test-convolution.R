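# Non-standard-form application of separated kernels.  Module tests run at
# reduced order/precision; the production-precision checks live in the
# acceptance suite.

kc <- 6L
pc <- 1e-4
Lc <- 16

test_that("Poisson on a Gaussian charge gives the erf potential", {
  b <- tiny_basis(kc)
  al <- 2
  rho <- function(x, y, z) (al / pi)^1.5 * exp(-al * (x^2 + y^2 + z^2))
  tr <- mw_project(rho, b, pc, L = Lc, guide = matrix(0, 3, 1))
  P <- mw_poisson_op(b, Lc, pc)
  V <- mw_apply(P, tr)
  r <- c(0.1, 0.3, 0.7, 1.5, 3, 6, 10)
  got <- 4 * pi * mw_eval(V, r, r * 0, r * 0)
  want <- pracma::erf(sqrt(al) * r) / r
  expect_lt(max(abs(got - want)), 10 * pc)
})

test_that("operator application is linear", {
  b <- tiny_basis(kc)
  ta <- mw_project(gauss3(1.1), b, pc, L = Lc, guide = matrix(0, 3, 1))
  tb <- mw_project(gauss3(0.5, c(1, 0.5, 0)), b, pc, L = Lc,
                   guide = matrix(c(1, 0.5, 0), 3, 1))
  P <- mw_poisson_op(b, Lc, pc)
  lhs <- mw_apply(P, mw_add(list(ta, tb), c(1, 1)))
  rhs <- mw_add(list(mw_apply(P, ta), mw_apply(P, tb)), c(1, 1))
  expect_lt(mw_norm(mw_add(list(lhs, rhs), c(1, -1))) / mw_norm(lhs), 30 * pc)
})

test_that("stronger decay gives a pointwise smaller positive output", {
  b <- tiny_basis(kc)
  tr <- mw_project(gauss3(1.5), b, pc, L = Lc, guide = matrix(0, 3, 1))
  G1 <- mw_bsh_op(2.0, b, Lc, pc)
  G2 <- mw_bsh_op(0.5, b, Lc, pc)
  r <- c(0.2, 0.5, 1, 2, 4)
  v1 <- mw_eval(mw_apply(G1, tr), r, r * 0, r * 0)
  v2 <- mw_eval(mw_apply(G2, tr), r, r * 0, r * 0)
  expect_true(all(v1 <= v2 + pc))
  expect_true(all(v2 > 0))
})

test_that("output is stable under extra input refinement", {
  b <- tiny_basis(kc)
  tr <- mw_project(gauss3(1.5), b, pc, L = Lc, guide = matrix(0, 3, 1))
  P <- mw_poisson_op(b, Lc, pc)
  v1 <- mw_apply(P, tr)
  v2 <- mw_apply(P, mw_refine(tr, 1L))
  expect_lt(mw_norm(mw_add(list(v1, v2), c(1, -1))) / mw_norm(v1), 20 * pc)
})

test_that("bound-state Helmholtz solves the hydrogen fixed point", {
  # reduced-order version of the production check: phi = -2 G[v phi]
  b <- tiny_basis(kc)
  phi <- hydrogenic_1s(1)
  vphi <- function(x, y, z) {
    r <- pmax(sqrt(x^2 + y^2 + z^2), 1e-12)
    -phi(x, y, z) / r
  }
  tphi <- suppressWarnings(mw_project(phi, b, pc, L = 32,
                                      guide = matrix(0, 3, 1)))
  tv <- suppressWarnings(mw_project(vphi, b, pc, L = 32,
                                    guide = matrix(0, 3, 1), maxdepth = 16L))
  G <- mw_bsh_op(1, b, 32, pc)
  res <- mw_add(list(tphi, mw_apply(G, tv)), c(1, 2))
  expect_lt(mw_norm(res), 10 * pc)
})
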