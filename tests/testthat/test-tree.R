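# Adaptive projection, arithmetic, inner products and differentiation.

L8 <- 8

test_that("projection of a polynomial needs only the root node", {
  b <- tiny_basis(4L)
  f <- function(x, y, z) (x / 8)^2 + (y / 8) * (z / 8) + 0.5
  t <- mw_project(f, b, 1e-6, L = L8, force_scale = 0L)
  expect_equal(mwdmrg:::tree_nnode(t), 1L)
})

test_that("projection of zero gives an empty function", {
  b <- tiny_basis(4L)
  t <- mw_project(function(x, y, z) 0 * x, b, 1e-6, L = L8, force_scale = 0L)
  expect_equal(mw_norm(t), 0)
})

test_that("non-finite function values are rejected with a location", {
  b <- tiny_basis(4L)
  expect_error(
    mw_project(function(x, y, z) 1 / (x - x), b, 1e-4, L = L8),
    "non-finite")
})

test_that("Gaussian projection reproduces the quadrature-oracle norm", {
  b <- tiny_basis(6L)
  p <- 1e-5
  al <- 1.0
  t <- mw_project(gauss3(al), b, p, L = L8, guide = matrix(0, 3, 1))
  oracle <- radial_integral(function(r) (2 * al / pi)^1.5 * exp(-2 * al * r^2))
  expect_lt(abs(mw_norm(t)^2 - oracle), p)
  expect_lt(abs(mw_norm(t)^2 - 1), p)  # the Gaussian is normalized
})

test_that("projection error is within p ||f|| across a family of widths", {
  b <- tiny_basis(6L)
  p <- 1e-4
  for (al in c(0.5, 5, 50)) {
    t <- mw_project(gauss3(al), b, p, L = L8, guide = matrix(0, 3, 1),
                    guide_scale = 8L)
    # L2 error estimated against the exact function on a radial grid plus
    # the exact norm identity
    rs <- seq(0, 3 / sqrt(al), length.out = 40)
    vals <- mw_eval(t, rs, rs * 0, rs * 0)
    exact <- gauss3(al)(rs, rs * 0, rs * 0)
    expect_lt(max(abs(vals - exact)) / max(exact), 20 * p)
    expect_lt(abs(mw_norm(t) - 1), p)
  }
})

test_that("grid size is monotone non-increasing in the precision", {
  b <- tiny_basis(5L)
  f <- gauss3(2)
  sizes <- vapply(c(1e-6, 1e-4, 1e-2), function(p) {
    mwdmrg:::tree_nnode(mw_project(f, b, p, L = L8, guide = matrix(0, 3, 1)))
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("addition is exact and linear against inner products", {
  b <- tiny_basis(5L)
  p <- 1e-5
  ta <- mw_project(gauss3(1.2), b, p, L = L8, guide = matrix(0, 3, 1))
  tb <- mw_project(gauss3(0.6, c(0.5, 0, 0)), b, p, L = L8,
                   guide = matrix(c(0.5, 0, 0), 3, 1))
  tc <- mw_project(gauss3(2.5, c(-0.3, 0.2, 0)), b, p, L = L8,
                   guide = matrix(c(-0.3, 0.2, 0), 3, 1))
  expect_equal(mw_norm(mw_add(list(ta, ta), c(1, -1))), 0)
  expect_lt(abs(mw_norm(mw_add(list(ta, ta), c(1, 1))) - 2 * mw_norm(ta)), 4 * p)
  s <- mw_add(list(ta, tb), c(1, 1))
  expect_lt(abs(mw_inner(s, tc) - mw_inner(ta, tc) - mw_inner(tb, tc)), 5 * p)
})

test_that("inner products of offset Gaussians match the closed form", {
  b <- tiny_basis(6L)
  p <- 1e-5
  al <- 1.5; be <- 0.8; d <- 1.1
  ta <- mw_project(gauss3(al), b, p, L = L8, guide = matrix(0, 3, 1))
  tb <- mw_project(gauss3(be, c(d, 0, 0)), b, p, L = L8,
                   guide = matrix(c(d, 0, 0), 3, 1))
  pref <- (2 * al / pi)^0.75 * (2 * be / pi)^0.75
  exact <- pref * (pi / (al + be))^1.5 * exp(-al * be / (al + be) * d^2)
  expect_lt(abs(mw_inner(ta, tb) - exact), 10 * p)
  expect_identical(mw_inner(ta, tb), mw_inner(tb, ta))
  expect_gte(mw_inner(ta, ta), 0)
})

test_that("inner product of disjointly supported bumps is negligible", {
  b <- tiny_basis(5L)
  p <- 1e-5
  ta <- mw_project(gauss3(40, c(-4, 0, 0)), b, p, L = L8,
                   guide = matrix(c(-4, 0, 0), 3, 1), guide_scale = 7L)
  tb <- mw_project(gauss3(40, c(4, 0, 0)), b, p, L = L8,
                   guide = matrix(c(4, 0, 0), 3, 1), guide_scale = 7L)
  expect_lt(abs(mw_inner(ta, tb)), p)
})

test_that("pointwise products integrate to the Gaussian closed form", {
  b <- tiny_basis(6L)
  p <- 1e-5
  al <- 1.3; be <- 2.1
  ta <- mw_project(gauss3(al), b, p, L = L8, guide = matrix(0, 3, 1))
  tb <- mw_project(gauss3(be), b, p, L = L8, guide = matrix(0, 3, 1))
  zero <- mw_project(function(x, y, z) 0 * x, b, p, L = L8, force_scale = 0L)
  expect_equal(mw_norm(mw_multiply(ta, zero)), 0)
  # int f^2 = |f|^2 by definition of the product
  one <- mw_project(function(x, y, z) 0 * x + 1, b, p, L = L8, force_scale = 0L)
  expect_lt(abs(mw_inner(mw_multiply(ta, ta), one) - mw_norm(ta)^2), 10 * p)
  # concentric product integral: closed-form Gaussian overlap
  pref <- (2 * al / pi)^0.75 * (2 * be / pi)^0.75
  exact <- pref * (pi / (al + be))^1.5
  expect_lt(abs(mw_inner(mw_multiply(ta, tb), one) - exact), 10 * p)
})

test_that("two-scale decompose-reconstruct is exact and norm-preserving", {
  b <- tiny_basis(5L)
  t <- mw_project(gauss3(1.7), b, 1e-4, L = L8, guide = matrix(0, 3, 1))
  key <- mwdmrg:::key_of(2L, c(1L, 1L, 1L))
  skip_if_not(mwdmrg:::has_node(t, key))
  s <- mwdmrg:::get_block(t, key)
  joint <- mwdmrg:::joint_from_parent(b, s)
  # reconstruct the parent block from the descended children
  back <- mwdmrg:::filter_up(b, joint)
  expect_lt(max(abs(back - s)), 1e-13)
  # Parseval: the child representation carries the same norm
  expect_lt(abs(sum(joint^2) - sum(s^2)), 1e-13 * max(1, sum(s^2)))
})

test_that("weak derivative: constants vanish, Gaussians give 3a/2, parts", {
  b <- tiny_basis(7L)
  p <- 1e-5
  const <- mw_project(function(x, y, z) 0 * x + 1, b, p, L = L8,
                      force_scale = 1L)
  expect_lt(mw_norm(mw_deriv(const, 1L)), 1e-10)
  al <- 1.3
  tg <- mw_project(gauss3(al), b, p, L = L8, guide = matrix(0, 3, 1))
  tgr <- mw_refine(tg, 1L)
  ke <- 0
  for (ax in 1:3) {
    d <- mw_deriv(tgr, ax)
    ke <- ke + 0.5 * mw_inner(d, d)
  }
  expect_lt(abs(ke - 1.5 * al), 1e-5)
  # integration by parts: <df, g> + <f, dg> = 0 for decaying functions
  tb <- mw_project(gauss3(0.7, c(0.4, -0.2, 0)), b, p, L = L8,
                   guide = matrix(c(0.4, -0.2, 0), 3, 1))
  anti <- mw_inner(mw_deriv(tg, 1L), tb) + mw_inner(tg, mw_deriv(tb, 1L))
  expect_lt(abs(anti), 1e-4)
  # empty tree differentiates to zero
  zero <- mw_project(function(x, y, z) 0 * x, b, p, L = L8, force_scale = 0L)
  expect_equal(mw_norm(mw_deriv(zero, 2L)), 0)
})

test_that("checkpoint save/load round-trips a tree collection", {
  b <- tiny_basis(5L)
  t1 <- mw_project(gauss3(1.1), b, 1e-4, L = L8, guide = matrix(0, 3, 1))
  t2 <- mw_project(gauss3(0.5, c(1, 0, 0)), b, 1e-4, L = L8,
                   guide = matrix(c(1, 0, 0), 3, 1))
  path <- tempfile(fileext = ".chk")
  on.exit(unlink(path))
  mw_save(list(t1, t2), path)
  back <- mw_load(path)
  expect_length(back, 2L)
  expect_equal(mw_norm(mw_add(list(t1, back[[1]]), c(1, -1))), 0)
  expect_equal(mw_norm(mw_add(list(t2, back[[2]]), c(1, -1))), 0)
})

test_that("refinement past the depth cap warns and caps", {
  b <- tiny_basis(4L)
  cusp <- function(x, y, z) exp(-4 * sqrt(x^2 + y^2 + z^2))
  expect_warning(
    mw_project(cusp, b, 1e-6, L = L8, maxdepth = 6L, guide = matrix(0, 3, 1),
               guide_scale = 4L),
    "capped")
})
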