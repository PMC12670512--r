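# Dense determinant-space oracle.

test_that("one-orbital closed forms hold", {
  h <- matrix(-0.9, 1, 1)
  g <- array(0.4, c(1, 1, 1, 1))
  expect_equal(fci_solve(h, g, 2L, 0L)$energy, -1.4, tolerance = 1e-13)
  expect_equal(fci_solve(h, g, 1L, 1L)$energy, -0.9, tolerance = 1e-13)
})

test_that("two-level electron pair matches the secular closed form", {
  # two orbitals, two electrons, Hubbard-like: on-site repulsion U on
  # orbital 1, hopping t between the two doubly-occupied configurations
  # through the cross integral g[1,1,2,2] = (12|12)
  e1 <- -2.0; e2 <- -0.4; U <- 0.6; x <- 0.2
  h <- diag(c(e1, e2))
  g <- array(0, rep(2, 4))
  g[1, 1, 1, 1] <- U
  # exchange-type element (12|12): couples |11> and |22> singlets
  g[1, 1, 2, 2] <- g[2, 2, 1, 1] <- g[1, 2, 2, 1] <- g[2, 1, 1, 2] <- x
  sol <- fci_solve(h, g, 2L, 0L)
  # restrict to the closed-shell pair: H = [[2e1 + U, x], [x, 2e2]]
  Hp <- matrix(c(2 * e1 + U, x, x, 2 * e2), 2, 2)
  eref <- min(eigen(Hp, symmetric = TRUE)$values)
  # the full sector also contains open-shell singlets/triplets at e1+e2;
  # with these parameters the paired state is the ground state
  expect_equal(sol$energy, eref, tolerance = 1e-12)
})

test_that("the energy is invariant under orbital rotation", {
  M <- 3L
  inst <- rand_hg(41, M)
  s <- fci_solve(inst$h, inst$g, 3L, 1L)
  set.seed(42)
  Q <- qr.Q(qr(matrix(rnorm(M * M), M)))
  h2 <- Q %*% inst$h %*% t(Q)
  g2 <- rotate_two_body(inst$g, Q)
  s2 <- fci_solve(h2, g2, 3L, 1L)
  expect_lt(abs(s2$energy - s$energy), 1e-9)
})

test_that("RDMs reconstruct the energy and satisfy the trace rules", {
  M <- 3L
  inst <- rand_hg(43, M)
  N <- 4L
  s <- fci_solve(inst$h, inst$g, N, 0L)
  rd <- fci_rdms(s)
  expect_lt(abs(sum(inst$h * rd$gamma) + 0.5 * sum(inst$g * rd$Gamma) -
                s$energy), 1e-12)
  expect_equal(sum(diag(rd$gamma)), N, tolerance = 1e-12)
})
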