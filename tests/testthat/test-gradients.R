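# Gradient extraction: RDM route, hole-cutting route, and their
# defining identities.

test_that("doubly occupied single orbital has gamma = Gamma = 2", {
  h <- matrix(-1, 1, 1)
  g <- array(0.5, c(1, 1, 1, 1))
  mpo <- build_mpo(h, g)
  gs <- dmrg_ground_state(mpo, 1L, 2L, 0L)
  gr <- extract_gradients(gs, 1L)
  expect_equal(gr$dE_dh[1, 1], 2, tolerance = 1e-12)
  expect_equal(gr$dE_dg[1, 1, 1, 1], 2, tolerance = 1e-12)
})

test_that("gradients equal FCI density matrices with exact trace rules", {
  for (seed in c(31, 32)) {
    M <- if (seed == 31) 4L else 5L
    N <- 4L
    inst <- rand_hg(seed, M)
    fci <- fci_solve(inst$h, inst$g, N, 0L)
    rd <- fci_rdms(fci)
    mpo <- build_mpo(inst$h, inst$g, penalty = list(w = 25, N0 = N, Sz0 = 0))
    gs <- suppressWarnings(dmrg_ground_state(mpo, M, N, 0L))
    gr <- extract_gradients(gs, M)
    expect_lt(max(abs(gr$dE_dh - rd$gamma)), 1e-8)
    expect_lt(max(abs(gr$dE_dg - rd$Gamma)), 1e-8)
    expect_lt(abs(sum(diag(gr$dE_dh)) - N), 1e-10)
    pt <- matrix(0, M, M)
    for (i in 1:M) for (k in 1:M)
      pt[i, k] <- sum(vapply(1:M, function(j) gr$dE_dg[i, j, k, j], 0))
    expect_lt(max(abs(pt - (N - 1) * gr$dE_dh)), 1e-10)
    # energy reconstruction identity
    Erec <- sum(inst$h * gr$dE_dh) + 0.5 * sum(inst$g * gr$dE_dg)
    expect_lt(abs(Erec - gs$energy), 1e-9)
    # gradient symmetries
    expect_lt(max(abs(gr$dE_dh - t(gr$dE_dh))), 1e-12)
    expect_lt(max(abs(gr$dE_dg - aperm(gr$dE_dg, c(2, 1, 4, 3)))), 1e-12)
  }
})

test_that("hole-cutting and RDM evaluation agree", {
  M <- 3L
  inst <- rand_hg(33, M)
  mpo <- build_mpo(inst$h, inst$g, penalty = list(w = 25, N0 = 2, Sz0 = 0))
  gs <- suppressWarnings(dmrg_ground_state(mpo, M, 2L, 0L))
  g1 <- extract_gradients(gs, M, method = "rdm")
  g2 <- extract_gradients(gs, M, method = "hole")
  expect_lt(max(abs(g1$dE_dh - g2$dE_dh)), 1e-10)
  expect_lt(max(abs(g1$dE_dg - g2$dE_dg)), 1e-10)
})
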