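# Two-site DMRG ground-state search.

test_that("single-orbital sectors have the closed-form energies", {
  h <- matrix(-1.1, 1, 1)
  g <- array(0.7, c(1, 1, 1, 1))
  mpo <- build_mpo(h, g)
  gs2 <- dmrg_ground_state(mpo, 1L, 2L, 0L)
  expect_equal(gs2$energy, 2 * (-1.1) + 0.7, tolerance = 1e-12)
  gs1 <- dmrg_ground_state(mpo, 1L, 1L, 1L)
  expect_equal(gs1$energy, -1.1, tolerance = 1e-12)
})

test_that("DMRG reaches the FCI energy and conserves the sector", {
  inst <- rand_hg(21, 4)
  fci <- fci_solve(inst$h, inst$g, 4L, 0L)
  mpo <- build_mpo(inst$h, inst$g, penalty = list(w = 25, N0 = 4, Sz0 = 0))
  gs <- suppressWarnings(dmrg_ground_state(mpo, 4L, 4L, 0L))
  expect_true(gs$converged)
  expect_lt(abs(gs$energy - fci$energy), 1e-9)
  # variational from above
  expect_gt(gs$energy - fci$energy, -1e-9)
  # independent energy recomputation on the returned state
  e2 <- mpo_expect(gs$mps, mpo) / mwdmrg:::mps_norm2(gs$mps)
  expect_lt(abs(e2 - gs$energy), 1e-9)
  sc <- mps_sector_check(gs$mps)
  expect_lt(abs(sc$N - 4), 1e-10)
  expect_lt(abs(sc$Sz), 1e-10)
})

test_that("runs are deterministic for a fixed configuration", {
  inst <- rand_hg(22, 4)
  mpo <- build_mpo(inst$h, inst$g, penalty = list(w = 25, N0 = 2, Sz0 = 0))
  g1 <- suppressWarnings(dmrg_ground_state(mpo, 4L, 2L, 0L))
  g2 <- suppressWarnings(dmrg_ground_state(mpo, 4L, 2L, 0L))
  expect_identical(g1$energy, g2$energy)
  expect_identical(g1$energy_trace, g2$energy_trace)
})

test_that("infeasible sectors are refused", {
  inst <- rand_hg(23, 2)
  mpo <- build_mpo(inst$h, inst$g)
  expect_error(dmrg_ground_state(mpo, 2L, 5L, 1L), "infeasible")
})

test_that("sweep energies are non-increasing at fixed accuracy settings", {
  inst <- rand_hg(24, 5)
  mpo <- build_mpo(inst$h, inst$g, penalty = list(w = 25, N0 = 4, Sz0 = 0))
  gs <- suppressWarnings(dmrg_ground_state(mpo, 5L, 4L, 0L))
  tr <- gs$energy_trace
  expect_true(all(diff(tr) < 1e-8))
})
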