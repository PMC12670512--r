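# Configuration handling, artifacts, determinism and the orbital-agnostic
# standalone mode.

test_that("flat configuration files parse and validate", {
  cfgp <- tempfile(fileext = ".cfg")
  xyzp <- tempfile(fileext = ".xyz")
  on.exit(unlink(c(cfgp, xyzp)))
  writeLines(c("2", "h2", "H 0 0 0", "H 0 0 0.7414"), xyzp)
  writeLines(c("# test configuration", paste0("geometry: ", xyzp),
               "M: 2", "p: 1e-3", "k = 5", "delta: 1e-4"), cfgp)
  cfg <- validate_config(read_config(cfgp))
  expect_equal(cfg$M, 2L)
  expect_equal(cfg$p, 1e-3)
  expect_equal(cfg$k, 5L)
  expect_equal(cfg$mode, "optimize")
  # invalid requests fail fast
  expect_error(validate_config(list(geometry = xyzp, M = 0)), "M")
  expect_error(validate_config(list(geometry = "nope.xyz", M = 1)),
               "not found")
  expect_error(validate_config(list(geometry = xyzp, M = 2, mode = "bogus")),
               "mode")
  expect_error(read_config({
    bad <- tempfile()
    writeLines("no separator here", bad)
    bad
  }), "malformed")
})

test_that("a full run writes artifacts, reruns bit-identically, and the
           standalone solver reproduces its final energy", {
  xyzp <- tempfile(fileext = ".xyz")
  out1 <- tempfile()
  out2 <- tempfile()
  on.exit(unlink(c(xyzp, out1, out2), recursive = TRUE))
  writeLines(c("1", "hydrogen", "H 0 0 0"), xyzp)
  cfg <- validate_config(list(geometry = xyzp, M = 1, p = 1e-3, k = 5,
                              delta = 1e-3, L = 16, maxiter = 8, out = out1))
  fit1 <- run_optimization(cfg)
  expect_true(fit1$converged)
  expect_identical(attr(fit1, "status"), 0L)
  expect_true(file.exists(file.path(out1, "trace.csv")))
  expect_true(file.exists(file.path(out1, "summary.json")))
  expect_true(file.exists(file.path(out1, "orbitals.chk")))
  expect_true(file.exists(file.path(out1, "integrals.fcidump")))
  # determinism: a rerun writes an identical trace
  cfg$out <- out2
  fit2 <- run_optimization(cfg)
  expect_identical(readLines(file.path(out1, "trace.csv")),
                   readLines(file.path(out2, "trace.csv")))
  # orbital-agnostic mode on the emitted integrals reproduces the final
  # ground-state energy
  res <- run_dmrg_file(file.path(out1, "integrals.fcidump"))
  expect_lt(abs(res$energy - fit1$energy), 1e-8)
})
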