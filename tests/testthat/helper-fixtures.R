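# Shared fixtures: all test inputs are generated in code.

# normalized 3D Gaussian centered at R0 with exponent alpha
gauss3 <- function(alpha, R0 = c(0, 0, 0)) {
  force(alpha); force(R0)
  function(x, y, z)
    (2 * alpha / pi)^0.75 *
      exp(-alpha * ((x - R0[1])^2 + (y - R0[2])^2 + (z - R0[3])^2))
}

# hydrogenic 1s orbital for nuclear charge Z
hydrogenic_1s <- function(Z) {
  force(Z)
  function(x, y, z) sqrt(Z^3 / pi) * exp(-Z * sqrt(x^2 + y^2 + z^2))
}

# random valid (h, g): symmetric h, positive-semidefinite 8-fold-symmetric g
rand_hg <- function(seed, M, gscale = 0.5) {
  set.seed(seed)
  h <- matrix(rnorm(M * M), M)
  h <- (h + t(h)) / 2
  g <- array(0, rep(M, 4))
  for (q in 1:2) {
    A <- matrix(rnorm(M * M), M)
    A <- (A + t(A)) / 2
    for (i in 1:M) for (j in 1:M) for (k in 1:M) for (l in 1:M)
      g[i, j, k, l] <- g[i, j, k, l] + gscale * A[i, k] * A[j, l]
  }
  list(h = h, g = g)
}

# radial quadrature oracle for integrals of spherically symmetric functions:
# Int f(r) 4 pi r^2 dr by adaptive Gauss-Kronrod
radial_integral <- function(f, upper = Inf) {
  stats::integrate(function(r) 4 * pi * r^2 * f(r), 0, upper,
                   rel.tol = 1e-10)$value
}

# cached small basis
tiny_basis <- local({
  env <- new.env()
  function(k = 5L) {
    key <- as.character(k)
    if (is.null(env[[key]])) env[[key]] <- mw_basis(k)
    env[[key]]
  }
})
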