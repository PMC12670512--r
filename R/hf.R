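# Independent integral-equation Hartree-Fock solver on the multiwavelet
# stack, for closed-shell two-electron systems described by a single
# doubly-occupied orbital (the determinant limit M = N/2 of the
# correlated optimizer).  The orbital is iterated directly on the Fock
# fixed point  phi = -2 G_mu[(v + J) phi],  mu = sqrt(-2 eps),
# eps = <phi|h + J|phi>, with no density-matrix or multiplier machinery;
# this provides the reference for the determinant-limit equivalence of
# the Lagrangian optimizer.

#' Multiwavelet Hartree-Fock for a closed-shell electron pair
#'
#' @param mol an \code{mw_molecule} with 2 electrons.
#' @param k polynomial order.
#' @param prec multiwavelet precision.
#' @param L domain half-width (bohr).
#' @param tol SCF energy convergence (Hartree, default 1e-7).
#' @param maxiter maximum SCF iterations.
#' @param verbose print per-iteration energies.
#' @return list with \code{energy} (total, Hartree), \code{eps} (orbital
#'   eigenvalue), \code{orbital} (an \code{mw_tree}), \code{trace},
#'   \code{converged}.
#' @export
mw_hf <- function(mol, k = 7L, prec = 1e-4, L = 32, tol = 1e-7,
                  maxiter = 40L, verbose = FALSE) {
  if (mol$nelec != 2L)
    stop("the Hartree-Fock reference handles closed-shell 2-electron systems")
  basis <- mw_basis(k)
  enuc <- nuclear_repulsion(mol)
  vtree <- nuclear_potential(mol, basis, prec, L)
  pois <- mw_poisson_op(basis, L, prec)
  orbs <- guess_orbitals(mol, 1L, basis, prec, L)
  phi <- orbs$orb[[1]]

  E_prev <- NA
  trace <- numeric(0)
  converged <- FALSE
  eps <- NA
  for (it in seq_len(maxiter)) {
    rho <- mw_multiply(phi, phi)
    J <- mw_add(list(mw_apply(pois, rho)), 4 * pi, prune = FALSE)
    # one-electron pieces
    rphi <- mw_refine(phi, 1L)
    T11 <- 0
    for (ax in 1:3) {
      d <- mw_deriv(rphi, ax)
      T11 <- T11 + 0.5 * mw_inner(d, d)
    }
    vphi <- mw_multiply(vtree, phi, prec = phi$prec)
    V11 <- mw_inner(phi, vphi)
    Jphi <- mw_multiply(J, phi)
    J11 <- mw_inner(phi, Jphi)
    h11 <- T11 + V11
    eps <- h11 + J11
    E <- 2 * h11 + J11 + enuc
    trace <- c(trace, E)
    if (verbose) message(sprintf("HF iter %2d  E = %.8f  eps = %.6f", it, E, eps))
    if (!is.na(E_prev) && abs(E - E_prev) < tol) {
      converged <- TRUE
      break
    }
    E_prev <- E
    ceff <- min(eps, -0.05)
    cker <- -exp(round(log(-ceff) * 40) / 40)  # snap: operator reuse
    G <- mw_bsh_op(cker, basis, L, prec, is_coeff = TRUE)
    if (abs(eps - cker) > 1e-14) {
      # level shift: move the snap/positivity residual into the source
      src <- mw_add(list(vphi, Jphi, phi), c(1, 1, cker - eps))
    } else {
      src <- mw_add(list(vphi, Jphi), c(1, 1))
    }
    phi_new <- mw_apply(G, src)
    phi_new <- mw_add(list(phi_new), -2, prune = FALSE)
    nrm <- mw_norm(phi_new)
    phi <- mw_add(list(phi_new), 1 / nrm, prune = FALSE)
  }
  list(energy = trace[length(trace)], eps = eps, orbital = phi,
       trace = trace, converged = converged, nuclear_repulsion = enuc)
}
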