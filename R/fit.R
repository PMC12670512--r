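# User-facing model interface: a single fitting function returning a
# classed object with the usual accessor methods.

#' Fit: multiwavelet + DMRG wavefunction optimization
#'
#' \code{mwdmrg()} is the package's main entry point.  It optimizes a set
#' of \code{M} real orbitals for the given molecule at the basis-set
#' limit: the orbitals are adaptive multiwavelet functions, the
#' correlated energy and its integral gradients come from a DMRG solve of
#' the second-quantized Hamiltonian, and the orbitals are updated through
#' bound-state Helmholtz inversions in the natural-orbital basis until
#' the total energy is converged to \code{delta}.
#'
#' @inheritParams mw_optimize
#' @param ... passed to \code{\link{mw_optimize}}.
#' @return an object of class \code{mwdmrg_fit} with components
#'   \code{energy} (total energy, Hartree), \code{trace} (per-iteration
#'   energies and kernel coefficients), \code{orbitals}, \code{integrals},
#'   \code{converged}.
#' @examples
#' \dontrun{
#' h_atom <- mw_molecule("H", matrix(0, 3, 1))
#' fit <- mwdmrg(h_atom, M = 1, k = 7, prec = 1e-5)
#' print(fit)        # converged total energy (-0.5 Ha for hydrogen)
#' plot(fit)         # energy trace across iterations
#' }
#' @export
mwdmrg <- function(mol, M, ...) mw_optimize(mol, M, ...)

#' @export
print.mwdmrg_fit <- function(x, ...) {
  cat("Multiwavelet + DMRG wavefunction optimization\n")
  cat(sprintf("  molecule: %s  (N = %d electrons, M = %d orbitals)\n",
              paste(x$molecule$symbols, collapse = ""), x$N, x$M))
  cat(sprintf("  settings: k = %d, p = %g, delta = %g Ha, L = %g bohr\n",
              x$k, x$prec, x$delta, x$L))
  cat(sprintf("  %s after %d iteration(s)\n",
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  total energy: %.8f Ha\n", x$energy))
  invisible(x)
}

#' @export
summary.mwdmrg_fit <- function(object, ...) {
  x <- object
  cat("Multiwavelet + DMRG wavefunction optimization\n\n")
  print(x$trace, row.names = FALSE)
  cat(sprintf("\nnuclear repulsion: %.8f Ha\n", x$nuclear_repulsion))
  cat(sprintf("final total energy: %.8f Ha (%s)\n", x$energy,
              if (x$converged) "converged" else "not converged"))
  if (length(x$kernel_hist)) {
    last <- x$kernel_hist[[length(x$kernel_hist)]]
    cat("final Helmholtz kernel coefficients (eps'_mm / Lambda_m):\n")
    print(round(last, 6))
    if (x$fallback_engaged)
      cat("note: the positive-coefficient fallback engaged during the run\n")
  }
  invisible(x)
}

#' @export
coef.mwdmrg_fit <- function(object, ...) {
  last <- object$kernel_hist[[length(object$kernel_hist)]]
  out <- cbind(kernel_coeff = last)
  rownames(out) <- paste0("orbital", seq_len(nrow(out)))
  out
}

#' @export
plot.mwdmrg_fit <- function(x, ...) {
  plot(x$trace$iter, x$trace$energy, type = "b", pch = 19,
       xlab = "iteration", ylab = "total energy (Ha)",
       main = "energy convergence", ...)
  invisible(x)
}

#' Energy trace of a fit
#' @param x an \code{mwdmrg_fit}.
#' @return numeric vector of per-iteration total energies (Hartree).
#' @export
energy_trace <- function(x) x$trace$energy
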