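# Lagrangian self-consistent orbital optimization.
#
# One iteration:  integrals -> ground-state solve -> energy gradients ->
# symmetrization -> multipliers -> rotation to the gradient-diagonal
# (natural-orbital) basis -> per-orbital bound-state Helmholtz update ->
# Loewdin orthonormalization.  The loop stops when the total energy moves
# by less than delta between iterations.
#
# Convention: dE_dg as extracted equals the spin-free 2-RDM Gamma, so the
# energy is E = sum h*dE_dh + (1/2) sum g*dE_dg and the symmetrized
# two-body gradient entering the update equations carries a factor 1/2
# relative to Gamma.  In the single-orbital closed-shell limit this makes
# the fixed point the Hartree-Fock equation (h + J) phi = (h11 + g1111)
# phi, which anchors the sign and factor conventions.

#' Symmetrize raw energy gradients
#'
#' @param raw an \code{mw_gradients} from \code{\link{extract_gradients}}.
#' @return list with \code{dE1} (symmetric M x M) and \code{dE2} (M^4 with
#'   the two-electron index symmetry), where \code{dE1} is the symmetrized
#'   1-RDM and \code{dE2} is half the symmetrized 2-RDM (the true
#'   derivative of E with respect to one two-body coefficient).
#' @export
symmetrize_gradients <- function(raw) {
  A <- raw$dE_dh
  B <- raw$dE_dg
  dE1 <- (A + t(A)) / 2
  Bs <- (B + aperm(B, c(2, 1, 4, 3)) + aperm(B, c(3, 2, 1, 4)) +
           aperm(B, c(2, 3, 4, 1))) / 4
  list(dE1 = dE1, dE2 = Bs / 2)
}

#' Symmetrized Lagrange multiplier matrix
#'
#' \eqn{\bar\varepsilon_{mn} = \sum_j \partial E^{(1)}_{mj} h_{nj} +
#' 2 \sum_{jkl} \partial E^{(2)}_{mjkl} g_{njkl}}, explicitly symmetrized.
#'
#' @param sg symmetrized gradients from \code{\link{symmetrize_gradients}}.
#' @param h,g integrals.
#' @return symmetric M x M matrix (Hartree).
#' @export
multipliers <- function(sg, h, g) {
  M <- nrow(h)
  eb <- sg$dE1 %*% h
  eb <- eb + 2 * matrix(sg$dE2, M, M^3) %*% t(matrix(g, M, M^3))
  (eb + t(eb)) / 2
}

#' Diagonalize the one-body gradient and rotate
#'
#' Finds the orthogonal \eqn{U} with \eqn{\partial E^{(1)} = U^T \Lambda U}
#' (\eqn{\Lambda} sorted descending, column signs fixed so each
#' eigenvector's largest component is positive), rotates the orbitals and
#' the multipliers; the two-body gradient keeps its unrotated indices and
#' is contracted against rows of \eqn{U} in the update step.
#'
#' @param sg symmetrized gradients.
#' @param eps_bar multiplier matrix.
#' @param h one-body integrals.
#' @param orbs an \code{mw_orbitals} (unrotated).
#' @return list with \code{U}, \code{Lambda}, \code{eps_prime}
#'   (\eqn{U\bar\varepsilon U^T}), \code{h_rot}, and \code{orbs_rot}.
#' @export
diagonalize_rotate <- function(sg, eps_bar, h, orbs) {
  ev <- eigen(sg$dE1, symmetric = TRUE)
  ord <- order(ev$values, decreasing = TRUE)
  Lambda <- ev$values[ord]
  V <- ev$vectors[, ord, drop = FALSE]
  for (c_ in seq_len(ncol(V))) {
    imax <- which.max(abs(V[, c_]))
    if (V[imax, c_] < 0) V[, c_] <- -V[, c_]
  }
  if (any(abs(Lambda) < 1e-10))
    stop("(near-)zero occupation eigenvalue: an orbital is unoccupied at ",
         "this M; reduce M or perturb the initial guess")
  U <- t(V)
  list(U = U, Lambda = Lambda,
       eps_prime = U %*% eps_bar %*% t(U),
       h_rot = U %*% h %*% t(U),
       orbs_rot = mw_rotate(orbs, U))
}

#' Bound-state Helmholtz update of one rotated orbital
#'
#' Solves the self-consistent equation by inverting the shifted kinetic
#' operator with the Helmholtz Green's function of exponent
#' \eqn{\mu_m = \sqrt{-2\,\varepsilon'_{mm}/\Lambda_m}}.  If the kernel
#' coefficient is not safely negative, a level shift to a floor value is
#' applied and the residual moved into the source term.
#'
#' @param m orbital index (in the rotated basis).
#' @param rot result of \code{\link{diagonalize_rotate}}.
#' @param sg symmetrized gradients.
#' @param orbs unrotated orbitals (for the two-body term).
#' @param vtree nuclear potential tree.
#' @param pair_pots list of pair potentials \eqn{\hat g_{jl}} keyed
#'   \code{"j.l"} with \eqn{j \le l}.
#' @param prec operator precision.
#' @param shift_floor fallback kernel coefficient (Hartree); engaged when
#'   \eqn{\varepsilon'_{mm}/\Lambda_m \ge -0.01}.
#' @return list with the updated \code{tree}, the kernel coefficient
#'   \code{coeff}, and \code{fallback} flag.
#' @export
update_orbital <- function(m, rot, sg, orbs, vtree, pair_pots, prec,
                           shift_floor = -0.05) {
  M <- orbs$M
  Lam <- rot$Lambda[m]
  coeff <- rot$eps_prime[m, m] / Lam
  fallback <- coeff >= -0.01
  # snap the kernel coefficient onto a coarse logarithmic grid so the
  # Helmholtz operators are reused across iterations; the residual is
  # moved into the source exactly like the positive-coefficient fallback
  cker <- if (fallback) shift_floor else snap_round(coeff)
  mu <- sqrt(-2 * cker)
  basis <- orbs$orb[[1]]$basis
  L <- orbs$orb[[1]]$L
  G <- mw_bsh_op(mu, basis, L, prec)

  phi_rot_m <- rot$orbs_rot$orb[[m]]
  terms <- list(mw_multiply(vtree, phi_rot_m, prec = phi_rot_m$prec))
  wts <- 1
  # two-body source: (2/Lambda_m) sum_jkl [U dE2]_{mjkl} ghat_jl phi_k
  C <- rot$U %*% matrix(sg$dE2, M, M^3)   # row m = sum_i U_mi dE2_ijkl
  Cm <- array(C[m, ], c(M, M, M))
  for (j in 1:M) for (l in 1:M) for (k in 1:M) {
    w <- 2 * Cm[j, k, l] / Lam
    if (abs(w) < 1e-14) next
    key <- paste(min(j, l), max(j, l), sep = ".")
    terms[[length(terms) + 1L]] <- mw_multiply(pair_pots[[key]], orbs$orb[[k]])
    wts <- c(wts, w)
  }
  # off-diagonal multipliers (rotated orbitals)
  for (j in seq_len(M)) {
    if (j == m) next
    w <- -rot$eps_prime[m, j] / Lam
    if (abs(w) < 1e-14) next
    terms[[length(terms) + 1L]] <- rot$orbs_rot$orb[[j]]
    wts <- c(wts, w)
  }
  if (abs(coeff - cker) > 1e-14) {
    terms[[length(terms) + 1L]] <- phi_rot_m
    wts <- c(wts, cker - coeff)
  }
  src <- mw_add(terms, wts)
  newphi <- mw_apply(G, src)
  newphi <- mw_add(list(newphi), -2, prune = FALSE)
  list(tree = newphi, coeff = coeff, fallback = fallback)
}

# deterministic initial guess: one Gaussian per nucleus (exponent from Z),
# then polynomial-times-Gaussian shells until M functions
guess_orbitals <- function(mol, M, basis, prec, L) {
  funs <- list()
  for (a in seq_along(mol$Z)) {
    al <- 0.2709 * mol$Z[a]^2
    R <- mol$coords[, a]
    funs[[length(funs) + 1L]] <- local({
      al0 <- al; R0 <- R
      function(x, y, z)
        (2 * al0 / pi)^0.75 * exp(-al0 * ((x - R0[1])^2 + (y - R0[2])^2 + (z - R0[3])^2))
    })
  }
  polys <- list(function(x, y, z) x, function(x, y, z) y, function(x, y, z) z,
                function(x, y, z) x * y, function(x, y, z) x * z,
                function(x, y, z) y * z, function(x, y, z) x^2 - y^2,
                function(x, y, z) 2 * z^2 - x^2 - y^2,
                function(x, y, z) x^2 + y^2 + z^2)
  cen <- rowMeans(mol$coords)
  e <- 0L
  while (length(funs) < M) {
    e <- e + 1L
    pfun <- polys[[(e - 1L) %% length(polys) + 1L]]
    al <- 0.6 / 1.4^((e - 1L) %/% length(polys))
    funs[[length(funs) + 1L]] <- local({
      p0 <- pfun; al0 <- al; c0 <- cen
      function(x, y, z) {
        dx <- x - c0[1]; dy <- y - c0[2]; dz <- z - c0[3]
        p0(dx, dy, dz) * exp(-al0 * (dx^2 + dy^2 + dz^2))
      }
    })
  }
  orbs <- lapply(funs[seq_len(M)], function(f)
    suppressWarnings(mw_project(f, basis, prec, L = L, guide = mol$coords)))
  mw_lowdin(mw_orbitals(orbs))
}

#' Self-consistent multiresolution + DMRG orbital optimization
#'
#' The main fitting routine: molecular orbitals represented as adaptive
#' multiwavelet functions are optimized at the basis-set limit, with the
#' correlated energy and its integral gradients supplied by a DMRG solve
#' of the second-quantized Hamiltonian in the current orbital set.
#'
#' @param mol an \code{mw_molecule} (or an XYZ path).
#' @param M number of spatial orbitals (\eqn{M \ge N/2}).
#' @param k multiwavelet polynomial order (default 9).
#' @param prec multiwavelet precision \eqn{p} (default 1e-5).
#' @param delta energy convergence threshold in Hartree (default 1e-5).
#' @param L cubic domain half-width in bohr (default 32).
#' @param maxiter maximum optimization iterations (default 25).
#' @param Sz2 twice the spin projection (default \code{N \%\% 2}).
#' @param dmrg list of DMRG options (see \code{\link{dmrg_ground_state}}).
#' @param penalty_w sector penalty strength (default 25 Hartree).
#' @param verbose print per-iteration progress.
#' @return an object of class \code{mwdmrg_fit}; see
#'   \code{\link{print.mwdmrg_fit}}, \code{summary}, \code{coef},
#'   \code{plot}.
#' @export
mw_optimize <- function(mol, M, k = 9L, prec = 1e-5, delta = 1e-5, L = 32,
                        maxiter = 25L, Sz2 = NULL, dmrg = list(),
                        penalty_w = 25, verbose = FALSE) {
  if (is.character(mol)) mol <- read_xyz(mol)
  N <- mol$nelec
  if (is.null(Sz2)) Sz2 <- N %% 2L
  if (M < ceiling(N / 2)) stop("M must be at least N/2")
  basis <- mw_basis(k)
  enuc <- nuclear_repulsion(mol)
  vtree <- nuclear_potential(mol, basis, prec, L)
  pois <- mw_poisson_op(basis, L, prec)
  orbs <- guess_orbitals(mol, M, basis, prec, L)

  trace <- data.frame(iter = integer(), energy = numeric(),
                      dE = numeric(), min_kernel_coeff = numeric(),
                      dmrg_sweeps = integer())
  kernel_hist <- list()
  fallback_any <- FALSE
  E_prev <- NA
  converged <- FALSE
  state <- NULL
  ints <- NULL

  for (it in seq_len(maxiter)) {
    h <- mw_one_body(orbs, vtree)
    g <- mw_two_body(orbs, pois)
    pair_pots <- attr(g, "pair_pots")
    mpo <- build_mpo(h, g, penalty = list(w = penalty_w, N0 = N, Sz0 = Sz2 / 2))
    state <- suppressWarnings(
      dmrg_ground_state(mpo, M, N, Sz2, cfg = dmrg))
    E <- state$energy + enuc
    dE <- if (is.na(E_prev)) NA else E - E_prev

    raw <- extract_gradients(state, M)
    sg <- symmetrize_gradients(raw)
    eps_bar <- multipliers(sg, h, g)
    rot <- diagonalize_rotate(sg, eps_bar, h, orbs)
    coeffs <- rot$eps_prime[cbind(1:M, 1:M)] / rot$Lambda
    kernel_hist[[it]] <- coeffs
    trace <- rbind(trace, data.frame(
      iter = it, energy = E, dE = ifelse(is.na(dE), NA, dE),
      min_kernel_coeff = min(coeffs), dmrg_sweeps = state$nsweep))
    if (verbose)
      message(sprintf("iter %2d  E = %.8f  dE = %s  min eps'/Lambda = %.4f",
                      it, E, ifelse(is.na(dE), "NA", sprintf("%.2e", dE)),
                      min(coeffs)))
    if (!is.na(dE) && abs(dE) < delta) {
      converged <- TRUE
      ints <- list(h = h, g = g, s = mw_overlap(orbs), ecore = enuc)
      break
    }

    newtrees <- vector("list", M)
    for (m in 1:M) {
      up <- update_orbital(m, rot, sg, orbs, vtree, pair_pots, prec)
      fallback_any <- fallback_any || up$fallback
      newtrees[[m]] <- up$tree
    }
    orbs <- mw_lowdin(mw_orbitals(newtrees))
    E_prev <- E
    ints <- list(h = h, g = g, s = NULL, ecore = enuc)
  }

  structure(list(molecule = mol, M = M, N = N, Sz2 = Sz2,
                 k = k, prec = prec, delta = delta, L = L,
                 energy = trace$energy[nrow(trace)],
                 trace = trace, kernel_hist = kernel_hist,
                 converged = converged, iterations = nrow(trace),
                 fallback_engaged = fallback_any,
                 orbitals = orbs, integrals = ints, ground_state = state,
                 nuclear_repulsion = enuc),
            class = "mwdmrg_fit")
}

# logarithmic snap grid for Helmholtz kernel coefficients (2.5% spacing)
snap_round <- function(coeff) -exp(round(log(-coeff) * 40) / 40)
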