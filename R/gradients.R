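# Energy gradients with respect to the one- and two-body integrals,
# extracted from the converged tensor-network ground state.
#
# Two routes are implemented and must agree:
#   "rdm"  - direct evaluation of the spin-free reduced density matrices
#            gamma_ij = <E_ij>, Gamma_ijkl = <e_ijkl> as transfer-matrix
#            correlation functions of the MPS;
#   "hole" - contraction of the MPS-MPO-MPS energy network with the
#            coefficient's operator family isolated (the generator MPO of
#            that coefficient), i.e. the network with the coefficient
#            removed.
# Because the Hamiltonian is linear in (h, g) with E = sum h gamma +
# 1/2 sum g Gamma, these expectations are the energy gradients:
# dE/dh_ij = gamma_ij and (per the convention used throughout) dE_dg is
# reported as Gamma itself.

# expectation of one spin-resolved operator string (list of c(site, kind))
string_expect <- function(mps, rhoR, M, ops) {
  mats <- op_string(M, ops)
  span <- which(!vapply(mats, is.null, TRUE))
  if (!length(span)) return(1)
  smin <- min(span)
  smax <- max(span)
  oplist <- lapply(smin:smax, function(s) {
    if (is.null(mats[[s]])) diag(1, 4) else mats[[s]]
  })
  cpp_mps_string_expect(mps, rhoR, smin, smax, oplist)
}

#' Extract energy gradients from a ground state
#'
#' @param state an \code{mw_dmrg_state} (left-canonical MPS).
#' @param M number of orbitals/sites.
#' @param method \code{"rdm"} (default, fast) or \code{"hole"}
#'   (per-coefficient generator-network contraction; used as cross-check).
#' @param mpo ignored (the generator networks are rebuilt per
#'   coefficient).
#' @return list of class \code{mw_gradients}: \code{dE_dh} (M x M,
#'   equals the spin-free 1-RDM) and \code{dE_dg} (M^4, equals the
#'   spin-free 2-RDM).
#' @export
extract_gradients <- function(state, M, method = c("rdm", "hole"), mpo = NULL) {
  method <- match.arg(method)
  mps <- state$mps
  nrm2 <- mps_norm2(mps)
  if (abs(nrm2 - 1) > 1e-8) {
    warning("state not normalized (|psi|^2 = ", format(nrm2), "); normalizing")
    mps <- mps_left_canonical(mps)
  }
  if (method == "rdm") {
    rhoR <- cpp_mps_rho_right(mps)
    dh <- matrix(0, M, M)
    for (i in 1:M) for (j in i:M) {
      v <- string_expect(mps, rhoR, M, list(c(i, "cu+"), c(j, "cu"))) +
        string_expect(mps, rhoR, M, list(c(i, "cd+"), c(j, "cd")))
      dh[i, j] <- dh[j, i] <- v
    }
    dg <- array(0, rep(M, 4))
    sp <- c("u", "d")
    for (i in 1:M) for (j in 1:M) for (k in 1:M) for (l in 1:M) {
      # e_ijkl = e_jilk: compute each unordered representative once
      key1 <- ((i - 1) * M + (j - 1)) * M^2 + (k - 1) * M + l
      key2 <- ((j - 1) * M + (i - 1)) * M^2 + (l - 1) * M + k
      if (key2 < key1) next
      v <- 0
      for (s1 in 1:2) for (s2 in 1:2) {
        v <- v + string_expect(mps, rhoR, M, list(
          c(i, paste0("c", sp[s1], "+")), c(j, paste0("c", sp[s2], "+")),
          c(l, paste0("c", sp[s2])), c(k, paste0("c", sp[s1]))))
      }
      dg[i, j, k, l] <- v
      dg[j, i, l, k] <- v
    }
  } else {
    dh <- matrix(0, M, M)
    for (i in 1:M) for (j in 1:M) {
      dh[i, j] <- mpo_expect(mps, generator_mpo_E(M, i, j))
    }
    dh <- (dh + t(dh)) / 2
    dg <- array(0, rep(M, 4))
    for (i in 1:M) for (j in 1:M) for (k in 1:M) for (l in 1:M) {
      dg[i, j, k, l] <- mpo_expect(mps, generator_mpo_e(M, i, j, k, l))
    }
  }
  structure(list(dE_dh = dh, dE_dg = dg), class = "mw_gradients")
}

#' Expectation value of an MPO against an MPS
#' @param mps list of site tensors.
#' @param mpo an \code{mw_mpo}.
#' @return \eqn{\langle\psi| W |\psi\rangle} (no normalization applied).
#' @export
mpo_expect <- function(mps, mpo) {
  L <- array(1, c(1, 1, 1))
  for (s in seq_along(mps)) {
    L <- env_step_left(L, mps[[s]], mpo$W[[s]])
  }
  L[1, 1, 1]
}

#' Particle number and spin projection of a state
#' @param mps list of site tensors (left-canonical).
#' @return list with \code{N}, \code{Sz}, \code{N2}, \code{Sz2exp}
#'   (expectations of the operators and their squares).
#' @export
mps_sector_check <- function(mps) {
  M <- length(mps)
  rhoR <- cpp_mps_rho_right(mps)
  one <- function(op, s) {
    cpp_mps_string_expect(mps, rhoR, s, s, list(op))
  }
  two <- function(op1, s1, op2, s2) {
    if (s1 == s2) return(one(op1 %*% op2, s1))
    ops <- lapply(min(s1, s2):max(s1, s2), function(s) {
      if (s == s1) op1 else if (s == s2) op2 else diag(1, 4)
    })
    cpp_mps_string_expect(mps, rhoR, min(s1, s2), max(s1, s2), ops)
  }
  Nv <- sum(vapply(1:M, function(s) one(lop$n, s), 0))
  Szv <- sum(vapply(1:M, function(s) one(lop$sz, s), 0))
  N2 <- 0
  Sz2 <- 0
  for (s1 in 1:M) for (s2 in 1:M) {
    N2 <- N2 + two(lop$n, s1, lop$n, s2)
    Sz2 <- Sz2 + two(lop$sz, s1, lop$sz, s2)
  }
  list(N = Nv, Sz = Szv, N2 = N2, Sz2exp = Sz2)
}
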