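# Two-site DMRG ground-state search over matrix product states.
#
# MPS site tensors are arrays (chi_l, 4, chi_r).  Left environments
# L[[s]] have dimensions (chi_bra, D, chi_ket) and contain the contraction
# of bra-MPO-ket over sites < s; right environments R[[s]] mirror this for
# sites > s.  The (N, Sz) sector is selected by the quadratic penalty
# carried by the MPO (see build_mpo) together with an in-sector initial
# state; conservation is verified on the converged state.

mps_dims <- function(mps) vapply(mps, function(a) dim(a)[3], 0L)

# random in-sector superposition of determinant product states
mps_random_sector <- function(M, N, Sz2, seed = 0L, nstate = 8L) {
  basis <- fci_space(M, N, Sz2)
  if (!length(basis)) stop("infeasible (N, Sz) sector")
  rs <- sample_int_det(length(basis), min(nstate, length(basis)), seed)
  coef <- det_runif(length(rs), seed + 1L)
  coef <- coef / sqrt(sum(coef^2))
  # site-local state index 1..4 for each selected determinant
  states <- lapply(basis[rs], function(mask) {
    st <- integer(M)
    for (s in 1:M) {
      up <- bitwAnd(mask, bitwShiftL(1L, 2L * (s - 1L))) != 0
      dn <- bitwAnd(mask, bitwShiftL(1L, 2L * (s - 1L) + 1L)) != 0
      st[s] <- 1L + up + 2L * dn
    }
    st
  })
  K <- length(states)
  mps <- vector("list", M)
  for (s in 1:M) {
    dl <- if (s == 1) 1L else K
    dr <- if (s == M) 1L else K
    A <- array(0, c(dl, 4, dr))
    for (kk in 1:K) {
      a <- if (s == 1) 1L else kk
      b <- if (s == M) 1L else kk
      A[a, states[[kk]][s], b] <- if (s == 1) coef[kk] else 1
    }
    mps[[s]] <- A
  }
  mps_compress(mps, chimax = K, cutoff = 1e-14)
}

# deterministic pseudo-random helpers that do not touch the global RNG
sample_int_det <- function(n, k, seed) {
  u <- det_runif(n, seed)
  order(u)[seq_len(k)]
}

det_runif <- function(n, seed) {
  x <- numeric(n)
  state <- (as.numeric(seed) + 12345) %% 2147483647
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    x[i] <- state / 2147483647
  }
  x
}

# overlap <a|b> of two MPS on the same chain
mps_overlap <- function(a, b) {
  E <- matrix(1, 1, 1)
  for (s in seq_along(a)) {
    da <- dim(a[[s]]); db <- dim(b[[s]])
    acc <- matrix(0, da[3], db[3])
    for (p in 1:4) {
      Ap <- matrix(a[[s]][, p, ], da[1], da[3])
      Bp <- matrix(b[[s]][, p, ], db[1], db[3])
      acc <- acc + t(Ap) %*% E %*% Bp
    }
    E <- acc
  }
  E[1, 1]
}

mps_norm2 <- function(mps) {
  E <- matrix(1, 1, 1)
  for (A in mps) {
    d <- dim(A)
    acc <- matrix(0, d[3], d[3])
    for (p in 1:4) {
      Ap <- matrix(A[, p, ], d[1], d[3])
      acc <- acc + t(Ap) %*% E %*% Ap
    }
    E <- acc
  }
  E[1, 1]
}

# left-to-right QR canonicalization; returns left-canonical MPS
mps_left_canonical <- function(mps) {
  M <- length(mps)
  for (s in 1:(M - 1)) {
    d <- dim(mps[[s]])
    qrr <- qr(matrix(mps[[s]], d[1] * 4, d[3]))
    Q <- qr.Q(qrr)
    Rm <- qr.R(qrr)
    r <- ncol(Q)
    mps[[s]] <- array(Q, c(d[1], 4, r))
    dn <- dim(mps[[s + 1]])
    mps[[s + 1]] <- array(Rm %*% matrix(mps[[s + 1]], dn[1], 4 * dn[3]),
                          c(r, 4, dn[3]))
  }
  nrm <- sqrt(sum(mps[[M]]^2))
  if (nrm > 0) mps[[M]] <- mps[[M]] / nrm
  attr(mps, "norm") <- nrm
  mps
}

# SVD compression to chimax / cutoff (right-to-left after left sweep)
mps_compress <- function(mps, chimax = Inf, cutoff = 1e-14) {
  mps <- mps_left_canonical(mps)
  M <- length(mps)
  for (s in M:2) {
    d <- dim(mps[[s]])
    sv <- svd(matrix(mps[[s]], d[1], 4 * d[3]))
    keep <- trunc_keep(sv$d, chimax, cutoff)
    U <- sv$u[, keep, drop = FALSE]
    mps[[s]] <- array(t(sv$v[, keep, drop = FALSE]), c(length(keep), 4, d[3]))
    carry <- U %*% diag(sv$d[keep], length(keep))
    dn <- dim(mps[[s - 1]])
    mps[[s - 1]] <- array(matrix(mps[[s - 1]], dn[1] * 4, dn[3]) %*% carry,
                          c(dn[1], 4, length(keep)))
  }
  mps
}

trunc_keep <- function(sv, chimax, cutoff) {
  tot <- sum(sv^2)
  if (tot == 0) return(1L)
  keep <- sv^2 > cutoff * tot
  keep[1] <- TRUE
  n <- min(sum(keep), chimax)
  # respect the discard-weight budget within chimax
  seq_len(max(1L, n))
}

# environment growth: L' over sites <= s from L over sites < s
env_step_left <- function(L, A, W) {
  dl <- dim(L)      # (bra, D, ket)
  da <- dim(A)      # (ket_l, 4, ket_r)
  dw <- dim(W)      # (D, 4, 4, D')
  t1 <- matrix(aperm(L, c(1, 2, 3)), dl[1] * dl[2], dl[3]) %*%
    matrix(A, da[1], 4 * da[3])
  t1 <- array(t1, c(dl[1], dl[2], 4, da[3]))                  # (bra, D, q, kr)
  t2 <- matrix(aperm(t1, c(1, 4, 2, 3)), dl[1] * da[3], dl[2] * 4) %*%
    matrix(aperm(W, c(1, 3, 2, 4)), dw[1] * dw[3], dw[2] * dw[4])
  t2 <- array(t2, c(dl[1], da[3], 4, dw[4]))                  # (bra, kr, p, D')
  t3 <- matrix(aperm(t2, c(2, 4, 1, 3)), da[3] * dw[4], dl[1] * 4)
  Abra <- matrix(A, da[1] * 4, da[3])                          # bra = ket tensor
  out <- t3 %*% Abra                                           # (kr*D', br)
  aperm(array(out, c(da[3], dw[4], da[3])), c(3, 2, 1))        # (bra_r, D', ket_r)
}

# right environment step (sites >= s from sites > s)
env_step_right <- function(R, A, W) {
  da <- dim(A)      # (ket_l, 4, ket_r)
  dw <- dim(W)      # (Dl, 4, 4, Dr)
  dr <- dim(R)      # (bra_r, Dr, ket_r)
  t1 <- matrix(A, da[1] * 4, da[3]) %*%
    matrix(aperm(R, c(3, 2, 1)), dr[3], dr[2] * dr[1])
  t1 <- array(t1, c(da[1], 4, dr[2], dr[1]))                  # (kl, q, Dr, bra_r)
  t2 <- matrix(aperm(t1, c(1, 4, 2, 3)), da[1] * dr[1], 4 * dr[2]) %*%
    t(matrix(W, dw[1] * dw[2], dw[3] * dw[4]))                # over (q=p_in, Dr)
  t2 <- array(t2, c(da[1], dr[1], dw[1], 4))                  # (kl, bra_r, Dl, p_out)
  t3 <- matrix(aperm(t2, c(4, 2, 3, 1)), 4 * dr[1], dw[1] * da[1])
  Abra <- matrix(A, da[1], 4 * da[3])                         # (bra_l, (p, bra_r))
  out <- Abra %*% t3                                          # (bra_l, (Dl, kl))
  array(out, c(da[1], dw[1], da[1]))                          # (bra_l, Dl, ket_l)
}

# two-site effective Hamiltonian application
heff_apply <- function(v, L, W1, W2, R) {
  dl <- dim(L); dw1 <- dim(W1); dw2 <- dim(W2); dr <- dim(R)
  cl <- dl[3]; cr <- dr[3]
  v <- array(v, c(cl, 4, 4, cr))
  t1 <- matrix(L, dl[1] * dl[2], cl) %*% matrix(v, cl, 16 * cr)
  t1 <- array(t1, c(dl[1], dl[2], 4, 4, cr))                  # (bl, D, p1, p2, kr)
  t2 <- matrix(aperm(t1, c(1, 4, 5, 2, 3)), dl[1] * 4 * cr, dl[2] * 4) %*%
    matrix(aperm(W1, c(1, 3, 2, 4)), dw1[1] * dw1[3], 4 * dw1[4])
  t2 <- array(t2, c(dl[1], 4, cr, 4, dw1[4]))                 # (bl, p2, kr, p1', D2)
  t3 <- matrix(aperm(t2, c(1, 4, 3, 5, 2)), dl[1] * 4 * cr, dw1[4] * 4) %*%
    matrix(aperm(W2, c(1, 3, 2, 4)), dw2[1] * dw2[3], 4 * dw2[4])
  t3 <- array(t3, c(dl[1], 4, cr, 4, dw2[4]))                 # (bl, p1', kr, p2', D3)
  t4 <- matrix(aperm(t3, c(1, 2, 4, 5, 3)), dl[1] * 16, dw2[4] * cr) %*%
    matrix(aperm(R, c(2, 3, 1)), dr[2] * cr, dr[1])
  array(t4, c(dl[1], 4, 4, dr[1]))                            # (bl, p1', p2', br)
}

# diagonal of the two-site effective Hamiltonian (preconditioner)
heff_diag <- function(L, W1, W2, R) {
  dl <- dim(L); dr <- dim(R)
  dL <- matrix(0, dl[1], dl[2])
  for (a in seq_len(dl[1])) dL[a, ] <- L[a, , a]
  dR <- matrix(0, dr[1], dr[2])
  for (a in seq_len(dr[1])) dR[a, ] <- R[a, , a]
  dW1 <- apply(W1, c(1, 4), function(m) diag(matrix(m, 4, 4)))  # (4, D, D2)
  dW2 <- apply(W2, c(1, 4), function(m) diag(matrix(m, 4, 4)))
  D2 <- dim(W1)[4]
  out <- array(0, c(dl[1], 4, 4, dr[1]))
  for (p1 in 1:4) for (p2 in 1:4) {
    # sum_{D, D2, D3} dL[a, D] W1[D, p1, p1, D2] W2[D2, p2, p2, D3] dR[b, D3]
    m1 <- dL %*% matrix(dW1[p1, , ], dl[2], D2)      # (a, D2)
    m2 <- matrix(dW2[p2, , ], D2, dr[2])             # (D2, D3)
    out[, p1, p2, ] <- m1 %*% m2 %*% t(dR)
  }
  out
}

davidson <- function(matvec, dvec, v0, tol = 1e-11, maxit = 60L, maxspace = 20L) {
  n <- length(v0)
  if (n <= 36) {
    Hd <- matrix(0, n, n)
    for (i in seq_len(n)) {
      e <- numeric(n); e[i] <- 1
      Hd[, i] <- matvec(e)
    }
    ev <- eigen((Hd + t(Hd)) / 2, symmetric = TRUE)
    return(list(value = ev$values[n], vector = ev$vectors[, n], iter = 0L))
  }
  V <- matrix(v0 / sqrt(sum(v0^2)), n, 1)
  HV <- matrix(matvec(V[, 1]), n, 1)
  theta <- NA
  x <- V[, 1]
  for (it in seq_len(maxit)) {
    Hs <- t(V) %*% HV
    Hs <- (Hs + t(Hs)) / 2
    es <- eigen(Hs, symmetric = TRUE)
    k <- ncol(Hs)
    theta <- es$values[k]
    y <- es$vectors[, k]
    x <- V %*% y
    r <- HV %*% y - theta * x
    rn <- sqrt(sum(r^2))
    if (rn < tol) break
    denom <- dvec - theta
    denom[abs(denom) < 1e-8] <- sign(denom[abs(denom) < 1e-8] + 1e-30) * 1e-8
    t_ <- as.numeric(r) / denom
    # orthogonalize
    for (rep in 1:2) t_ <- t_ - V %*% (t(V) %*% t_)
    tn <- sqrt(sum(t_^2))
    if (tn < 1e-13) break
    t_ <- t_ / tn
    if (ncol(V) >= maxspace) {
      V <- x
      HV <- matrix(matvec(as.numeric(x)), n, 1)
      V <- cbind(V, t_)
      HV <- cbind(HV, matvec(as.numeric(t_)))
    } else {
      V <- cbind(V, t_)
      HV <- cbind(HV, matvec(as.numeric(t_)))
    }
  }
  list(value = theta, vector = as.numeric(x), iter = it)
}

#' Ground state of an MPO by two-site DMRG
#'
#' Variational sweeps with a bond-dimension schedule; the energy is
#' non-increasing across sweeps up to truncation effects and the run is
#' deterministic for a fixed configuration.
#'
#' @param mpo an \code{mw_mpo}, typically from \code{\link{build_mpo}}
#'   with a sector penalty.
#' @param M number of sites.
#' @param N target electron number.
#' @param Sz2 target twice-Sz.
#' @param cfg list: \code{chis} bond schedule (default \code{c(16, 32,
#'   64)}), \code{nsweep} sweeps per stage (default 2), \code{tol}
#'   sweep-energy convergence (default 1e-9), \code{cutoff} discarded-
#'   weight cutoff (default 1e-13), \code{seed} initial-state seed
#'   (default 0), \code{max_extra} additional sweeps at the final bond
#'   dimension (default 6).
#' @return list of class \code{mw_dmrg_state}: \code{mps} (left-canonical),
#'   \code{energy} (sweep eigenvalue), \code{energy_trace}, \code{chi},
#'   \code{converged}, \code{nsweep}.
#' @export
dmrg_ground_state <- function(mpo, M, N, Sz2, cfg = list()) {
  chis <- cfg$chis %||% c(16L, 32L, 64L)
  nsweep <- cfg$nsweep %||% 2L
  tol <- cfg$tol %||% 1e-11
  cutoff <- cfg$cutoff %||% 3e-16
  seed <- cfg$seed %||% 0L
  max_extra <- cfg$max_extra %||% 12L
  state_tol <- cfg$state_tol %||% 5e-9
  if (N > 2 * M) stop("infeasible sector: N > 2M")

  if (M == 1L) {
    # single site: diagonalize the local operator in the sector directly
    Hloc <- matrix(mpo$W[[1]][1, , , 1], 4, 4)
    occn <- c(0, 1, 1, 2)
    szs <- c(0, 1, -1, 0)
    sel <- which(occn == N & szs == Sz2)
    if (!length(sel)) stop("infeasible sector for a single orbital")
    Hs <- matrix(Hloc[sel, sel], length(sel), length(sel))
    ev <- eigen((Hs + t(Hs)) / 2, symmetric = TRUE)
    kmin <- which.min(ev$values)
    vec <- numeric(4)
    vec[sel] <- ev$vectors[, kmin]
    mps <- list(array(vec, c(1, 4, 1)))
    return(structure(list(mps = mps, energy = min(ev$values),
                          energy_trace = min(ev$values), chi = 1L,
                          converged = TRUE, nsweep = 0L),
                     class = "mw_dmrg_state"))
  }

  mps <- mps_random_sector(M, N, Sz2, seed = seed)
  mps <- mps_left_canonical(mps)

  # right environments for the initial state
  Renv <- vector("list", M + 1L)
  Renv[[M + 1L]] <- array(1, c(1, 1, 1))
  for (s in M:1) {
    Renv[[s]] <- env_step_right(Renv[[s + 1L]], mps[[s]], mpo$W[[s]])
  }
  Lenv <- vector("list", M + 1L)
  Lenv[[1L]] <- array(1, c(1, 1, 1))

  energy <- NA
  prev_mps <- NULL
  trace <- numeric(0)
  stage_list <- rep(chis, each = nsweep)
  stage_list <- c(stage_list, rep(chis[length(chis)], max_extra))
  converged <- FALSE
  nsweep_done <- 0L
  for (stage in seq_along(stage_list)) {
    chi <- stage_list[stage]
    eprev <- energy
    # left-to-right half sweep
    for (s in 1:(M - 1L)) {
      d1 <- dim(mps[[s]]); d2 <- dim(mps[[s + 1]])
      v0 <- array(0, c(d1[1], 4, 4, d2[3]))
      # build from current tensors: theta = A_s * A_{s+1}
      v0[] <- array(matrix(mps[[s]], d1[1] * 4, d1[3]) %*%
                      matrix(mps[[s + 1]], d2[1], 4 * d2[3]),
                    c(d1[1], 4, 4, d2[3]))
      L <- Lenv[[s]]; R <- Renv[[s + 2L]]
      W1 <- mpo$W[[s]]; W2 <- mpo$W[[s + 1]]
      dg <- as.numeric(heff_diag(L, W1, W2, R))
      sol <- davidson(function(x) as.numeric(heff_apply(x, L, W1, W2, R)),
                      dg, as.numeric(v0), tol = max(tol * 0.1, 1e-12))
      energy <- sol$value
      th <- array(sol$vector, c(d1[1], 4, 4, d2[3]))
      sv <- svd(matrix(th, d1[1] * 4, 4 * d2[3]))
      keep <- trunc_keep(sv$d, chi, cutoff)
      r <- length(keep)
      mps[[s]] <- array(sv$u[, keep, drop = FALSE], c(d1[1], 4, r))
      mps[[s + 1]] <- array(diag(sv$d[keep], r) %*% t(sv$v[, keep, drop = FALSE]),
                            c(r, 4, d2[3]))
      Lenv[[s + 1L]] <- env_step_left(Lenv[[s]], mps[[s]], mpo$W[[s]])
    }
    # right-to-left half sweep
    for (s in (M - 1L):1) {
      d1 <- dim(mps[[s]]); d2 <- dim(mps[[s + 1]])
      v0 <- array(matrix(mps[[s]], d1[1] * 4, d1[3]) %*%
                    matrix(mps[[s + 1]], d2[1], 4 * d2[3]),
                  c(d1[1], 4, 4, d2[3]))
      L <- Lenv[[s]]; R <- Renv[[s + 2L]]
      W1 <- mpo$W[[s]]; W2 <- mpo$W[[s + 1]]
      dg <- as.numeric(heff_diag(L, W1, W2, R))
      sol <- davidson(function(x) as.numeric(heff_apply(x, L, W1, W2, R)),
                      dg, as.numeric(v0), tol = max(tol * 0.1, 1e-12))
      energy <- sol$value
      th <- array(sol$vector, c(d1[1], 4, 4, d2[3]))
      sv <- svd(matrix(th, d1[1] * 4, 4 * d2[3]))
      keep <- trunc_keep(sv$d, chi, cutoff)
      r <- length(keep)
      mps[[s + 1]] <- array(t(sv$v[, keep, drop = FALSE]), c(r, 4, d2[3]))
      mps[[s]] <- array(sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], r),
                        c(d1[1], 4, r))
      Renv[[s + 1L]] <- env_step_right(Renv[[s + 2L]], mps[[s + 1]], mpo$W[[s + 1]])
    }
    nsweep_done <- nsweep_done + 1L
    trace <- c(trace, energy)
    # sweep-to-sweep state movement: the energy criterion alone is
    # quadratic in the wavefunction error, so the reduced density
    # matrices demand an explicit fidelity check
    dstate <- if (is.null(prev_mps)) Inf else {
      o <- mps_overlap(mps, prev_mps) /
        sqrt(mps_norm2(mps) * mps_norm2(prev_mps))
      sqrt(max(0, 2 * (1 - abs(o))))
    }
    prev_mps <- mps
    at_final_chi <- stage > length(chis) * nsweep - nsweep
    if (at_final_chi && !is.na(eprev) && abs(energy - eprev) < tol &&
        dstate < state_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("DMRG did not reach |dE| < ", tol, " in ", nsweep_done,
            " sweeps; returning best state")
  mps <- mps_left_canonical(mps)
  structure(list(mps = mps, energy = energy, energy_trace = trace,
                 chi = max(mps_dims(mps)), converged = converged,
                 nsweep = nsweep_done),
            class = "mw_dmrg_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
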