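# Second-quantized operator algebra on a chain of spatial-orbital sites.
# Each site has local dimension 4 with basis |0>, |up>, |dn>, |updn> and
# |updn> = a+_up a+_dn |0>.  Fermionic statistics are carried by
# Jordan-Wigner parity operators; the global mode order is site-major with
# up before down within a site.

lop <- local({
  a_up <- matrix(0, 4, 4); a_up[1, 2] <- 1; a_up[3, 4] <- 1
  a_dn <- matrix(0, 4, 4); a_dn[1, 3] <- 1; a_dn[2, 4] <- -1
  list(a_up = a_up, a_dn = a_dn,
       c_up = t(a_up), c_dn = t(a_dn),
       P = diag(c(1, -1, -1, 1)),
       n_up = diag(c(0, 1, 0, 1)), n_dn = diag(c(0, 0, 1, 1)),
       n = diag(c(0, 1, 1, 2)), sz = diag(c(0, 0.5, -0.5, 0)),
       I = diag(1, 4))
})

# product of elementary fermionic operators as per-site 4 x 4 matrices
# ops: list of c(site, kind) applied left to right in the operator product;
# kind in "cu+", "cu", "cd+", "cd" (within-site JW sign for the down mode
# is already encoded in a_dn / c_dn)
op_string <- function(M, ops) {
  mats <- vector("list", M)
  for (t in seq_along(ops)) {
    s <- as.integer(ops[[t]][[1]])
    kind <- ops[[t]][[2]]
    loc <- switch(kind,
                  "cu+" = lop$c_up, "cu" = lop$a_up,
                  "cd+" = lop$c_dn, "cd" = lop$a_dn,
                  stop("unknown operator kind ", kind))
    if (s > 1) for (sp in 1:(s - 1)) {
      mats[[sp]] <- if (is.null(mats[[sp]])) lop$P else mats[[sp]] %*% lop$P
    }
    mats[[s]] <- if (is.null(mats[[s]])) loc else mats[[s]] %*% loc
  }
  mats
}

# ---- determinant (bit-mask) utilities for the dense FCI oracle --------
# mode m = 2*(i-1) + (sigma == "dn") + 1 for spatial orbital i

popcount16 <- local({
  tab <- integer(65536)
  for (b in 0:15) {
    idx <- which(bitwAnd(0:65535, bitwShiftL(1L, b)) != 0L)
    tab[idx] <- tab[idx] + 1L
  }
  tab
})

bits_below <- function(mask, m) {
  if (m <= 1) return(0L)
  popcount16[bitwAnd(mask, bitwShiftL(1L, m - 1L) - 1L) + 1L]
}

det_ann <- function(mask, m) {
  bit <- bitwShiftL(1L, m - 1L)
  if (bitwAnd(mask, bit) == 0L) return(NULL)
  list(mask = bitwXor(mask, bit), sign = 1L - 2L * (bits_below(mask, m) %% 2L))
}

det_cre <- function(mask, m) {
  bit <- bitwShiftL(1L, m - 1L)
  if (bitwAnd(mask, bit) != 0L) return(NULL)
  list(mask = bitwXor(mask, bit), sign = 1L - 2L * (bits_below(mask, m) %% 2L))
}

det_occ <- function(mask, nmode) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(nmode - 1L))) != 0L)
}

#' Determinant basis of a fixed (N, Sz) sector
#' @param M number of spatial orbitals.
#' @param N electron count.
#' @param Sz2 twice the spin projection (integer).
#' @return integer vector of determinant bit masks (site-major modes,
#'   up before down), in a fixed deterministic order.
#' @keywords internal
fci_space <- function(M, N, Sz2) {
  if ((N + Sz2) %% 2 != 0) return(integer(0))
  Na <- (N + Sz2) / 2
  Nb <- (N - Sz2) / 2
  if (Na < 0 || Nb < 0 || Na > M || Nb > M) return(integer(0))
  choose_masks <- function(nchoose, offset) {
    # masks over modes offset, offset+2, ..., offset+2*(M-1)
    if (nchoose == 0) return(0L)
    sets <- utils::combn(M, nchoose)
    apply(sets, 2, function(ix) {
      Reduce(bitwOr, bitwShiftL(1L, offset + 2L * (ix - 1L)), 0L)
    })
  }
  am <- choose_masks(Na, 0L)
  bm <- choose_masks(Nb, 1L)
  masks <- as.integer(outer(am, bm, bitwOr))
  sort(masks)
}

# spin-resolved one-body coefficient for modes (p, q): both must share spin
mode_orb <- function(m) (m + 1L) %/% 2L
mode_spin <- function(m) 1L - (m %% 2L)  # 0 = up (odd), 1 = down (even)

#' Dense full configuration interaction in a fixed sector
#'
#' Explicit construction and diagonalization of the second-quantized
#' Hamiltonian in the determinant space with fixed particle number and
#' spin projection.  Serves as the independent oracle for the tensor
#' network ground-state solver and its gradients.
#'
#' @param h M x M one-body integrals.
#' @param g M^4 two-body tensor (real-orbital symmetric).
#' @param N electron count.
#' @param Sz2 twice the spin projection (default: \code{N %% 2}).
#' @param nroots number of eigenpairs kept (default 1).
#' @return list with \code{energy} (ground state), \code{energies},
#'   \code{vec} (ground vector), \code{basis} masks, and \code{M}.
#' @export
fci_solve <- function(h, g, N, Sz2 = N %% 2L, nroots = 1L) {
  M <- nrow(h)
  if (M > 8) stop("dense FCI oracle limited to M <= 8")
  basis <- fci_space(M, N, Sz2)
  if (!length(basis)) stop("empty (N, Sz) sector")
  dim <- length(basis)
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(dim)) assign(as.character(basis[i]), i, envir = index)
  H <- matrix(0, dim, dim)
  nmode <- 2L * M
  for (col in seq_len(dim)) {
    d0 <- basis[col]
    occ <- det_occ(d0, nmode)
    # one-body
    for (mq in occ) {
      a1 <- det_ann(d0, mq)
      iq <- mode_orb(mq); sq <- mode_spin(mq)
      for (ip in 1:M) {
        if (h[ip, iq] == 0) next
        mp <- 2L * (ip - 1L) + sq + 1L
        c1 <- det_cre(a1$mask, mp)
        if (is.null(c1)) next
        row <- get(as.character(c1$mask), envir = index)
        H[row, col] <- H[row, col] + h[ip, iq] * a1$sign * c1$sign
      }
    }
    # two-body: 1/2 sum_ijkl g_ijkl a+_{i,s} a+_{j,t} a_{l,t} a_{k,s}
    for (mk in occ) {                       # a_{k,sigma} first
      a1 <- det_ann(d0, mk)
      ik <- mode_orb(mk); ss <- mode_spin(mk)
      occ2 <- det_occ(a1$mask, nmode)
      for (ml in occ2) {                    # then a_{l,tau}
        a2 <- det_ann(a1$mask, ml)
        il <- mode_orb(ml); tt <- mode_spin(ml)
        for (ij in 1:M) {                   # a+_{j,tau}
          mj <- 2L * (ij - 1L) + tt + 1L
          c1 <- det_cre(a2$mask, mj)
          if (is.null(c1)) next
          for (ii in 1:M) {                 # a+_{i,sigma}
            gv <- g[ii, ij, ik, il]
            if (gv == 0) next
            mi <- 2L * (ii - 1L) + ss + 1L
            c2 <- det_cre(c1$mask, mi)
            if (is.null(c2)) next
            row <- get(as.character(c2$mask), envir = index)
            H[row, col] <- H[row, col] +
              0.5 * gv * a1$sign * a2$sign * c1$sign * c2$sign
          }
        }
      }
    }
  }
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- length(ev$values):1L
  list(energy = ev$values[ord[1]],
       energies = ev$values[ord[seq_len(min(nroots, dim))]],
       vec = ev$vectors[, ord[1]],
       basis = basis, M = M, N = N, Sz2 = Sz2)
}

#' Reduced density matrices from an FCI vector
#'
#' Spin-free 1- and 2-RDMs: \eqn{\gamma_{ij} = \langle \hat E_{ij}\rangle}
#' and \eqn{\Gamma_{ijkl} = \langle \hat e_{ijkl} \rangle} with
#' \eqn{\hat e_{ijkl} = \sum_{\sigma\tau} a^+_{i\sigma} a^+_{j\tau}
#' a_{l\tau} a_{k\sigma}}.
#'
#' @param sol result of \code{\link{fci_solve}}.
#' @return list with \code{gamma} (M x M) and \code{Gamma} (M^4).
#' @export
fci_rdms <- function(sol) {
  M <- sol$M
  basis <- sol$basis
  vec <- sol$vec
  dim <- length(basis)
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(dim)) assign(as.character(basis[i]), i, envir = index)
  gam <- matrix(0, M, M)
  Gam <- array(0, rep(M, 4))
  nmode <- 2L * M
  for (col in seq_len(dim)) {
    c0 <- vec[col]
    if (abs(c0) < 1e-300) next
    d0 <- basis[col]
    occ <- det_occ(d0, nmode)
    for (mq in occ) {
      a1 <- det_ann(d0, mq)
      iq <- mode_orb(mq); sq <- mode_spin(mq)
      for (ip in 1:M) {
        mp <- 2L * (ip - 1L) + sq + 1L
        c1 <- det_cre(a1$mask, mp)
        if (is.null(c1)) next
        row <- get(as.character(c1$mask), envir = index)
        gam[ip, iq] <- gam[ip, iq] + vec[row] * c0 * a1$sign * c1$sign
      }
    }
    for (mk in occ) {
      a1 <- det_ann(d0, mk)
      ik <- mode_orb(mk); ss <- mode_spin(mk)
      occ2 <- det_occ(a1$mask, nmode)
      for (ml in occ2) {
        a2 <- det_ann(a1$mask, ml)
        il <- mode_orb(ml); tt <- mode_spin(ml)
        for (ij in 1:M) {
          mj <- 2L * (ij - 1L) + tt + 1L
          c1 <- det_cre(a2$mask, mj)
          if (is.null(c1)) next
          for (ii in 1:M) {
            mi <- 2L * (ii - 1L) + ss + 1L
            c2 <- det_cre(c1$mask, mi)
            if (is.null(c2)) next
            row <- get(as.character(c2$mask), envir = index)
            Gam[ii, ij, ik, il] <- Gam[ii, ij, ik, il] +
              vec[row] * c0 * a1$sign * a2$sign * c1$sign * c2$sign
          }
        }
      }
    }
  }
  list(gamma = gam, Gamma = Gam)
}

# exported accessors for the local operators (validation aids)
lop_n <- function() lop$n
lop_sz <- function() lop$sz
lop_parity <- function() lop$P
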