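# Application of separated radial kernels to adaptive trees in
# non-standard form.  Each Gaussian term is separable across dimensions, so
# a 3D operator block is a tensor product of 1D blocks.  At every scale the
# operator acts on the joint child-representation block of a node and the
# part already representable at the parent scale is subtracted; summing the
# telescoped contributions over scales (plus the full coarsest-scale term)
# reconstructs the convolution while touching only a narrow displacement
# band per scale.

#' Convolution operator from a separated kernel
#'
#' @param kern an \code{mw_kernel} (physical units).
#' @param basis an \code{mw_basis}.
#' @param L domain half-width (bohr).
#' @param prec target application precision.
#' @return an object of class \code{mw_conv} (per-scale matrices are built
#'   lazily and cached on the object).
#' @export
mw_conv_op <- function(kern, basis, L, prec) {
  op <- new.env(parent = emptyenv())
  op$kern <- kern
  op$basis <- basis
  op$L <- L
  op$prec <- prec
  # unit-cube rescaling of the Gaussian terms
  op$coef <- kern$coef * (2 * L)^3
  op$expo <- kern$expo * (2 * L)^2
  op$tcache <- new.env(hash = TRUE, parent = emptyenv())  # 1D matrices
  op$scache <- new.env(hash = TRUE, parent = emptyenv())  # per-scale struct
  class(op) <- "mw_conv"
  op
}

#' Poisson and bound-state Helmholtz operators
#'
#' Convenience constructors for the two kernels used by the orbital
#' machinery.  \code{mw_bsh_op} is the Green's function of
#' \eqn{(-\nabla^2 + \mu^2)}; the conventional factor \eqn{-2} of the
#' orbital update equation is applied by the caller, not by the operator.
#'
#' @param basis an \code{mw_basis}.
#' @param L domain half-width (bohr).
#' @param prec application precision.
#' @param mu Helmholtz decay parameter (1/bohr).
#' @return an \code{mw_conv} operator.
#' @export
mw_poisson_op <- function(basis, L, prec) {
  key <- sprintf("P_%d_%g_%g", basis$k, L, prec)
  hit <- conv_op_cache[[key]]
  if (!is.null(hit)) return(hit)
  kern <- mw_kernel_expand(0, eps = prec / 10, rmin = 2 * L * 2^-16,
                           rmax = 2 * sqrt(3) * 2 * L)
  op <- mw_conv_op(kern, basis, L, prec)
  conv_op_cache[[key]] <- op
  op
}

#' @rdname mw_poisson_op
#' @param is_coeff if TRUE, \code{mu} is interpreted as the (negative)
#'   kernel energy coefficient and converted via
#'   \eqn{\mu = \sqrt{-2\,c}}.
#' @export
mw_bsh_op <- function(mu, basis, L, prec, is_coeff = FALSE) {
  if (is_coeff) mu <- sqrt(-2 * mu)
  stopifnot(mu > 0)
  key <- sprintf("B_%.12g_%d_%g_%g", mu, basis$k, L, prec)
  hit <- conv_op_cache[[key]]
  if (!is.null(hit)) return(hit)
  kern <- mw_kernel_expand(mu, eps = prec / 10, rmin = 2 * L * 2^-16,
                           rmax = 2 * sqrt(3) * 2 * L)
  op <- mw_conv_op(kern, basis, L, prec)
  conv_op_cache[[key]] <- op
  op
}

conv_op_cache <- new.env(parent = emptyenv())

# 1D operator matrix  T^m_{j'j}(Delta) = 2^{-m} II phi_j'(xi) phi_j(eta)
#   exp(-beta (xi - eta + Delta)^2) dxi deta,  beta = expo * 4^{-m}
op1d <- function(op, term, m, Delta) {
  key <- paste(term, m, Delta, sep = "_")
  hit <- op$tcache[[key]]
  if (!is.null(hit)) return(hit)
  basis <- op$basis
  beta <- op$expo[term] * 4^(-m)
  k <- basis$k
  k1 <- basis$k1
  if (beta <= 50) {
    q <- get_gl(30L)
    E <- leg_eval(q$x, k)
    K <- exp(-beta * (outer(q$x, q$x, `-`) + Delta)^2)
    T_ <- 2^(-m) * t(E * q$w) %*% K %*% (E * q$w)
  } else {
    # panel the outer integral around the erf transition layers
    g16 <- get_gl(16L)
    w <- min(0.5, 8 / sqrt(beta))
    bp <- sort(unique(pmin(pmax(c(0, -Delta - w, -Delta + w,
                                  1 - Delta - w, 1 - Delta + w, 1), 0), 1)))
    xs <- NULL
    ws <- NULL
    for (i in seq_len(length(bp) - 1)) {
      if (bp[i + 1] - bp[i] < 1e-14) next
      xs <- c(xs, bp[i] + (bp[i + 1] - bp[i]) * g16$x)
      ws <- c(ws, (bp[i + 1] - bp[i]) * g16$w)
    }
    Ip <- gauss_moments(xs + Delta, beta, k)     # (k+1) x length(xs)
    inner <- basis$mono %*% Ip                   # phi_j moments, (k+1) x nq
    Eo <- leg_eval(xs, k)                        # nq x (k+1)
    T_ <- 2^(-m) * t(Eo * ws) %*% t(inner)
  }
  op$tcache[[key]] <- T_
  T_
}

# memoized Gauss-Legendre rules on (0, 1)
gl_cache <- new.env(parent = emptyenv())
get_gl <- function(n) {
  key <- as.character(n)
  hit <- gl_cache[[key]]
  if (is.null(hit)) {
    g <- pracma::gaussLegendre(n, 0, 1)
    hit <- list(x = g$x, w = g$w)
    gl_cache[[key]] <- hit
  }
  hit
}

# I_p(c) = Int_0^1 eta^p exp(-beta (eta - c)^2) deta for p = 0..k,
# vectorized over c; stable upward recursion driven by erf for large beta
gauss_moments <- function(cc, beta, k) {
  sb <- sqrt(beta)
  e1 <- exp(-beta * (1 - cc)^2)
  e0 <- exp(-beta * cc^2)
  I <- matrix(0, k + 1L, length(cc))
  I0 <- sqrt(pi / beta) / 2 * (pracma::erf(sb * (1 - cc)) + pracma::erf(sb * cc))
  I[1L, ] <- I0
  if (k >= 1) {
    I[2L, ] <- cc * I0 - (e1 - e0) / (2 * beta)
    if (k >= 2) for (p in 2:k) {
      I[p + 1L, ] <- cc * I[p, ] + ((p - 1) * I[p - 1L, ] - e1) / (2 * beta)
    }
  }
  I
}

# per-scale application structure: surviving terms with their child-level
# cubes and the displacement band
conv_scale_struct <- function(op, n, cut_rel) {
  key <- as.character(n)
  hit <- op$scache[[key]]
  if (!is.null(hit)) return(hit)
  basis <- op$basis
  k1 <- basis$k1
  H <- basis$H          # k1 x 2k1
  U1 <- t(H)
  nterm <- length(op$coef)
  maxd <- min(2^n - 1, 64)   # displacements cannot exceed the scale's boxes

  build_Aj <- function(term, Delta) {
    # child-representation matrix from scale n+1 blocks
    A <- matrix(0, 2 * k1, 2 * k1)
    for (bo in 0:1) for (bi in 0:1) {
      A[bo * k1 + 1:k1, bi * k1 + 1:k1] <- op1d(op, term, n + 1L, 2 * Delta + bo - bi)
    }
    A
  }

  terms <- list()
  band <- 0L
  for (t in seq_len(nterm)) {
    ct <- op$coef[t]
    # quick size estimate of the term at this scale
    A0 <- build_Aj(t, 0L)
    Tn0 <- op1d(op, t, n, 0L)
    M0 <- A0 - U1 %*% Tn0 %*% H
    n0 <- norm(A0, "F")
    if (abs(ct) * norm(M0, "F") * max(n0, 1)^2 < cut_rel) next
    Ajs <- list(A0)
    Tns <- list(Tn0)
    nM <- norm(M0, "F")
    nA <- n0
    D <- 0L
    while (D < maxd) {
      D1 <- D + 1L
      A <- build_Aj(t, D1)
      Tn <- op1d(op, t, n, D1)
      Mn <- norm(A - U1 %*% Tn %*% H, "F")
      if (abs(ct) * Mn * max(nA[1], 1)^2 < cut_rel) break
      Ajs[[D1 + 1L]] <- A
      Tns[[D1 + 1L]] <- Tn
      nM <- c(nM, Mn)
      nA <- c(nA, norm(A, "F"))
      D <- D1
    }
    # mirror to negative displacements: T(-Delta) = T(Delta)^T for even
    # kernels, and the band is symmetric
    nd <- 2L * D + 1L
    Aj <- array(0, c(2 * k1, 2 * k1, nd))
    Bj <- array(0, c(2 * k1, k1, nd))
    nAv <- numeric(nd)
    nMv <- numeric(nd)
    for (Delta in -D:D) {
      idx <- Delta + D + 1L
      A <- if (Delta >= 0) Ajs[[Delta + 1L]] else t(Ajs[[-Delta + 1L]])
      Tn <- if (Delta >= 0) Tns[[Delta + 1L]] else t(Tns[[-Delta + 1L]])
      Aj[, , idx] <- A
      Bj[, , idx] <- U1 %*% Tn
      nAv[idx] <- norm(A, "F")
      nMv[idx] <- norm(A - U1 %*% Tn %*% H, "F")
    }
    terms[[length(terms) + 1L]] <-
      list(Aj = Aj, Bj = Bj, nA = nAv, nM = nMv, coef = ct, D = D)
    band <- max(band, D)
  }
  out <- list(terms = terms, band = band)
  op$scache[[key]] <- out
  out
}

#' Apply a convolution operator to a tree
#'
#' Pure kernel convolution \eqn{(K * f)(r) = \int K(|r - r'|) f(r') dr'};
#' no sign or prefactor convention is attached to the operator itself.
#'
#' @param op an \code{mw_conv} operator.
#' @param f an \code{mw_tree} on the operator's basis and domain.
#' @return an \code{mw_tree} holding the convolution, thresholded at the
#'   tree precision.
#' @export
mw_apply <- function(op, f) {
  basis <- op$basis
  if (basis$k != f$basis$k || op$L != f$L)
    stop("operator and tree bases/domains differ")
  if (op$kern$rmax < 2 * sqrt(3) * 2 * op$L) {
    warning("kernel range shorter than the domain diagonal; re-expanding")
    kern <- mw_kernel_expand(op$kern$mu, op$kern$eps, op$kern$rmin,
                             2 * sqrt(3) * 2 * op$L)
    op <- mw_conv_op(kern, basis, op$L, op$prec)
  }
  k1 <- basis$k1
  U1 <- t(basis$H)
  fnorm <- max(f$norm_est, mw_norm(f))
  if (fnorm == 0) return(mw_tree_new(basis, f$L, f$prec, f$maxdepth))
  tune <- getOption("mwdmrg.conv_cuts", c(0.02, 0.08))
  cut_rel <- op$prec * tune[1]
  cut_abs <- op$prec * fnorm * tune[2]

  ks <- tree_keys(f)
  ns <- tree_scales(f)
  depth <- max(ns)
  Jenv <- new.env(hash = TRUE, parent = emptyenv())

  # coarsest-scale full term
  s_root <- get_block(f, key_of(0L, c(0L, 0L, 0L)))
  root_out <- numeric(k1^3)
  for (t in seq_along(op$coef)) {
    T0 <- op1d(op, t, 0L, 0L)
    if (abs(op$coef[t]) * norm(T0, "F")^3 * sqrt(sum(s_root^2)) < cut_abs * 1e-3) next
    root_out <- root_out + op$coef[t] * cpp_mode3(T0, T0, T0, s_root)
  }

  for (n in 0:depth) {
    sel <- which(ns == n)
    if (!length(sel)) next
    st <- conv_scale_struct(op, n, cut_rel)
    if (!length(st$terms)) next
    keys_n <- ks[sel]
    lmat <- t(vapply(keys_n, function(k) key_parse(k)[2:4], integer(3)))
    nsrc <- length(keys_n)
    mj3 <- (2 * k1)^3
    src_joint <- matrix(0, mj3, nsrc)
    src_spar <- matrix(0, k1^3, nsrc)
    for (i in seq_len(nsrc)) {
      v <- key_parse(keys_n[i])
      s <- get_block(f, keys_n[i])
      src_spar[, i] <- s
      if (is_leaf(f, keys_n[i])) {
        src_joint[, i] <- cpp_mode3(U1, U1, U1, s)
      } else {
        ch <- lapply(1:8, function(b) {
          bits <- as.integer(child_bits[b, ])
          get_block(f, key_of(n + 1L, 2L * v[2:4] + bits))
        })
        src_joint[, i] <- joint_from_children(k1, ch)
      }
    }
    src_nrm <- sqrt(colSums(src_joint^2))
    B <- st$band
    # per-displacement screening bound over terms (1D norms are padded to
    # the common band below)
    nd <- 2L * B + 1L
    nAall <- matrix(vapply(st$terms, function(tt) {
      v <- numeric(nd); v[(B - tt$D + 1L):(B + tt$D + 1L)] <- tt$nA; v
    }, numeric(nd)), nrow = nd)
    nMall <- matrix(vapply(st$terms, function(tt) {
      v <- numeric(nd); v[(B - tt$D + 1L):(B + tt$D + 1L)] <- tt$nM; v
    }, numeric(nd)), nrow = nd)
    cts <- abs(vapply(st$terms, `[[`, 0, "coef"))
    offs <- as.matrix(expand.grid(dx = -B:B, dy = -B:B, dz = -B:B))
    obnd <- numeric(nrow(offs))
    for (o in seq_len(nrow(offs))) {
      ix <- offs[o, ] + B + 1L
      ax <- nAall[ix[1], ]; ay <- nAall[ix[2], ]; az <- nAall[ix[3], ]
      mx <- nMall[ix[1], ]; my <- nMall[ix[2], ]; mz <- nMall[ix[3], ]
      obnd[o] <- max(cts * (mx * ay * az + ax * my * az + ax * ay * mz +
                            mx * my * az + mx * ay * mz + ax * my * mz +
                            mx * my * mz))
    }
    keep_off <- which(obnd * max(src_nrm) >= cut_abs)
    if (!length(keep_off)) next
    # build pair lists against existing nodes at this scale
    keyidx <- seq_len(nsrc)
    names(keyidx) <- keys_n
    plist <- vector("list", length(keep_off))
    for (oi in seq_along(keep_off)) {
      d <- offs[keep_off[oi], ]
      tl1 <- lmat[, 1] + d[1]; tl2 <- lmat[, 2] + d[2]; tl3 <- lmat[, 3] + d[3]
      ok <- tl1 >= 0 & tl2 >= 0 & tl3 >= 0 & tl1 < 2^n & tl2 < 2^n & tl3 < 2^n
      if (!any(ok)) next
      tk <- paste(n, tl1[ok], tl2[ok], tl3[ok], sep = ".")
      ti <- keyidx[tk]
      hit <- !is.na(ti)
      if (!any(hit)) next
      si <- which(ok)[hit]
      nb <- sum(hit)
      plist[[oi]] <- cbind(si - 1L, ti[hit] - 1L,
                           rep(d[1] + B, nb), rep(d[2] + B, nb), rep(d[3] + B, nb))
    }
    pmat <- do.call(rbind, plist)
    if (is.null(pmat) || !nrow(pmat)) next
    pr_s <- as.integer(pmat[, 1]); pr_t <- as.integer(pmat[, 2])
    pr_dx <- as.integer(pmat[, 3]); pr_dy <- as.integer(pmat[, 4])
    pr_dz <- as.integer(pmat[, 5])
    # per-term cubes may have different bands; pad to the scale band
    terms_pad <- lapply(st$terms, function(tt) {
      if (tt$D == B) return(tt[c("Aj", "Bj", "nA", "nM", "coef")])
      nd <- 2L * B + 1L
      Aj <- array(0, c(2 * k1, 2 * k1, nd))
      Bj <- array(0, c(2 * k1, k1, nd))
      nAv <- numeric(nd); nMv <- numeric(nd)
      sl <- (B - tt$D + 1L):(B + tt$D + 1L)
      Aj[, , sl] <- tt$Aj; Bj[, , sl] <- tt$Bj
      nAv[sl] <- tt$nA; nMv[sl] <- tt$nM
      list(Aj = Aj, Bj = Bj, nA = nAv, nM = nMv, coef = tt$coef)
    })
    out_joint <- cpp_conv_scale(src_joint, src_spar, src_nrm,
                                pr_s, pr_t, pr_dx, pr_dy, pr_dz,
                                terms_pad, cut_abs, nsrc)
    for (i in seq_len(nsrc)) {
      cj <- out_joint[, i]
      if (!any(cj != 0)) next
      kk <- keys_n[i]
      prev <- Jenv[[kk]]
      Jenv[[kk]] <- if (is.null(prev)) cj else prev + cj
    }
  }

  # reconstruct top-down
  out <- mw_tree_new(basis, f$L, f$prec, f$maxdepth)
  rec <- function(n, l, s_acc) {
    kk <- key_of(n, l)
    J <- Jenv[[kk]]
    if (is.null(J)) {
      set_block(out, kk, s_acc, leaf = TRUE)
      return(invisible(NULL))
    }
    set_block(out, kk, s_acc, leaf = FALSE)
    joint_total <- cpp_mode3(U1, U1, U1, s_acc) + J
    for (b in 1:8) {
      bits <- as.integer(child_bits[b, ])
      rec(n + 1L, 2L * l + bits, joint_child(k1, joint_total, bits))
    }
  }
  rec(0L, c(0L, 0L, 0L), root_out)
  build_internals(out)
  mw_truncate(out, f$prec)
  out$norm_est <- mw_norm(out)
  out
}
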