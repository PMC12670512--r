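# One- and two-electron integrals over multiwavelet orbitals, the overlap
# matrix, Loewdin orthonormalization, and FCIDUMP interchange.
#
# Conventions (real orbitals):
#   h_ij    = <phi_i | -grad^2/2 - sum_a Z_a/|r - R_a| | phi_j>
#   ghat_jl = int phi_j(r') phi_l(r') / |r - r'| dr'     (a potential)
#   g_ijkl  = <phi_i phi_k | ghat_jl>  (physicists' ordering of the paper;
#             equals the chemists' integral (ik|jl))

#' Orbital set container
#' @param orbitals list of \code{mw_tree} objects.
#' @return object of class \code{mw_orbitals}.
#' @export
mw_orbitals <- function(orbitals) {
  stopifnot(length(orbitals) >= 1)
  for (t in orbitals[-1]) check_compat(orbitals[[1]], t)
  structure(list(orb = orbitals, M = length(orbitals)), class = "mw_orbitals")
}

#' Overlap matrix of an orbital set
#' @param orbs an \code{mw_orbitals}.
#' @return symmetric M x M matrix \eqn{s_{ij}}.
#' @export
mw_overlap <- function(orbs) {
  M <- orbs$M
  s <- matrix(0, M, M)
  for (i in 1:M) for (j in i:M) {
    s[i, j] <- s[j, i] <- mw_inner(orbs$orb[[i]], orbs$orb[[j]])
  }
  s
}

#' Loewdin (symmetric) orthonormalization
#'
#' Replaces the set by \eqn{\phi \leftarrow \sum_j (s^{-1/2})_{ij}\phi_j};
#' minimally perturbing and span-preserving.
#'
#' @param orbs an \code{mw_orbitals}.
#' @return an orthonormalized \code{mw_orbitals}.
#' @export
mw_lowdin <- function(orbs) {
  s <- mw_overlap(orbs)
  ev <- eigen(s, symmetric = TRUE)
  if (min(ev$values) <= 0 || max(ev$values) / min(ev$values) > 1e10)
    stop("overlap matrix is (near) singular: linearly dependent orbitals")
  shalf <- ev$vectors %*% diag(1 / sqrt(ev$values), orbs$M) %*% t(ev$vectors)
  mw_rotate(orbs, shalf)
}

#' Apply a linear transformation to an orbital set
#' @param orbs an \code{mw_orbitals}.
#' @param U M x M matrix; new orbital i is \eqn{\sum_j U_{ij} \phi_j}.
#' @return transformed \code{mw_orbitals}.
#' @export
mw_rotate <- function(orbs, U) {
  M <- orbs$M
  out <- vector("list", M)
  for (i in 1:M) {
    out[[i]] <- mw_add(orbs$orb, U[i, ])
  }
  mw_orbitals(out)
}

#' Kinetic energy matrix
#'
#' \eqn{T_{ij} = \tfrac12 \sum_{axis} \langle \partial\phi_i,
#' \partial\phi_j\rangle}, evaluated on a once-refined grid to keep the
#' derivative stencil error well below the projection error.
#' @param orbs an \code{mw_orbitals}.
#' @return symmetric M x M matrix (Hartree).
#' @export
mw_kinetic <- function(orbs) {
  M <- orbs$M
  T_ <- matrix(0, M, M)
  dlist <- vector("list", M)
  for (i in 1:M) {
    ri <- mw_refine(orbs$orb[[i]], 1L)
    dlist[[i]] <- lapply(1:3, function(ax) mw_deriv(ri, ax))
  }
  for (i in 1:M) for (j in i:M) {
    v <- 0
    for (ax in 1:3) v <- v + 0.5 * mw_inner(dlist[[i]][[ax]], dlist[[j]][[ax]])
    T_[i, j] <- T_[j, i] <- v
  }
  T_
}

#' One-body integrals h
#'
#' @param orbs an \code{mw_orbitals}.
#' @param vtree nuclear potential tree from \code{\link{nuclear_potential}}.
#' @return symmetric M x M matrix \eqn{h_{ij}} (Hartree).
#' @export
mw_one_body <- function(orbs, vtree) {
  M <- orbs$M
  T_ <- mw_kinetic(orbs)
  V <- matrix(0, M, M)
  for (j in 1:M) {
    vphi <- mw_multiply(vtree, orbs$orb[[j]], prec = orbs$orb[[j]]$prec)
    for (i in 1:M) V[i, j] <- mw_inner(orbs$orb[[i]], vphi)
  }
  V <- (V + t(V)) / 2
  T_ + V
}

#' Electron-pair potential \eqn{\hat g_{jl}}
#'
#' The Coulomb potential generated by the orbital product
#' \eqn{\phi_j \phi_l}: a Poisson convolution with kernel \eqn{1/|r-r'|}.
#' Symmetric in (j, l).
#' @param orbs an \code{mw_orbitals}.
#' @param j,l orbital indices.
#' @param pois a Poisson operator from \code{\link{mw_poisson_op}} (kernel
#'   \eqn{1/(4\pi r)}; the \eqn{4\pi} is restored here).
#' @return an \code{mw_tree} potential.
#' @export
mw_pair_potential <- function(orbs, j, l, pois) {
  rho <- mw_multiply(orbs$orb[[j]], orbs$orb[[l]])
  V <- mw_apply(pois, rho)
  # scale by 4*pi in place via a trivial linear combination
  mw_add(list(V), 4 * pi, prune = FALSE)
}

#' Two-body integral tensor g
#'
#' \eqn{g_{ijkl} = \langle \phi_i \phi_k | \hat g_{jl} \rangle}; the
#' 8-fold real-orbital symmetry is used to compute only unique pairs of
#' products.
#' @param orbs an \code{mw_orbitals}.
#' @param pois Poisson operator.
#' @param pair_pots optional precomputed list of pair potentials (as
#'   returned with \code{attr(g, "pair_pots")}) to reuse across calls.
#' @return M^4 array with the symmetries of a real two-electron tensor;
#'   the list of pair potentials is attached as attribute
#'   \code{pair_pots} (keyed \code{"j.l"}, \eqn{j \le l}).
#' @export
mw_two_body <- function(orbs, pois, pair_pots = NULL) {
  M <- orbs$M
  prods <- list()
  for (i in 1:M) for (k in i:M) {
    prods[[paste(i, k, sep = ".")]] <- mw_multiply(orbs$orb[[i]], orbs$orb[[k]])
  }
  if (is.null(pair_pots)) {
    pair_pots <- list()
    for (j in 1:M) for (l in j:M) {
      key <- paste(j, l, sep = ".")
      V <- mw_apply(pois, prods[[key]])
      pair_pots[[key]] <- mw_add(list(V), 4 * pi, prune = FALSE)
    }
  }
  g <- array(0, c(M, M, M, M))
  for (i in 1:M) for (k in i:M) {
    for (j in 1:M) for (l in j:M) {
      if (paste(i, k, sep = ".") < paste(j, l, sep = ".")) next
      val <- mw_inner(prods[[paste(i, k, sep = ".")]],
                      pair_pots[[paste(j, l, sep = ".")]])
      # (ik|jl) with all 8 index symmetries of real orbitals
      for (idx in list(c(i, j, k, l), c(k, j, i, l), c(i, l, k, j),
                       c(k, l, i, j), c(j, i, l, k), c(j, k, l, i),
                       c(l, i, j, k), c(l, k, j, i))) {
        g[idx[1], idx[2], idx[3], idx[4]] <- val
      }
    }
  }
  attr(g, "pair_pots") <- pair_pots
  g
}

#' All integrals for an orbital set
#'
#' @param orbs an orthonormal \code{mw_orbitals}.
#' @param mol an \code{mw_molecule}.
#' @param prec precision for the nuclear potential and operators.
#' @param vtree,pois optional cached nuclear potential / Poisson operator.
#' @return list with \code{h} (M x M), \code{g} (M^4), \code{s} (M x M),
#'   \code{ecore} (nuclear repulsion, Hartree) and the caches
#'   \code{vtree}, \code{pois}, \code{pair_pots}.
#' @export
mw_integrals <- function(orbs, mol, prec, vtree = NULL, pois = NULL) {
  b <- orbs$orb[[1]]$basis
  L <- orbs$orb[[1]]$L
  if (is.null(vtree)) vtree <- nuclear_potential(mol, b, prec, L)
  if (is.null(pois)) pois <- mw_poisson_op(b, L, prec)
  h <- mw_one_body(orbs, vtree)
  g <- mw_two_body(orbs, pois)
  list(h = h, g = g, s = mw_overlap(orbs), ecore = nuclear_repulsion(mol),
       vtree = vtree, pois = pois, pair_pots = attr(g, "pair_pots"))
}

#' Write integrals to an FCIDUMP file
#'
#' Standard FCIDUMP: a namelist header, then \code{value i j k l} records
#' in chemists' notation.  A record \code{(i j k l)} holds the chemists'
#' integral \eqn{(ij|kl)}, which in the tensor convention used here is
#' \eqn{g_{i k j l}} (first/third index electron 1, second/fourth electron
#' 2).  Only symmetry-unique records are written.  The core-energy record
#' \code{value 0 0 0 0} holds the nuclear repulsion.
#'
#' @param h M x M one-body matrix.
#' @param g M^4 two-body tensor.
#' @param ecore core (nuclear repulsion) energy.
#' @param nelec electron count.
#' @param path output path.
#' @param ms2 twice the spin projection (default 0 for even, 1 for odd
#'   electron counts).
#' @export
fcidump_write <- function(h, g, ecore, nelec, path,
                          ms2 = nelec %% 2L) {
  M <- nrow(h)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", M, nelec, ms2), con)
  writeLines(sprintf(" ORBSYM=%s", paste(rep("1,", M), collapse = "")), con)
  writeLines(" ISYM=1,", con)
  writeLines("&END", con)
  fmt <- function(v, i, j, k, l) sprintf("%23.16e %4d %4d %4d %4d", v, i, j, k, l)
  out <- character(0)
  for (i in 1:M) for (j in 1:i) for (k in 1:i) {
    lmax <- if (k == i) j else k
    for (l in 1:lmax) {
      val <- g[i, k, j, l]   # (ij|kl) = g_{i k j l}
      if (abs(val) > 1e-16) out <- c(out, fmt(val, i, j, k, l))
    }
  }
  for (i in 1:M) for (j in 1:i) {
    if (abs(h[i, j]) > 1e-16) out <- c(out, fmt(h[i, j], i, j, 0, 0))
  }
  out <- c(out, fmt(ecore, 0, 0, 0, 0))
  writeLines(out, con)
  invisible(path)
}

#' Read an FCIDUMP file
#' @param path file path.
#' @return list with \code{h}, \code{g} (fully expanded by the 8-fold
#'   symmetry), \code{ecore}, \code{norb}, \code{nelec}, \code{ms2}.
#' @export
fcidump_read <- function(path) {
  lines <- readLines(path)
  hdr_end <- grep("^\\s*[/&]\\s*(END)?\\s*$|&END", lines)[1]
  if (is.na(hdr_end)) stop("no &END/namelist terminator in ", path)
  hdr <- paste(lines[1:hdr_end], collapse = " ")
  getnum <- function(name) {
    m <- regmatches(hdr, regexpr(paste0(name, "\\s*=\\s*-?[0-9]+"), hdr))
    if (!length(m)) stop("missing ", name, " in FCIDUMP header")
    as.integer(sub(paste0(name, "\\s*=\\s*"), "", m))
  }
  M <- getnum("NORB")
  nelec <- getnum("NELEC")
  ms2 <- tryCatch(getnum("MS2"), error = function(e) nelec %% 2L)
  h <- matrix(0, M, M)
  g <- array(0, c(M, M, M, M))
  ecore <- 0
  for (line in lines[(hdr_end + 1):length(lines)]) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) < 5) next
    v <- as.numeric(tok[1])
    ix <- as.integer(tok[2:5])
    if (all(ix == 0)) {
      ecore <- v
    } else if (ix[3] == 0 && ix[4] == 0) {
      h[ix[1], ix[2]] <- h[ix[2], ix[1]] <- v
    } else {
      i <- ix[1]; j <- ix[2]; k <- ix[3]; l <- ix[4]
      # (ij|kl) -> g_{i k j l}; expand chemists' 8-fold symmetry
      for (p in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                     c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                     c(k, l, j, i), c(l, k, j, i))) {
        g[p[1], p[3], p[2], p[4]] <- v
      }
    }
  }
  list(h = h, g = g, ecore = ecore, norb = M, nelec = nelec, ms2 = ms2)
}
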