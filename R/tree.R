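# Adaptive multiwavelet representation of real functions on the cube
# [-L, L]^3.  A tree stores scaling-coefficient blocks of (k+1)^3 reals for
# every node it has visited; leaves carry the working representation and
# internal nodes hold the exact two-scale filtered coefficients of their
# children.  All coefficients refer to the unit-cube rescaling
# ft(X) = (2L)^{3/2} f(2L X - L), so that L2 norms and inner products agree
# with their physical values.

key_of <- function(n, l) paste(n, l[1], l[2], l[3], sep = ".")

key_parse <- function(key) as.integer(strsplit(key, ".", fixed = TRUE)[[1]])

child_bits <- as.matrix(expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1))

#' Create an empty multiwavelet function tree
#' @param basis an \code{mw_basis} object.
#' @param L half-width of the cubic domain (bohr).
#' @param prec requested relative precision \eqn{p}.
#' @param maxdepth maximum refinement scale.
#' @return an object of class \code{mw_tree}.
#' @keywords internal
mw_tree_new <- function(basis, L, prec, maxdepth = 20L) {
  t <- new.env(parent = emptyenv())
  t$basis <- basis
  t$L <- L
  t$prec <- prec
  t$maxdepth <- as.integer(maxdepth)
  t$blocks <- new.env(hash = TRUE, parent = emptyenv())
  t$leaf <- new.env(hash = TRUE, parent = emptyenv())
  t$norm_est <- 0
  t$capped <- FALSE
  class(t) <- "mw_tree"
  t
}

tree_keys <- function(tree) ls(tree$blocks)

tree_nnode <- function(tree) length(tree_keys(tree))

tree_scales <- function(tree) {
  ks <- tree_keys(tree)
  if (!length(ks)) return(integer())
  as.integer(vapply(strsplit(ks, ".", fixed = TRUE), `[[`, "", 1L))
}

get_block <- function(tree, key) get(key, envir = tree$blocks, inherits = FALSE)

has_node <- function(tree, key) exists(key, envir = tree$blocks, inherits = FALSE)

is_leaf <- function(tree, key) exists(key, envir = tree$leaf, inherits = FALSE)

set_block <- function(tree, key, block, leaf = FALSE) {
  assign(key, block, envir = tree$blocks)
  if (leaf) assign(key, TRUE, envir = tree$leaf)
  else if (is_leaf(tree, key)) rm(list = key, envir = tree$leaf)
  invisible(tree)
}

drop_node <- function(tree, key) {
  if (has_node(tree, key)) rm(list = key, envir = tree$blocks)
  if (is_leaf(tree, key)) rm(list = key, envir = tree$leaf)
}

# descend a parent scaling block to child b (0/1 bits per dimension);
# exact because V_n is contained in V_{n+1}
descend_block <- function(basis, s, bits) {
  D1 <- t(if (bits[1] == 0) basis$H0 else basis$H1)
  D2 <- t(if (bits[2] == 0) basis$H0 else basis$H1)
  D3 <- t(if (bits[3] == 0) basis$H0 else basis$H1)
  cpp_mode3(D1, D2, D3, s)
}

# scaling block of (n, l) from the stored tree, descending from the deepest
# stored ancestor when (n, l) itself was pruned; zero outside the domain
block_at <- function(tree, n, l) {
  if (any(l < 0L) || any(l >= 2^n)) return(numeric(tree$basis$k1^3))
  nn <- n
  ll <- l
  path <- list()
  while (!has_node(tree, key_of(nn, ll))) {
    if (nn == 0L) return(numeric(tree$basis$k1^3))
    path[[length(path) + 1L]] <- ll %% 2L
    ll <- ll %/% 2L
    nn <- nn - 1L
  }
  s <- get_block(tree, key_of(nn, ll))
  for (i in rev(seq_along(path))) s <- descend_block(tree$basis, s, path[[i]])
  s
}

# stack 8 child blocks into the joint child-representation block of the
# parent; per-dimension index is b*(k+1) + j
joint_from_children <- function(k1, children) {
  J <- array(0, rep(2L * k1, 3L))
  for (b in 1:8) {
    bb <- child_bits[b, ]
    J[bb[1] * k1 + 1:k1, bb[2] * k1 + 1:k1, bb[3] * k1 + 1:k1] <-
      array(children[[b]], rep(k1, 3L))
  }
  as.numeric(J)
}

joint_child <- function(k1, joint, bits) {
  J <- array(joint, rep(2L * k1, 3L))
  as.numeric(J[bits[1] * k1 + 1:k1, bits[2] * k1 + 1:k1, bits[3] * k1 + 1:k1])
}

filter_up <- function(basis, joint) cpp_mode3(basis$H, basis$H, basis$H, joint)

joint_from_parent <- function(basis, s) cpp_mode3(t(basis$H), t(basis$H), t(basis$H), s)

# quadrature projection of f (physical function of x, y, z) on node (n, l)
node_project <- function(f, basis, L, n, l) {
  q <- basis$x
  X <- (l[1] + q) / 2^n
  Y <- (l[2] + q) / 2^n
  Z <- (l[3] + q) / 2^n
  g <- expand.grid(x = X, y = Y, z = Z)
  vals <- f(2 * L * g$x - L, 2 * L * g$y - L, 2 * L * g$z - L)
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals))[1]
    stop(sprintf("non-finite function value at (%.6g, %.6g, %.6g)",
                 2 * L * g$x[bad] - L, 2 * L * g$y[bad] - L, 2 * L * g$z[bad] - L))
  }
  vals <- vals * (2 * L)^1.5
  2^(-1.5 * n) * cpp_mode3(basis$P, basis$P, basis$P, vals)
}

#' Project a function onto an adaptive multiwavelet tree
#'
#' Adaptive projection with the thresholding rule that a node is refined
#' while its wavelet-block norm exceeds \eqn{p\,\|f\|\,2^{-n/2}}.  The
#' wavelet norm of a node is estimated from a one-level-deeper quadrature
#' projection of its children.
#'
#' @param f vectorized function of three physical coordinate vectors
#'   (bohr), returning function values.
#' @param basis an \code{mw_basis}.
#' @param prec requested precision \eqn{p} (relative to \eqn{\|f\|}).
#' @param L domain half-width in bohr (default 32).
#' @param maxdepth maximum scale (default 20); exceeding it warns and caps.
#' @param force_scale refine uniformly down to this scale before the
#'   adaptive criterion takes over (default 2).
#' @param guide optional 3 x m matrix of physical points (e.g. nuclear
#'   positions) whose containing boxes are refined to \code{guide_scale}
#'   regardless of the local wavelet norm, protecting narrow features from
#'   being missed by coarse quadrature.
#' @param guide_scale forced scale for guide boxes (default 6).
#' @return an \code{mw_tree}.
#' @export
mw_project <- function(f, basis, prec, L = 32, maxdepth = 20L,
                       force_scale = 2L, guide = NULL, guide_scale = 6L) {
  tree <- mw_tree_new(basis, L, prec, maxdepth)
  k1 <- basis$k1
  guide_unit <- if (is.null(guide)) NULL else (guide + L) / (2 * L)
  sq_est <- 0

  has_guide <- function(n, l) {
    if (is.null(guide_unit) || n > guide_scale) return(FALSE)
    w <- 2^(-n)
    any(guide_unit[1, ] >= l[1] * w & guide_unit[1, ] <= (l[1] + 1) * w &
        guide_unit[2, ] >= l[2] * w & guide_unit[2, ] <= (l[2] + 1) * w &
        guide_unit[3, ] >= l[3] * w & guide_unit[3, ] <= (l[3] + 1) * w)
  }

  build <- function(n, l) {
    children <- vector("list", 8L)
    csq <- 0
    for (b in 1:8) {
      cl <- 2L * l + as.integer(child_bits[b, ])
      children[[b]] <- node_project(f, basis, L, n + 1L, cl)
      csq <- csq + sum(children[[b]]^2)
    }
    joint <- joint_from_children(k1, children)
    s <- filter_up(basis, joint)
    sq_est <<- max(sq_est, csq, sum(s^2))
    dnorm <- sqrt(max(0, csq - sum(s^2)))
    tau <- prec * sqrt(sq_est) * 2^(-n / 2)
    refine <- (n < force_scale) || dnorm > tau || has_guide(n, l)
    if (refine && n + 1L >= maxdepth) {
      tree$capped <- TRUE
      refine <- FALSE
    }
    if (refine) {
      set_block(tree, key_of(n, l), s, leaf = FALSE)
      kids <- vector("list", 8L)
      for (b in 1:8) {
        cl <- 2L * l + as.integer(child_bits[b, ])
        kids[[b]] <- build(n + 1L, cl)
      }
      # replace this node's block by the exact filtration of its children
      joint2 <- joint_from_children(k1, kids)
      s2 <- filter_up(basis, joint2)
      set_block(tree, key_of(n, l), s2, leaf = FALSE)
      s2
    } else {
      set_block(tree, key_of(n, l), s, leaf = TRUE)
      s
    }
  }

  build(0L, c(0L, 0L, 0L))
  if (tree$capped)
    warning("refinement capped at maxdepth = ", maxdepth)
  tree$norm_est <- mw_norm(tree)
  tree
}

#' L2 norm of a tree
#' @param tree an \code{mw_tree}.
#' @return the L2 norm (physical units).
#' @export
mw_norm <- function(tree) {
  ks <- ls(tree$leaf)
  if (!length(ks)) return(0)
  sqrt(sum(vapply(ks, function(k) sum(get_block(tree, k)^2), 0)))
}

#' Inner product of two trees
#'
#' Exact sum over shared coefficient blocks after reconciling the two
#' adaptive grids (coarser blocks are descended through the two-scale
#' relation, which is exact).
#' @param a,b trees on the same basis and domain.
#' @return \eqn{\int a\, b\, d^3r} in physical units.
#' @export
mw_inner <- function(a, b) {
  check_compat(a, b)
  rec <- function(n, l, sa, sb) {
    ka <- key_of(n, l)
    a_leaf <- is_leaf(a, ka) || (!has_node(a, ka) && !is.null(sa))
    b_leaf <- is_leaf(b, ka) || (!has_node(b, ka) && !is.null(sb))
    if (a_leaf && b_leaf) {
      va <- if (has_node(a, ka)) get_block(a, ka) else sa
      vb <- if (has_node(b, ka)) get_block(b, ka) else sb
      return(sum(va * vb))
    }
    tot <- 0
    for (bb in 1:8) {
      bits <- as.integer(child_bits[bb, ])
      cl <- 2L * l + bits
      nsa <- if (a_leaf) {
        base <- if (has_node(a, ka)) get_block(a, ka) else sa
        descend_block(a$basis, base, bits)
      } else NULL
      nsb <- if (b_leaf) {
        base <- if (has_node(b, ka)) get_block(b, ka) else sb
        descend_block(b$basis, base, bits)
      } else NULL
      tot <- tot + rec(n + 1L, cl, nsa, nsb)
    }
    tot
  }
  rec(0L, c(0L, 0L, 0L), NULL, NULL)
}

check_compat <- function(a, b) {
  if (a$basis$k != b$basis$k || a$L != b$L)
    stop("trees live on different bases or domains")
  invisible(TRUE)
}

# union leaf set of a list of trees: keys where every tree is leaf-or-pruned
union_leaves <- function(trees) {
  internal <- new.env(hash = TRUE, parent = emptyenv())
  leaves <- character()
  for (t in trees) {
    for (k in tree_keys(t)) if (!is_leaf(t, k)) assign(k, TRUE, envir = internal)
  }
  rec <- function(n, l) {
    k <- key_of(n, l)
    if (exists(k, envir = internal, inherits = FALSE)) {
      for (b in 1:8) rec(n + 1L, 2L * l + as.integer(child_bits[b, ]))
    } else {
      leaves <<- c(leaves, k)
    }
  }
  rec(0L, c(0L, 0L, 0L))
  leaves
}

# rebuild internal blocks bottom-up from the leaf blocks
build_internals <- function(tree) {
  ks <- tree_keys(tree)
  ns <- tree_scales(tree)
  k1 <- tree$basis$k1
  if (!length(ks)) return(invisible(tree))
  depth <- max(ns)
  if (depth == 0L) return(invisible(tree))
  for (n in seq(depth, 1L)) {
    ks <- tree_keys(tree)
    ns <- tree_scales(tree)
    sel <- ks[ns == n]
    if (!length(sel)) next
    parents <- unique(vapply(sel, function(k) {
      v <- key_parse(k)
      key_of(v[1] - 1L, v[2:4] %/% 2L)
    }, ""))
    for (pk in parents) {
      v <- key_parse(pk)
      children <- vector("list", 8L)
      for (b in 1:8) {
        bits <- as.integer(child_bits[b, ])
        ck <- key_of(v[1] + 1L, 2L * v[2:4] + bits)
        children[[b]] <- if (has_node(tree, ck)) get_block(tree, ck)
          else numeric(k1^3)  # should not happen on a connected tree
      }
      set_block(tree, pk, filter_up(tree$basis, joint_from_children(k1, children)),
                leaf = FALSE)
    }
  }
  invisible(tree)
}

# prune: merge children into their parent wherever the parent's wavelet
# norm is below the threshold
mw_truncate <- function(tree, prec = tree$prec) {
  nrm <- mw_norm(tree)
  if (nrm == 0) return(tree)
  repeat {
    ks <- tree_keys(tree)
    ns <- tree_scales(tree)
    merged <- FALSE
    for (i in order(ns, decreasing = TRUE)) {
      k <- ks[i]
      if (!has_node(tree, k) || is_leaf(tree, k)) next
      v <- key_parse(k)
      n <- v[1]
      allleaf <- TRUE
      csq <- 0
      for (b in 1:8) {
        ck <- key_of(n + 1L, 2L * v[2:4] + as.integer(child_bits[b, ]))
        if (!is_leaf(tree, ck)) { allleaf <- FALSE; break }
        csq <- csq + sum(get_block(tree, ck)^2)
      }
      if (!allleaf) next
      s <- get_block(tree, k)
      dnorm <- sqrt(max(0, csq - sum(s^2)))
      if (dnorm <= prec * nrm * 2^(-n / 2)) {
        for (b in 1:8) {
          ck <- key_of(n + 1L, 2L * v[2:4] + as.integer(child_bits[b, ]))
          drop_node(tree, ck)
        }
        assign(k, TRUE, envir = tree$leaf)
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  tree$norm_est <- mw_norm(tree)
  tree
}

#' Linear combination of trees
#'
#' Represents \eqn{\sum_i w_i f_i} on the union grid of the inputs, then
#' re-thresholds at the target precision.
#' @param trees list of \code{mw_tree} objects on a common basis/domain.
#' @param w numeric weights.
#' @param prune re-threshold the result (default TRUE).
#' @return an \code{mw_tree}.
#' @export
mw_add <- function(trees, w, prune = TRUE) {
  stopifnot(length(trees) == length(w), length(trees) >= 1)
  for (t in trees[-1]) check_compat(trees[[1]], t)
  out <- mw_tree_new(trees[[1]]$basis, trees[[1]]$L, trees[[1]]$prec,
                     trees[[1]]$maxdepth)
  leaves <- union_leaves(trees)
  for (k in leaves) {
    v <- key_parse(k)
    acc <- numeric(out$basis$k1^3)
    for (i in seq_along(trees)) {
      if (w[i] == 0) next
      acc <- acc + w[i] * block_at(trees[[i]], v[1], v[2:4])
    }
    set_block(out, k, acc, leaf = TRUE)
  }
  build_internals(out)
  if (prune) mw_truncate(out)
  out$norm_est <- mw_norm(out)
  out
}

# values of a tree block at the tensor quadrature points of node (n,l)
block_values <- function(basis, s, n) {
  2^(1.5 * n) * cpp_mode3(basis$E, basis$E, basis$E, s)
}

#' Pointwise product of two trees
#'
#' Adaptive: the product is projected on the union grid and refined where
#' the one-level-deeper residual of the product exceeds the threshold.
#' @param a,b trees on the same basis/domain.
#' @param prec precision for the product (default: \code{a$prec}).
#' @return an \code{mw_tree} representing \eqn{a\,b}.
#' @export
mw_multiply <- function(a, b, prec = a$prec) {
  check_compat(a, b)
  basis <- a$basis
  k1 <- basis$k1
  L <- a$L
  out <- mw_tree_new(basis, L, prec, a$maxdepth)
  D0 <- t(basis$H0)
  D1 <- t(basis$H1)

  sq_est <- 0
  build <- function(n, l, sa, sb) {
    # sa, sb: blocks of the factors at (n, l), stored or exactly descended
    pn <- cpp_product_node(sa, sb, D0, D1, basis$E, basis$P,
                           basis$H0, basis$H1,
                           2^(1.5 * (n + 1)) * (2 * L)^(-1.5))
    s <- as.numeric(pn$s)
    csq <- pn$csq
    sq_est <<- max(sq_est, csq, sum(s^2))
    dnorm <- sqrt(max(0, csq - sum(s^2)))
    tau <- prec * sqrt(sq_est) * 2^(-n / 2)
    k <- key_of(n, l)
    # force the union structure so that no feature present in either
    # factor is skipped before the adaptive criterion sees it
    must <- exists(k, envir = forced_env, inherits = FALSE)
    if ((dnorm > tau || must) && n + 1L < a$maxdepth) {
      set_block(out, k, s, leaf = FALSE)
      for (bb in 1:8) {
        bits <- as.integer(child_bits[bb, ])
        cl <- 2L * l + bits
        ck <- key_of(n + 1L, cl)
        nsa <- if (has_node(a, ck)) get_block(a, ck) else descend_block(basis, sa, bits)
        nsb <- if (has_node(b, ck)) get_block(b, ck) else descend_block(basis, sb, bits)
        build(n + 1L, cl, nsa, nsb)
      }
      # refresh from actual children
      ch <- lapply(1:8, function(bb) {
        bits <- as.integer(child_bits[bb, ])
        get_block(out, key_of(n + 1L, 2L * l + bits))
      })
      set_block(out, k, filter_up(basis, joint_from_children(k1, ch)), leaf = FALSE)
    } else {
      set_block(out, k, s, leaf = TRUE)
    }
  }

  forced_env <- new.env(hash = TRUE, parent = emptyenv())
  for (t in list(a, b)) for (k in tree_keys(t))
    if (!is_leaf(t, k)) assign(k, TRUE, envir = forced_env)

  rk <- key_of(0L, c(0L, 0L, 0L))
  build(0L, c(0L, 0L, 0L), get_block(a, rk), get_block(b, rk))
  mw_truncate(out)
  out$norm_est <- mw_norm(out)
  out
}

#' Evaluate a tree at physical points
#' @param tree an \code{mw_tree}.
#' @param x,y,z coordinate vectors (bohr).
#' @return function values.
#' @export
mw_eval <- function(tree, x, y, z) {
  basis <- tree$basis
  L <- tree$L
  k1 <- basis$k1
  n_out <- length(x)
  out <- numeric(n_out)
  X <- cbind((x + L) / (2 * L), (y + L) / (2 * L), (z + L) / (2 * L))
  for (i in seq_len(n_out)) {
    p <- pmin(pmax(X[i, ], 0), 1 - 1e-15)
    n <- 0L
    l <- c(0L, 0L, 0L)
    repeat {
      k <- key_of(n, l)
      if (!has_node(tree, k)) { # pruned region: back up one level
        n <- n - 1L
        l <- l %/% 2L
        break
      }
      if (is_leaf(tree, k)) break
      n <- n + 1L
      l <- as.integer(floor(p * 2^n))
    }
    s <- get_block(tree, key_of(n, l))
    xi <- p * 2^n - l
    e1 <- leg_eval(xi[1], basis$k)
    e2 <- leg_eval(xi[2], basis$k)
    e3 <- leg_eval(xi[3], basis$k)
    out[i] <- 2^(1.5 * n) * as.numeric(cpp_mode3(e1, e2, e3, s)) / (2 * L)^1.5
  }
  out
}

#' Weak first derivative of a tree along one axis
#'
#' Applies the central (averaged-flux) multiwavelet derivative stencil on
#' the leaf grid: the derivative block of a cell couples to the cell itself
#' and its two same-scale neighbors along the axis.
#' @param tree an \code{mw_tree}.
#' @param axis 1, 2 or 3.
#' @return an \code{mw_tree} for \eqn{\partial f/\partial x_{axis}}.
#' @export
mw_deriv <- function(tree, axis) {
  stopifnot(axis %in% 1:3)
  basis <- tree$basis
  k1 <- basis$k1
  D <- deriv_matrices(basis)
  out <- mw_tree_new(basis, tree$L, tree$prec, tree$maxdepth)
  ks <- ls(tree$leaf)
  if (!length(ks)) return(out)
  Ident <- diag(1, k1)
  e0 <- leg_eval(0, tree$basis$k)[1, ]
  e1 <- leg_eval(1, tree$basis$k)[1, ]
  for (k in ks) {
    v <- key_parse(k)
    n <- v[1]
    l <- v[2:4]
    em <- ep <- integer(3)
    em[axis] <- -1L
    s_m <- block_at(tree, n, l + em)
    s_0 <- get_block(tree, k)
    ep[axis] <- 1L
    s_p <- block_at(tree, n, l + ep)
    # one-sided flux at the domain faces (free boundary): the averaged
    # boundary value degenerates to the interior trace
    Bm <- D$B
    if (l[axis] == 0L) Bm <- Bm - 0.5 * outer(e0, e0)
    if (l[axis] == 2L^n - 1L) Bm <- Bm + 0.5 * outer(e1, e1)
    mats <- function(M) {
      if (axis == 1) list(M, Ident, Ident)
      else if (axis == 2) list(Ident, M, Ident)
      else list(Ident, Ident, M)
    }
    mA <- mats(D$A); mB <- mats(Bm); mC <- mats(D$C)
    res <- cpp_mode3(mA[[1]], mA[[2]], mA[[3]], s_m) +
      cpp_mode3(mB[[1]], mB[[2]], mB[[3]], s_0) +
      cpp_mode3(mC[[1]], mC[[2]], mC[[3]], s_p)
    set_block(out, k, res * 2^n / (2 * tree$L), leaf = TRUE)
  }
  build_internals(out)
  out$norm_est <- mw_norm(out)
  out
}

deriv_matrices <- function(basis) {
  if (!is.null(basis$derivmats)) return(basis$derivmats)
  k <- basis$k
  e0 <- leg_eval(0, k)[1, ]
  e1 <- leg_eval(1, k)[1, ]
  # -int phi'_j phi_m + 0.5 phi_j(1)phi_m(1) - 0.5 phi_j(0)phi_m(0)
  Dm <- leg_deriv(basis$x, k)
  inner_dp <- t(Dm) %*% (basis$E * basis$w)   # int phi'_j phi_m
  B <- -inner_dp + 0.5 * outer(e1, e1) - 0.5 * outer(e0, e0)
  C <- 0.5 * outer(e1, e0)
  A <- -0.5 * outer(e0, e1)
  list(A = A, B = B, C = C)
}

#' Save / load a collection of trees as a binary checkpoint
#'
#' Layout: int32 magic, k, maxdepth, number of trees; double L, prec; then
#' per tree an int32 node count followed, per node, by int32 (n, l1, l2,
#' l3, leaf) and the (k+1)^3 coefficient doubles.
#' @param trees list of \code{mw_tree} objects (a shared basis is assumed).
#' @param path file path.
#' @export
mw_save <- function(trees, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  b <- trees[[1]]$basis
  writeBin(c(77001L, b$k, trees[[1]]$maxdepth, length(trees)), con)
  writeBin(c(trees[[1]]$L, trees[[1]]$prec), con)
  for (t in trees) {
    ks <- tree_keys(t)
    writeBin(length(ks), con)
    for (k in ks) {
      v <- key_parse(k)
      writeBin(c(v, as.integer(is_leaf(t, k))), con)
      writeBin(as.numeric(get_block(t, k)), con)
    }
  }
  invisible(path)
}

#' @rdname mw_save
#' @export
mw_load <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- readBin(con, "integer", 4L)
  if (hd[1] != 77001L) stop("not a multiwavelet checkpoint file")
  dd <- readBin(con, "double", 2L)
  basis <- mw_basis(hd[2])
  k13 <- basis$k1^3
  trees <- vector("list", hd[4])
  for (i in seq_len(hd[4])) {
    t <- mw_tree_new(basis, dd[1], dd[2], hd[3])
    nn <- readBin(con, "integer", 1L)
    for (j in seq_len(nn)) {
      v <- readBin(con, "integer", 5L)
      blk <- readBin(con, "double", k13)
      set_block(t, key_of(v[1], v[2:4]), blk, leaf = v[5] == 1L)
    }
    t$norm_est <- mw_norm(t)
    trees[[i]] <- t
  }
  trees
}

#' @export
print.mw_tree <- function(x, ...) {
  cat(sprintf("<mw_tree k=%d p=%.2g L=%g nodes=%d depth=%d norm=%.8g>\n",
              x$basis$k, x$prec, x$L, tree_nnode(x),
              max(c(0L, tree_scales(x))), x$norm_est))
  invisible(x)
}

#' Refine a tree uniformly by descending leaves
#'
#' Replaces every leaf by its 8 two-scale-descended children (repeated
#' \code{nlev} times).  The represented function is unchanged; the deeper
#' grid sharpens grid-limited stencil operations such as differentiation.
#' @param tree an \code{mw_tree}.
#' @param nlev number of extra levels (default 1).
#' @return an \code{mw_tree} representing the same function.
#' @export
mw_refine <- function(tree, nlev = 1L) {
  out <- mw_tree_new(tree$basis, tree$L, tree$prec, tree$maxdepth)
  for (k in tree_keys(tree))
    set_block(out, k, get_block(tree, k), leaf = is_leaf(tree, k))
  for (rep in seq_len(nlev)) {
    for (k in ls(out$leaf)) {
      v <- key_parse(k)
      s <- get_block(out, k)
      for (b in 1:8) {
        bits <- as.integer(child_bits[b, ])
        set_block(out, key_of(v[1] + 1L, 2L * v[2:4] + bits),
                  descend_block(out$basis, s, bits), leaf = TRUE)
      }
      rm(list = k, envir = out$leaf)
    }
  }
  out$norm_est <- tree$norm_est
  out
}
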