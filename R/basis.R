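#' Legendre scaling basis on the unit interval
#'
#' Constructs the order-\code{k} multiwavelet scaling space \eqn{V_0}:
#' the \eqn{k+1} normalized shifted Legendre polynomials
#' \eqn{\phi_j(x) = \sqrt{2j+1}\, P_j(2x-1)} on \eqn{(0,1)}, together with
#' the Gauss-Legendre quadrature, the evaluation/projection matrices and
#' the two-scale filter pair \eqn{(H^0, H^1)} used throughout the adaptive
#' tree algorithms.  The basis is orthonormal on \eqn{(0,1)} and reproduces
#' polynomials of degree \eqn{\le k} exactly.
#'
#' @param k polynomial order (integer \eqn{\ge 1}); the space has
#'   \code{k + 1} functions per dimension.
#' @return An object of class \code{mw_basis}: a list with the order
#'   \code{k}, quadrature nodes \code{x} and weights \code{w} on
#'   \eqn{(0,1)}, evaluation matrix \code{E} (\code{q x (k+1)}),
#'   projection matrix \code{P} (\code{(k+1) x q}, \code{P = t(E) diag(w)}),
#'   filter matrices \code{H0}, \code{H1} with
#'   \eqn{s^{n}_{l} = H^0 s^{n+1}_{2l} + H^1 s^{n+1}_{2l+1}}, and the
#'   monomial coefficient matrix \code{mono} with
#'   \eqn{\phi_j(x) = \sum_p \code{mono}[j+1, p+1]\, x^p}.
#' @export
mw_basis <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == round(k))
  k <- as.integer(k)
  k1 <- k + 1L
  gl <- pracma::gaussLegendre(k1, 0, 1)
  x <- gl$x
  w <- gl$w
  E <- leg_eval(x, k)            # q x k1
  P <- sweep(t(E), 2L, w, `*`)   # k1 x q
  # two-scale filters: H0[j,m] = (1/sqrt(2)) int phi_j(y/2) phi_m(y) dy
  # integrand is a polynomial of degree <= 2k: k+1-point GL is exact
  E_half0 <- leg_eval(x / 2, k)
  E_half1 <- leg_eval((x + 1) / 2, k)
  H0 <- (1 / sqrt(2)) * t(E_half0) %*% (E * w)
  H1 <- (1 / sqrt(2)) * t(E_half1) %*% (E * w)
  structure(list(k = k, k1 = k1, x = x, w = w, E = E, P = P,
                 H0 = H0, H1 = H1, H = cbind(H0, H1),
                 mono = leg_mono(k)),
            class = "mw_basis")
}

#' Evaluate the normalized shifted Legendre polynomials
#'
#' @param x numeric vector of points (any real values; the basis is used
#'   on \eqn{(0,1)} but the polynomial extension is well defined).
#' @param k maximum order.
#' @return matrix \code{length(x) x (k+1)}; column \code{j+1} holds
#'   \eqn{\sqrt{2j+1} P_j(2x-1)}.
#' @keywords internal
leg_eval <- function(x, k) {
  t <- 2 * x - 1
  n <- length(x)
  out <- matrix(0, n, k + 1L)
  p0 <- rep(1, n)
  out[, 1L] <- p0
  if (k >= 1) {
    p1 <- t
    out[, 2L] <- p1 * sqrt(3)
    if (k >= 2) {
      for (j in 2:k) {
        p2 <- ((2 * j - 1) * t * p1 - (j - 1) * p0) / j
        out[, j + 1L] <- p2 * sqrt(2 * j + 1)
        p0 <- p1
        p1 <- p2
      }
    }
  }
  out
}

#' First derivatives of the scaling functions
#' @inheritParams leg_eval
#' @return matrix \code{length(x) x (k+1)} of \eqn{\phi_j'(x)}.
#' @keywords internal
leg_deriv <- function(x, k) {
  # P'_{j+1}(t) = (2j+1) P_j(t) + P'_{j-1}(t); chain rule factor 2
  t <- 2 * x - 1
  n <- length(x)
  P <- matrix(0, n, k + 2L)
  P[, 1L] <- 1
  if (k + 1L >= 1L) P[, 2L] <- t
  if (k >= 1) for (j in 2:(k + 1L)) {
    P[, j + 1L] <- ((2 * j - 1) * t * P[, j] - (j - 1) * P[, j - 1L]) / j
  }
  D <- matrix(0, n, k + 1L)
  dprev <- rep(0, n)  # P'_{j-2}
  dcur <- rep(0, n)   # P'_{j-1}
  if (k >= 1) {
    for (j in 1:k) {
      dnew <- (2 * j - 1) * P[, j] + dprev   # P'_j = (2j-1) P_{j-1} + P'_{j-2}
      D[, j + 1L] <- dnew * 2 * sqrt(2 * j + 1)
      dprev <- dcur
      dcur <- dnew
    }
  }
  D
}

# monomial coefficients of the normalized shifted Legendre polynomials
leg_mono <- function(k) {
  k1 <- k + 1L
  # P_j(2x-1) via recurrence in monomial coefficients of x
  co <- matrix(0, k1, k1)
  co[1L, 1L] <- 1
  if (k >= 1) {
    co[2L, 1:2] <- c(-1, 2)
    if (k >= 2) for (j in 2:k) {
      # (j) P_j = (2j-1)(2x-1) P_{j-1} - (j-1) P_{j-2}
      prev <- co[j, ]
      shifted <- c(0, prev[-k1]) * 2        # 2x * prev
      co[j + 1L, ] <- ((2 * j - 1) * (shifted - prev) - (j - 1) * co[j - 1L, ]) / j
    }
  }
  co * sqrt(2 * seq_len(k1) - 1)
}
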