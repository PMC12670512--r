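# Separated (sum-of-Gaussians) representations of the radial kernels
#   Poisson:            1/(4 pi r)
#   bound-state Helmholtz: exp(-mu r)/(4 pi r),  Green's fn of (-lap + mu^2)
# built from the integral representation
#   exp(-mu r)/r = (2/sqrt(pi)) Int exp(-r^2 e^{2s} - mu^2 e^{-2s}/4 + s) ds
# discretized by the trapezoid rule on a truncated s-interval.

#' Expand a radial kernel as a sum of Gaussians
#'
#' Produces coefficients and exponents such that
#' \eqn{\sum_t c_t e^{-a_t r^2}} approximates \eqn{e^{-\mu r}/(4\pi r)}
#' with pointwise relative error \code{<= eps} on \code{[rmin, rmax]}.
#' The term count grows logarithmically in \code{rmax/rmin} and
#' \code{1/eps}.
#'
#' @param mu decay parameter (1/bohr), \eqn{\mu \ge 0}; \eqn{\mu = 0}
#'   gives the Poisson kernel.
#' @param eps requested relative accuracy.
#' @param rmin,rmax validity range in bohr, \code{0 < rmin < rmax}.
#' @return an object of class \code{mw_kernel} with fields \code{coef},
#'   \code{expo}, \code{mu}, \code{eps}, \code{rmin}, \code{rmax}.
#' @export
mw_kernel_expand <- function(mu, eps, rmin, rmax) {
  stopifnot(mu >= 0, rmin > 0, rmin < rmax)
  if (eps < 1e-13)
    stop("requested accuracy below the attainable floor (about 1e-13)")
  key <- sprintf("%.12g_%.3g_%.6g_%.6g", mu, eps, rmin, rmax)
  hit <- kernel_cache[[key]]
  if (!is.null(hit)) return(hit)

  # strict relative accuracy is enforced where the kernel is non-negligible
  # (mu r <= 5); beyond that the error is controlled relative to the
  # Poisson kernel 1/(4 pi r), which bounds the absolute error of the
  # convolution by eps times a Coulomb integral of |f|
  rmax_eff <- if (mu > 0) max(min(rmax, 5 / mu), 10 * rmin) else rmax
  rr <- exp(seq(log(rmin), log(rmax), length.out = 120))
  target <- exp(-mu * rr) / (4 * pi * rr)
  short <- rr <= rmax_eff
  h <- 1 / (0.2 - 0.47 * log10(eps))
  s_hi <- 0.5 * log((log(1 / eps) + 6) / rmin^2) + 1
  s_lo <- log(eps * sqrt(pi) / 2) - log(rmax) - 1

  build <- function(h) {
    s <- seq(s_lo, s_hi, by = h)
    expo <- exp(2 * s)
    coef <- h * (2 / sqrt(pi)) * exp(s - mu^2 * exp(-2 * s) / 4) / (4 * pi)
    keep <- coef > 0
    list(coef = coef[keep], expo = expo[keep])
  }
  relerr <- function(kk) {
    approx <- drop(exp(-outer(rr^2, kk$expo)) %*% kk$coef)
    d <- abs(approx - target)
    max(max(d * 4 * pi * rr), max((d / target)[short]))
  }
  kk <- build(h)
  tries <- 0
  while (relerr(kk) > eps && tries < 10) {
    h <- h / 1.25
    kk <- build(h)
    tries <- tries + 1
  }
  err <- relerr(kk)
  if (err > eps)
    stop(sprintf("kernel expansion cannot reach eps = %g; attainable about %g",
                 eps, err))
  # prune terms whose best-case contribution is negligible everywhere
  contrib <- exp(-outer(rr^2, kk$expo)) * rep(kk$coef, each = length(rr))
  keep <- apply(contrib * (4 * pi * rr), 2, max) > eps / (10 * length(kk$coef))
  out <- structure(list(coef = kk$coef[keep], expo = kk$expo[keep],
                        mu = mu, eps = eps, rmin = rmin, rmax = rmax,
                        rmax_eff = rmax_eff, relerr = err),
                   class = "mw_kernel")
  kernel_cache[[key]] <- out
  out
}

kernel_cache <- new.env(parent = emptyenv())

#' Evaluate a separated kernel at radii
#' @param kern an \code{mw_kernel}.
#' @param r radii (bohr).
#' @return kernel values.
#' @export
mw_kernel_eval <- function(kern, r) {
  drop(exp(-outer(r^2, kern$expo)) %*% kern$coef)
}

#' @export
print.mw_kernel <- function(x, ...) {
  cat(sprintf("<mw_kernel mu=%.6g terms=%d eps=%.1g range=[%.3g, %.3g] relerr=%.2g>\n",
              x$mu, length(x$coef), x$eps, x$rmin, x$rmax, x$relerr))
  invisible(x)
}
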