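#' Matérn 5/2 covariance kernel and derivatives
#'
#' Radial kernel used by the gradient-enhanced Kriging surrogate.  The
#' correlation between two points is a function of the anisotropically
#' scaled Euclidean distance \code{d}: each coordinate difference is divided
#' by a per-dimension characteristic length \code{l_k} before the norm is
#' taken.  The Matérn 5/2 family is twice differentiable, which is the
#' minimum smoothness for conditioning a Gaussian process on gradients while
#' still exposing a predictor Hessian.
#'
#' @name matern
#' @keywords internal
NULL

SQRT5 <- sqrt(5)

#' Anisotropically scaled distance
#'
#' \code{d = sqrt(sum_k ((x_k - xp_k) / l_k)^2)}, the argument of the
#' Matérn 5/2 correlation.
#'
#' @param x,xp numeric vectors of equal length (points in the reduced space).
#' @param l positive numeric vector of characteristic lengths, same length.
#' @return a single nonnegative number; 0 iff \code{x == xp}.
#' @export
scaled_distance <- function(x, xp, l) {
  if (length(x) != length(xp) || length(x) != length(l))
    stop("scaled_distance: x, xp and l must have the same length")
  if (any(l <= 0)) stop("scaled_distance: characteristic lengths must be positive")
  sqrt(sum(((x - xp) / l)^2))
}

#' Matérn 5/2 correlation as a function of scaled distance
#'
#' \code{f(d) = (1 + sqrt(5) d + 5 d^2 / 3) exp(-sqrt(5) d)}; equals 1 at
#' coincident points and decays monotonically to zero.
#'
#' @param d nonnegative scaled distance (vectorized).
#' @return correlation value(s) in (0, 1].
#' @export
matern52 <- function(d) {
  if (any(d < 0)) stop("matern52: d must be nonnegative")
  a <- SQRT5 * d
  (1 + a + a^2 / 3) * exp(-a)
}

## Radial derivative helpers.  Writing f as F(s) with s = d^2 gives smooth
## coefficients for all coordinate derivatives used by the surrogate:
##   dF/ds   = -(5/6) (1 + sqrt5 d) exp(-sqrt5 d)
##   d2F/ds2 = (25/12) exp(-sqrt5 d)
##   d3F/ds3 = -(25 sqrt5 / 24) exp(-sqrt5 d) / d   (removable via *d)
.m52_F1 <- function(d) -(5 / 6) * (1 + SQRT5 * d) * exp(-SQRT5 * d)
.m52_F2 <- function(d) (25 / 12) * exp(-SQRT5 * d)
## returns d * F'''(s); callers multiply by (tau/d) ratios so the d -> 0
## limit (zero) is handled without dividing by d
.m52_G3 <- function(d) -(25 * SQRT5 / 24) * exp(-SQRT5 * d)

#' Kernel value and first/second cross derivatives at a pair of points
#'
#' Returns the blocks needed to assemble the generalized covariance matrix:
#' the kernel value, its gradient with respect to each argument, and the
#' cross Hessian \code{d2 f / dx_k dxp_j}.  At coincident points the cross
#' Hessian is \code{diag(5 / (3 l_k^2))} and both gradients vanish.
#'
#' @inheritParams scaled_distance
#' @return list with \code{value}, \code{grad_x}, \code{grad_xp} (=
#'   \code{-grad_x}) and \code{cross_hessian} (K x K).
#' @export
kernel_block <- function(x, xp, l) {
  d <- scaled_distance(x, xp, l)   # validates inputs
  K <- length(x)
  tau <- (x - xp) / l
  F1 <- .m52_F1(d)
  F2 <- .m52_F2(d)
  grad_x <- 2 * F1 * tau / l
  ch <- -4 * F2 * tcrossprod(tau / l) - diag(2 * F1 / l^2, nrow = K)
  list(value = matern52(d), grad_x = grad_x, grad_xp = -grad_x,
       cross_hessian = ch)
}

#' Characteristic lengths from guess-Hessian eigenvalues
#'
#' Sets the per-dimension lengths noniteratively so that a surrogate built
#' from a single data point has predictor curvature \code{eps_k} along
#' dimension k: \code{l_k = sqrt(5 (mu - e_max) / (3 eps_k))}, where
#' \code{e_max} is the maximum energy among the data points and \code{mu}
#' the constant prior mean (default \code{e_max + 10} hartree).
#'
#' @param eps positive eigenvalues of the projected guess Hessian.
#' @param mu prior mean energy; must exceed \code{e_max}.
#' @param e_max maximum training energy.
#' @return numeric vector of characteristic lengths.
#' @export
lengths_from_eigenvalues <- function(eps, mu, e_max) {
  if (any(eps <= 0))
    stop("lengths_from_eigenvalues: eigenvalues must be positive (floor them first)")
  if (mu <= e_max)
    stop("lengths_from_eigenvalues: mu must exceed the maximum data energy")
  sqrt(5 * (mu - e_max) / (3 * eps))
}
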