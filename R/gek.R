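#' Gradient-enhanced Kriging surrogate
#'
#' Fits the GEK interpolant used by the restricted-variance optimizer.  The
#' model is conditioned on energies and gradients at up to 20 previous
#' points in a reduced coordinate space and predicts energy, gradient,
#' Hessian, and a variance that grows away from the data:
#' \deqn{E^*(x) = \mu + v(x)^T M^{-1} (y - 1\mu)}
#' where \code{M} is the generalized covariance matrix over all energy and
#' gradient observations (Matérn 5/2 kernel and its derivatives), \code{v}
#' the covariance vector of the prediction point with those observations,
#' and \code{1} has ones at energy positions only.  The prior mean
#' \code{mu} is set above the maximum training energy so the surrogate is
#' bounded with positive curvature far from the data.
#'
#' Observation order in \code{y} and \code{M}: all energies first, then
#' gradients grouped by data point (row-major over points, then dimension).
#'
#' @param coords m x K matrix of training coordinates (rows distinct).
#' @param energies length-m numeric vector of energies (hartree).
#' @param grads m x K matrix of gradients at the training coordinates.
#' @param lengths characteristic lengths (length K), see
#'   [lengths_from_eigenvalues()].
#' @param mu constant prior mean; conventionally \code{max(energies) + 10}.
#' @param nugget diagonal jitter added on factorization failure.
#' @param prune one of \code{"age"} (drop oldest point and refit when the
#'   covariance matrix stays singular after the nugget) or \code{"error"}.
#' @return an object of class \code{"gek"}.
#' @seealso [predict.gek()], [variance_far_field()]
#' @export
gek <- function(coords, energies, grads, lengths, mu,
                nugget = 1e-10, prune = c("age", "error")) {
  prune <- match.arg(prune)
  coords <- as.matrix(coords)
  grads <- as.matrix(grads)
  m <- nrow(coords)
  K <- ncol(coords)
  stopifnot(length(energies) == m, nrow(grads) == m, ncol(grads) == K,
            length(lengths) == K, m >= 1)
  if (any(lengths <= 0)) stop("gek: characteristic lengths must be positive")

  n_obs <- m * (K + 1)
  M <- matrix(0, n_obs, n_obs)
  gidx <- function(i) m + (i - 1L) * K + seq_len(K)  # gradient rows of point i
  for (i in seq_len(m)) {
    for (j in i:m) {
      kb <- kernel_block(coords[i, ], coords[j, ], lengths)
      M[i, j] <- kb$value
      M[i, gidx(j)] <- kb$grad_xp          # Cov(E_i, g_j)
      M[gidx(i), j] <- kb$grad_x           # Cov(g_i, E_j)
      M[gidx(i), gidx(j)] <- kb$cross_hessian
      if (j > i) {
        M[j, i] <- M[i, j]
        M[gidx(j), i] <- M[i, gidx(j)]
        M[j, gidx(i)] <- M[gidx(i), j]
        M[gidx(j), gidx(i)] <- t(kb$cross_hessian)
      }
    }
  }
  y <- c(energies, as.vector(t(grads)))
  ones_mask <- c(rep(1, m), rep(0, m * K))
  yc <- y - ones_mask * mu

  fac <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(fac)) {
    fac <- tryCatch(chol(M + diag(nugget, n_obs)), error = function(e) NULL)
  }
  if (is.null(fac)) {
    if (prune == "age" && m > 1) {
      return(gek(coords[-1, , drop = FALSE], energies[-1],
                 grads[-1, , drop = FALSE], lengths, mu,
                 nugget = nugget, prune = prune))
    }
    stop("gek: covariance matrix is singular; prune the training history")
  }
  alpha <- backsolve(fac, forwardsolve(t(fac), yc))
  structure(list(coords = coords, energies = energies, grads = grads,
                 lengths = lengths, mu = mu, M = M, y = y,
                 ones_mask = ones_mask, chol = fac, alpha = alpha,
                 sigma2 = sum(yc * alpha) / m, m = m, K = K),
            class = "gek")
}

## covariance vector of a prediction point with all observations, plus its
## first and second derivatives with respect to the prediction point.
## Returns matrices V (n_obs), dV (n_obs x K), d2V (n_obs x K x K).
.gek_v <- function(object, x, order = 2L) {
  m <- object$m; K <- object$K; l <- object$lengths
  n_obs <- m * (K + 1)
  V <- numeric(n_obs)
  dV <- if (order >= 1L) matrix(0, n_obs, K) else NULL
  d2V <- if (order >= 2L) array(0, c(n_obs, K, K)) else NULL
  for (i in seq_len(m)) {
    xi <- object$coords[i, ]
    tau <- (x - xi) / l
    d <- sqrt(sum(tau^2))
    F1 <- .m52_F1(d); F2 <- .m52_F2(d); G3 <- .m52_G3(d)
    rows_g <- m + (i - 1L) * K + seq_len(K)
    V[i] <- matern52(d)
    V[rows_g] <- -2 * F1 * tau / l         # d f(x, x_i) / d x_i  (grad_xp)
    if (order >= 1L) {
      dV[i, ] <- 2 * F1 * tau / l          # d f / d x
      ## d^2 f / dx_p dx'_k = -4 F2 tau_p tau_k/(l_p l_k) - 2 F1 delta/l^2
      dV[rows_g, ] <- t(-4 * F2 * tcrossprod(tau / l) -
                          diag(2 * F1 / l^2, nrow = K))
    }
    if (order >= 2L) {
      tl <- tau / l
      ## own Hessian of f wrt x: 4 F2 tau_p tau_q/(l_p l_q) + 2 F1 delta/l^2
      d2V[i, , ] <- 4 * F2 * tcrossprod(tl) + diag(2 * F1 / l^2, nrow = K)
      ## third derivative d^3 f / dx_p dx_q dx'_k:
      ##   -8 F''' tau_p tau_q tau_k/(l_p l_q l_k)
      ##   -4 F2 (d_pq tau_k + d_pk tau_q + d_qk tau_p)/(l_p l_q l_k)
      ## with F''' tau_p = G3 * (tau_p / d) (limit 0 at coincidence)
      tld <- if (d > 0) tl / d else tl * 0
      for (k in seq_len(K)) {
        ek <- as.numeric(seq_len(K) == k) / l[k]^2
        Tpq <- -8 * G3 * tld[k] * tcrossprod(tl) -
          4 * F2 * (diag(tl[k] / l^2, nrow = K) +
                      outer(ek, tl) + outer(tl, ek))
        d2V[rows_g[k], , ] <- Tpq
      }
    }
  }
  list(V = V, dV = dV, d2V = d2V)
}

#' Predict from a GEK surrogate
#'
#' Evaluates the surrogate energy, gradient, Hessian and predicted variance
#' at a point of the reduced space.  The surrogate interpolates: at every
#' training coordinate the energy and gradient are reproduced exactly and
#' the variance is zero; far from all data the energy tends to the prior
#' mean \code{mu} with vanishing gradient.
#'
#' @param object a [gek()] model.
#' @param x numeric vector of length K (a single point).
#' @param order 0 = energy and variance only, 1 = + gradient, 2 = + Hessian.
#' @param ... unused.
#' @return list with \code{energy}, \code{gradient}, \code{hessian},
#'   \code{variance} (entries \code{NULL} when not requested).
#' @export
predict.gek <- function(object, x, order = 2L, ...) {
  stopifnot(length(x) == object$K)
  vv <- .gek_v(object, x, order = order)
  a <- object$alpha
  energy <- object$mu + sum(vv$V * a)
  gradient <- if (order >= 1L) as.numeric(crossprod(vv$dV, a)) else NULL
  hessian <- NULL
  if (order >= 2L) {
    hessian <- apply(vv$d2V, c(2, 3), function(col) sum(col * a))
    hessian <- (hessian + t(hessian)) / 2
  }
  Minv_v <- backsolve(object$chol, forwardsolve(t(object$chol), vv$V))
  variance <- object$sigma2 * (1 - sum(vv$V * Minv_v))
  if (variance < 0) variance <- if (variance > -1e-10) 0 else variance
  list(energy = energy, gradient = gradient, hessian = hessian,
       variance = max(variance, 0))
}

#' Far-field variance of a GEK surrogate
#'
#' Limit of the predicted variance as the covariance with all data
#' vanishes: \code{(y - 1 mu)^T M^{-1} (y - 1 mu) / m}.
#'
#' @param object a [gek()] model.
#' @return a nonnegative number.
#' @export
variance_far_field <- function(object) object$sigma2

#' @export
print.gek <- function(x, ...) {
  cat(sprintf("GEK surrogate: %d point(s), %d dimension(s)\n", x$m, x$K))
  cat(sprintf("  prior mean mu = %.6f, far-field variance = %.3e\n",
              x$mu, x$sigma2))
  cat(sprintf("  characteristic lengths: %s\n",
              paste(signif(x$lengths, 4), collapse = " ")))
  invisible(x)
}
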