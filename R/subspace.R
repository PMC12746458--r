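#' Reduced-subspace construction
#'
#' The optimizer compresses the full orbital-rotation space (dimension
#' n = n_occ x n_vir) to at most 2m + 2 directions spanned by the m stored
#' displacements and gradients, the current gradient and one cheap
#' expansion direction (r-GDIIS or BFGS prediction).  The diagonal guess
#' Hessian is projected onto this span and diagonalized; its eigenvectors
#' define the reduced coordinates and its eigenvalues set the kernel's
#' characteristic lengths.
#'
#' @name subspace
#' @keywords internal
NULL

#' Candidate vectors spanning the subspace
#'
#' Returns, in a fixed order that determines which near-dependent vectors
#' are later dropped: the m displacements \code{x_i - x_current} (oldest
#' first), the m stored gradients, the current gradient, and optionally the
#' expansion direction — at most 2m + 2 vectors.
#'
#' @param history list of records, each with elements \code{x} and \code{g}
#'   (full-space numeric vectors, oldest first).
#' @param g_current current full-space gradient.
#' @param x_current current full-space coordinates (default zero vector:
#'   the current point is the reference).
#' @param expansion optional full-space expansion direction.
#' @return list of full-space vectors.
#' @export
collect_vectors <- function(history, g_current, x_current = NULL,
                            expansion = NULL) {
  if (is.null(x_current)) x_current <- numeric(length(g_current))
  out <- c(lapply(history, function(r) r$x - x_current),
           lapply(history, function(r) r$g),
           list(g_current))
  if (!is.null(expansion)) out <- c(out, list(expansion))
  out
}

#' Modified Gram-Schmidt orthonormalization with dropping
#'
#' Orthonormalizes a list of vectors with one re-orthogonalization pass;
#' vectors whose residual norm after projection on the previous columns
#' falls below \code{tol} times their original norm are dropped (as are
#' zero vectors).
#'
#' @param vectors list of numeric vectors of common length n.
#' @param tol relative drop tolerance.
#' @return n x K matrix with orthonormal columns, K <= length(vectors).
#' @export
orthonormalize <- function(vectors, tol = 1e-8) {
  stopifnot(length(vectors) >= 1)
  n <- length(vectors[[1]])
  cols <- list()
  for (v in vectors) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    w <- v
    for (pass in 1:2) {
      for (b in cols) w <- w - sum(b * w) * b
    }
    if (sqrt(sum(w^2)) >= tol * nv) cols[[length(cols) + 1L]] <- w / sqrt(sum(w^2))
  }
  if (length(cols) == 0)
    stop("orthonormalize: all vectors below tolerance")
  matrix(unlist(cols), nrow = n)
}

#' Project the diagonal guess Hessian and define the reduced basis
#'
#' Forms \code{H^r = B^T diag(h) B}, diagonalizes it, and combines the
#' eigenvectors with B into the projection map \code{P_hat = B R} whose
#' columns are the Hessian-eigenvector basis of the subspace expressed in
#' the full space.  Optionally the Hessian is first softened along a unit
#' direction \code{q} by a loosening factor \code{f_L} (curvature along q
#' divided by \code{f_L^2}), which lengthens the corresponding
#' characteristic length; see [scale_hessian()].
#'
#' @param B n x K matrix with orthonormal columns (from [orthonormalize()]).
#' @param h_diag positive full-space diagonal Hessian entries.
#' @param f_L loosening factor (>= 1); 1 disables the scaling.
#' @param q_dir unit full-space direction of the previous step (required
#'   when \code{f_L > 1}).
#' @return object of class \code{"subspace_basis"}: list with \code{B},
#'   \code{P_hat} (n x K), and ascending eigenvalues \code{eps}.
#' @export
project_hessian <- function(B, h_diag, f_L = 1, q_dir = NULL) {
  K <- ncol(B)
  W_B <- B
  if (f_L != 1) {
    stopifnot(!is.null(q_dir))
    ## W = I + (1/f_L - 1) q q^T applied to each basis column
    W_B <- B + (1 / f_L - 1) * outer(q_dir, as.numeric(crossprod(q_dir, B)))
  }
  Hr <- crossprod(W_B, h_diag * W_B)
  Hr <- (Hr + t(Hr)) / 2
  ed <- eigen(Hr, symmetric = TRUE)
  ord <- order(ed$values)
  R <- ed$vectors[, ord, drop = FALSE]
  structure(list(B = B, P_hat = B %*% R, eps = ed$values[ord]),
            class = "subspace_basis")
}

#' Project a full-space vector to reduced coordinates
#'
#' \code{x^r = P_hat^T x^f}.  Both coordinates and gradients transform
#' this way because the columns of \code{P_hat} are orthonormal.
#'
#' @param P_hat n x K projection map (or a \code{"subspace_basis"}).
#' @param v_full full-space numeric vector.
#' @return length-K reduced vector.
#' @export
project_point <- function(P_hat, v_full) {
  if (inherits(P_hat, "subspace_basis")) P_hat <- P_hat$P_hat
  as.numeric(crossprod(P_hat, v_full))
}

#' Back-transform a reduced step to the full space
#'
#' \code{dx^f = P_hat dx^r}, the adjoint of [project_point()].
#'
#' @inheritParams project_point
#' @param dx_reduced length-K reduced displacement.
#' @return full-space numeric vector in the span of \code{P_hat}.
#' @export
back_transform <- function(P_hat, dx_reduced) {
  if (inherits(P_hat, "subspace_basis")) P_hat <- P_hat$P_hat
  as.numeric(P_hat %*% dx_reduced)
}

## solve the GDIIS least-squares system over error vectors e_i with the
## constraint sum(c) = 1; returns NULL when singular or ill-conditioned
.diis_coefficients <- function(E, c_max = 15) {
  m <- ncol(E)
  G <- crossprod(E)
  A <- rbind(cbind(G, 1), c(rep(1, m), 0))
  sol <- tryCatch(solve(A, c(rep(0, m), 1)), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  cf <- sol[seq_len(m)]
  if (any(!is.finite(cf)) || max(abs(cf)) > c_max) return(NULL)
  cf
}

#' r-GDIIS-like expansion direction
#'
#' Unit direction of the displacement predicted by a GDIIS extrapolation
#' over the stored (coordinate, gradient) pairs, using quasi-Newton error
#' vectors \code{e_i = -diag(h)^{-1} g_i}.  The prediction is
#' \code{sum_i c_i (x_i + e_i) - x_current} with \code{sum c_i = 1};
#' coefficients exceeding 15 in magnitude, or a singular system, trigger
#' the fallback \code{-diag(h)^{-1} g} of the newest record.  Only the
#' direction is meaningful — the subspace consumes unit vectors.
#'
#' @param history list of records with \code{x}, \code{g} (oldest first);
#'   the newest record is taken as the current point.
#' @param h_diag positive diagonal guess Hessian.
#' @return unit-norm full-space direction.
#' @export
diis_direction <- function(history, h_diag) {
  stopifnot(length(history) >= 1)
  cur <- history[[length(history)]]
  fallback <- -cur$g / h_diag
  if (length(history) == 1) return(fallback / sqrt(sum(fallback^2)))
  n <- length(h_diag)
  E <- matrix(vapply(history, function(r) -r$g / h_diag, numeric(n)), nrow = n)
  cf <- .diis_coefficients(E)
  if (is.null(cf)) return(fallback / sqrt(sum(fallback^2)))
  X <- matrix(vapply(history, function(r) r$x, numeric(n)), nrow = n)
  dir <- as.numeric((X + E) %*% cf) - cur$x
  nd <- sqrt(sum(dir^2))
  if (!is.finite(nd) || nd < 1e-14) return(fallback / sqrt(sum(fallback^2)))
  dir / nd
}

#' BFGS quasi-Newton expansion direction
#'
#' Unit direction \code{-H^{-1} g} where H starts from \code{diag(h_diag)}
#' and is BFGS-updated over successive history pairs
#' \code{(s, y) = (x_{i+1} - x_i, g_{i+1} - g_i)}; updates violating the
#' curvature condition \code{s^T y > 1e-12 |s||y|} are skipped, so H stays
#' positive definite.
#'
#' @inheritParams diis_direction
#' @return unit-norm full-space direction.
#' @export
bfgs_direction <- function(history, h_diag) {
  stopifnot(length(history) >= 1)
  n <- length(h_diag)
  H <- diag(h_diag, n)
  if (length(history) >= 2) {
    for (i in seq_len(length(history) - 1L)) {
      s <- history[[i + 1L]]$x - history[[i]]$x
      y <- history[[i + 1L]]$g - history[[i]]$g
      sy <- sum(s * y)
      if (sy <= 1e-12 * sqrt(sum(s^2)) * sqrt(sum(y^2))) next
      Hs <- H %*% s
      H <- H + tcrossprod(y) / sy - tcrossprod(Hs) / as.numeric(crossprod(s, Hs))
    }
  }
  g <- history[[length(history)]]$g
  dir <- -solve(H, g)
  dir / sqrt(sum(dir^2))
}
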