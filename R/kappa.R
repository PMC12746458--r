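#' Orbital-rotation algebra
#'
#' Points on the SCF orbital manifold are parametrized as
#' \code{C' = C exp(kappa)} with \code{kappa} the blocked antisymmetric
#' generator \code{[[0, X], [-X^T, 0]]}; the occupied-virtual block X (an
#' n_occ x n_vir matrix) holds the nonredundant rotation parameters.  When
#' the reference orbitals C change along the optimization, coordinates are
#' re-expressed through an SVD retraction and gradients are parallel
#' transported by a nested-commutator series or an equivalent closed sinc
#' formula.
#'
#' Flattening between X blocks and coordinate vectors is row-major over
#' the occupied index (all virtuals of occupied 1, then occupied 2, ...).
#'
#' @name kappa-algebra
#' @keywords internal
NULL

#' @rdname kappa-algebra
#' @param X n_occ x n_vir rotation block.
#' @export
flatten_block <- function(X) as.vector(t(X))

#' @rdname kappa-algebra
#' @param v flattened coordinate vector of length n_occ * n_vir.
#' @param n_occ,n_vir block dimensions.
#' @export
unflatten_block <- function(v, n_occ, n_vir) t(matrix(v, n_vir, n_occ))

#' Exponential of a blocked antisymmetric generator
#'
#' Closed form via the SVD \code{X = U S V^T}:
#' \deqn{\exp\kappa = \begin{pmatrix} I + U(\cos S - I)U^T & U \sin S V^T \\
#'   -V \sin S U^T & I + V(\cos S - I)V^T \end{pmatrix}}
#' The result is orthogonal for any X.
#'
#' @param X n_occ x n_vir rotation block.
#' @return orthogonal (n_occ + n_vir) x (n_occ + n_vir) matrix.
#' @export
expm_blocked <- function(X) {
  X <- as.matrix(X)
  no <- nrow(X); nv <- ncol(X)
  sv <- svd(X)
  U <- sv$u; V <- sv$v; s <- sv$d
  cs <- cos(s); sn <- sin(s)
  Q <- diag(1, no + nv)
  io <- seq_len(no); iv <- no + seq_len(nv)
  Q[io, io] <- diag(1, no) + U %*% ((cs - 1) * t(U))
  Q[io, iv] <- U %*% (sn * t(V))
  Q[iv, io] <- -V %*% (sn * t(U))
  Q[iv, iv] <- diag(1, nv) + V %*% ((cs - 1) * t(V))
  Q
}

#' Rotate molecular orbitals
#'
#' \code{C' = C exp(kappa)}; preserves S-orthonormality.
#'
#' @param C AO x MO coefficient matrix, S-orthonormal.
#' @param S AO overlap matrix.
#' @param X rotation block; \code{nrow(X) + ncol(X)} must equal
#'   \code{ncol(C)} with the occupied columns first.
#' @return rotated coefficient matrix.
#' @export
rotate_orbitals <- function(C, S, X) {
  stopifnot(nrow(X) + ncol(X) == ncol(C))
  ortho <- crossprod(C, S %*% C)
  if (max(abs(ortho - diag(1, ncol(C)))) > 1e-8)
    stop("rotate_orbitals: input orbitals are not S-orthonormal")
  C %*% expm_blocked(X)
}

#' Inverse scaled cosine
#'
#' \code{scos(x) = acos(x) / sqrt(1 - x^2)}, continuous with
#' \code{scos(1) = 1}; evaluated as \code{theta / sin(theta)} with a series
#' near the removable singularity at x = 1.
#'
#' @param x numeric in (-1, 1] (vectorized); values within 1e-12 above 1
#'   are clamped.
#' @return numeric of the same length.
#' @export
scos <- function(x) {
  if (any(x > 1 + 1e-12) || any(x <= -1))
    stop("scos: argument outside (-1, 1]")
  x <- pmin(x, 1)
  th <- acos(x)
  out <- ifelse(th < 1e-4,
                1 + th^2 / 6 + 7 * th^4 / 360,
                th / sin(pmax(th, .Machine$double.xmin)))
  out
}

#' Rebase rotation coordinates onto a new reference
#'
#' Given a point at coordinates X in the frame of reference orbitals C and
#' an accepted step dX (so the new reference is \code{C exp(dkappa)}),
#' finds the blocked coordinates X_tilde of the same point in the new
#' frame, together with the redundant occupied and virtual rotations
#' relating the retracted orbitals to the original ones:
#' \code{C_new exp(kappa_tilde) = C exp(kappa) U} with
#' \code{U = blockdiag(U_occ, U_vir)}.  Built from the SVD of the
#' occupied-occupied block of \code{exp(-dkappa) exp(kappa)}.
#'
#' @param X,dX n_occ x n_vir rotation blocks (same shape).
#' @param sv_tol smallest admissible singular value of the
#'   occupied-occupied block; below it the rotation is too large to rebase
#'   (a 90-degree occupied-space rotation) and an error is thrown so the
#'   caller can restart its history.
#' @return list with \code{X_tilde}, \code{U_occ}, \code{U_vir}.
#' @export
rebase_coordinates <- function(X, dX, sv_tol = 1e-8) {
  X <- as.matrix(X); dX <- as.matrix(dX)
  stopifnot(all(dim(X) == dim(dX)))
  no <- nrow(X); nv <- ncol(X)
  io <- seq_len(no); iv <- no + seq_len(nv)
  Kmat <- expm_blocked(-dX) %*% expm_blocked(X)
  Koo <- Kmat[io, io, drop = FALSE]
  Kvo <- Kmat[iv, io, drop = FALSE]
  Kov <- Kmat[io, iv, drop = FALSE]
  Kvv <- Kmat[iv, iv, drop = FALSE]
  sv <- svd(Koo)
  if (min(sv$d) < sv_tol)
    stop("rebase_coordinates: vanishing singular value; rotation too large to rebase")
  V <- sv$u; W <- sv$v
  X_tilde <- -V %*% (scos(sv$d) * t(W)) %*% t(Kvo)
  ## oriented so that exp(dkappa) exp(kappa_tilde) = exp(kappa) blockdiag(U)
  U_occ <- W %*% t(V)
  U_vir <- t(Kvv - Kvo %*% W %*% ((1 / (sv$d + 1)) * t(V)) %*% Kov)
  list(X_tilde = X_tilde, U_occ = U_occ, U_vir = U_vir)
}

#' Gradient parallel transport: commutator series
#'
#' Transports the nonredundant gradient block of a data point into a new
#' reference frame.  With \code{T_0 = U_occ^T L U_vir} and
#' \code{P = X X^T}, the series
#' \deqn{\tilde L = \sum_k T_k / (2k+1)!, \quad
#'   T_k = (2 X T_{k-1}^T - T_{k-1} X^T) X - P T_{k-1}}
#' sums the occupied-virtual block of the nested-commutator expansion of
#' the frame change; X is the blocked coordinate of the data point in the
#' new frame (the series is even in X, so its sign is immaterial).
#' Terms are added until \code{max|T_k|/(2k+1)!} falls below machine
#' precision relative to the leading term.
#'
#' @param L n_occ x n_vir gradient block at the point's own reference.
#' @param X n_occ x n_vir rotation block of the frame change.
#' @param U_occ,U_vir accumulated redundant rotations (identity if NULL).
#' @param max_terms series guard; exceeding it signals a rotation too
#'   large for the expansion.
#' @return transported n_occ x n_vir gradient block.
#' @export
transport_gradient_series <- function(L, X, U_occ = NULL, U_vir = NULL,
                                      max_terms = 40L) {
  L <- as.matrix(L); X <- as.matrix(X)
  T_k <- L
  if (!is.null(U_occ)) T_k <- crossprod(U_occ, T_k)
  if (!is.null(U_vir)) T_k <- T_k %*% U_vir
  P <- tcrossprod(X)
  out <- T_k                      # k = 0 term, 1! = 1
  scale_ref <- max(abs(T_k), 1e-300)
  for (k in seq_len(max_terms)) {
    T_k <- (2 * X %*% t(T_k) - T_k %*% t(X)) %*% X - P %*% T_k
    term <- T_k / factorial(2 * k + 1)
    out <- out + term
    if (max(abs(term)) < .Machine$double.eps * scale_ref) return(out)
  }
  stop("transport_gradient_series: no convergence; rotation too large")
}

#' Gradient parallel transport: closed sinc formula
#'
#' Noniterative equivalent of [transport_gradient_series()] built from the
#' SVD \code{X = R Gamma Q^T} (convention \code{n_vir >= n_occ}):
#' \deqn{\tilde L = R[(Z + Z^T) \odot D^- + (Z - Z^T) \odot D^+] Q^T +
#'   (R\,\mathrm{sinc}\Gamma\,R^T)\, T_0 (I - QQ^T)}
#' with \code{Z = R^T T_0 Q} and
#' \code{D^±_ij = sinc(gamma_i ± gamma_j)/2}.  The sinc form is free of
#' divisions, so repeated singular values are harmless.
#'
#' The \code{n_occ > n_vir} case is reduced to the tall one through the
#' block-swap symmetry of the antisymmetric embedding
#' (\code{L~(L, X) = -t(L~(-t(L), t(X)))}).
#'
#' @inheritParams transport_gradient_series
#' @return transported n_occ x n_vir gradient block.
#' @export
transport_gradient_closed <- function(L, X, U_occ = NULL, U_vir = NULL) {
  L <- as.matrix(L); X <- as.matrix(X)
  T0 <- L
  if (!is.null(U_occ)) T0 <- crossprod(U_occ, T0)
  if (!is.null(U_vir)) T0 <- T0 %*% U_vir
  no <- nrow(X); nv <- ncol(X)
  if (no > nv)
    return(-t(transport_gradient_closed(-t(T0), t(X))))
  sv <- svd(X)                    # R: no x no, Q: nv x no, full row rank
  R <- sv$u; Q <- sv$v; g <- sv$d
  sinc <- function(t) ifelse(abs(t) < 1e-6, 1 - t^2 / 6, sin(t) / t)
  Z <- crossprod(R, T0 %*% Q)
  Dm <- outer(g, g, function(a, b) sinc(a - b)) / 2
  Dp <- outer(g, g, function(a, b) sinc(a + b)) / 2
  core <- (Z + t(Z)) * Dm + (Z - t(Z)) * Dp
  R %*% core %*% t(Q) +
    (R %*% (sinc(g) * t(R))) %*% T0 %*% (diag(1, nv) - tcrossprod(Q))
}

#' Nested-commutator transport oracle
#'
#' Brute-force truncated sum \code{sum_k ad_nu^k G / (k+1)!} over full
#' antisymmetric matrices; used as an independent check of the blocked
#' transport formulas.
#'
#' @param G_full,nu_full square antisymmetric matrices of the same size.
#' @param terms truncation order (number of commutator nestings).
#' @return square matrix of the same size.
#' @export
commutator_series_oracle <- function(G_full, nu_full, terms = 30L) {
  acc <- G_full
  term <- G_full
  for (k in seq_len(terms)) {
    term <- nu_full %*% term - term %*% nu_full
    acc <- acc + term / factorial(k + 1)
  }
  acc
}

#' Occupied-space overlap of two orbital sets
#'
#' Product of the singular values of \code{C1^T S C2} over the occupied
#' blocks: 1 iff the two sets span the same occupied space, 0 if any
#' dimension of one is S-orthogonal to the other.
#'
#' @param C1,C2 AO x n_occ matrices of occupied orbital coefficients
#'   (each S-orthonormal).
#' @param S AO overlap matrix.
#' @return a number in [0, 1] (tiny negative rounding clamped).
#' @export
occupied_space_overlap <- function(C1, C2, S) {
  stopifnot(ncol(C1) == ncol(C2))
  d <- svd(crossprod(C1, S %*% C2))$d
  min(max(prod(d), 0), 1)
}
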