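#' Objective backends
#'
#' The optimizer consumes objectives through a small S3 contract: report
#' the dimension, energy and gradient at the current reference, apply a
#' full-space displacement (moving the reference), and expose what the
#' convergence test needs.  Two families are provided: the toy
#' Hartree-Fock engine (orbital rotations, Fock-derived gradients) and
#' analytic surfaces (plain vector addition).
#'
#' @name backends
#' @keywords internal
NULL

#' @rdname backends
#' @param backend a backend object.
#' @export
backend_dim <- function(backend) UseMethod("backend_dim")
#' @rdname backends
#' @export
backend_energy <- function(backend) UseMethod("backend_energy")
#' @rdname backends
#' @export
backend_gradient <- function(backend) UseMethod("backend_gradient")
#' @rdname backends
#' @param dx_full full-space displacement vector.
#' @export
backend_step <- function(backend, dx_full) UseMethod("backend_step")
#' @rdname backends
#' @param floor lower bound applied to the curvature guess.
#' @export
backend_guess_hessian <- function(backend, floor = 0.025)
  UseMethod("backend_guess_hessian")
#' @rdname backends
#' @export
backend_grad_metric <- function(backend) UseMethod("backend_grad_metric")
#' @rdname backends
#' @export
backend_block_dims <- function(backend) UseMethod("backend_block_dims")
#' @rdname backends
#' @export
backend_occupied <- function(backend) UseMethod("backend_occupied")

## ---------------------------------------------------------------- HF ----

#' Hartree-Fock objective backend
#'
#' Wraps an [build_toy_system()] result as an optimizer backend.  The
#' coordinates are the flattened occupied-virtual rotation blocks (alpha
#' block then beta block for UHF); the gradient at the reference is
#' \code{-4 F_ov} (RHF) or \code{-2 F_ov} per spin (UHF), both pinned
#' against finite differences in the test suite.
#'
#' @param sys an \code{"hf_system"}.
#' @param C starting orbitals (default: core guess).
#' @return an object of classes \code{"hf_backend"}, \code{"scf_backend"}.
#' @export
hf_backend <- function(sys, C = NULL) {
  if (is.null(C)) {
    C <- if (sys$restricted) sys$C_guess else list(a = sys$C_guess, b = sys$C_guess)
  }
  ef <- energy_and_fock(sys, C)
  structure(list(sys = sys, C = C, energy = ef$energy, F_mo = ef$F_mo),
            class = c("hf_backend", "scf_backend"))
}

#' @export
backend_block_dims.hf_backend <- function(backend) {
  sys <- backend$sys
  if (sys$restricted) {
    list(list(n_occ = sys$n_alpha, n_vir = sys$nbf - sys$n_alpha))
  } else {
    list(list(n_occ = sys$n_alpha, n_vir = sys$nbf - sys$n_alpha),
         list(n_occ = sys$n_beta, n_vir = sys$nbf - sys$n_beta))
  }
}

#' @export
backend_dim.hf_backend <- function(backend)
  sum(vapply(backend_block_dims(backend), function(b) b$n_occ * b$n_vir, 0))

#' @export
backend_energy.hf_backend <- function(backend) backend$energy

## split a full coordinate vector into per-spin rotation blocks
.hf_blocks <- function(backend, v) {
  dims <- backend_block_dims(backend)
  out <- list(); off <- 0L
  for (b in dims) {
    nb <- b$n_occ * b$n_vir
    out[[length(out) + 1L]] <- unflatten_block(v[off + seq_len(nb)], b$n_occ, b$n_vir)
    off <- off + nb
  }
  out
}

#' @export
backend_gradient.hf_backend <- function(backend) {
  sys <- backend$sys
  if (sys$restricted) {
    no <- sys$n_alpha
    L <- -4 * backend$F_mo[seq_len(no), (no + 1):sys$nbf, drop = FALSE]
    flatten_block(L)
  } else {
    g <- numeric(0)
    for (spin in c("a", "b")) {
      no <- if (spin == "a") sys$n_alpha else sys$n_beta
      F_mo <- backend$F_mo[[spin]]
      if (no == 0 || no == sys$nbf) next
      L <- -2 * F_mo[seq_len(no), (no + 1):sys$nbf, drop = FALSE]
      g <- c(g, flatten_block(L))
    }
    g
  }
}

#' @export
backend_step.hf_backend <- function(backend, dx_full) {
  sys <- backend$sys
  blocks <- .hf_blocks(backend, dx_full)
  C <- backend$C
  if (sys$restricted) {
    C <- rotate_orbitals(C, sys$S, blocks[[1]])
  } else {
    C$a <- rotate_orbitals(C$a, sys$S, blocks[[1]])
    if (length(blocks) > 1) C$b <- rotate_orbitals(C$b, sys$S, blocks[[2]])
  }
  hf_backend(sys, C)
}

#' @export
backend_guess_hessian.hf_backend <- function(backend, floor = 0.025) {
  sys <- backend$sys
  h <- numeric(0)
  dims <- backend_block_dims(backend)
  fmos <- if (sys$restricted) list(backend$F_mo) else backend$F_mo[c("a", "b")]
  scale <- if (sys$restricted) 4 else 2
  for (k in seq_along(dims)) {
    b <- dims[[k]]
    if (b$n_occ == 0 || b$n_vir == 0) next
    eps <- diag(as.matrix(fmos[[k]]))
    gap <- outer(eps[seq_len(b$n_occ)],
                 eps[b$n_occ + seq_len(b$n_vir)],
                 function(ei, ea) scale * (ea - ei))
    h <- c(h, flatten_block(gap))
  }
  pmax(h, floor)
}

#' @export
backend_grad_metric.hf_backend <- function(backend) {
  sys <- backend$sys
  fmax <- function(F_mo, no) {
    if (no == 0 || no == sys$nbf) return(0)
    max(abs(F_mo[seq_len(no), (no + 1):sys$nbf]))
  }
  if (sys$restricted) fmax(backend$F_mo, sys$n_alpha)
  else max(fmax(backend$F_mo$a, sys$n_alpha), fmax(backend$F_mo$b, sys$n_beta))
}

#' @export
backend_occupied.hf_backend <- function(backend) {
  sys <- backend$sys
  if (sys$restricted) {
    list(backend$C[, seq_len(sys$n_alpha), drop = FALSE])
  } else {
    out <- list(backend$C$a[, seq_len(sys$n_alpha), drop = FALSE])
    if (sys$n_beta > 0)
      out <- c(out, list(backend$C$b[, seq_len(sys$n_beta), drop = FALSE]))
    out
  }
}

## ---------------------------------------------------------- analytic ----

#' Analytic test surfaces
#'
#' Objective backends with closed-form energies on plain vector
#' coordinates.  Available surfaces:
#' \describe{
#'   \item{quadratic}{\code{E = 0.5 (x-c)^T A (x-c)}; params \code{A}
#'     (SPD matrix) and \code{center}.}
#'   \item{slope}{1-D straight slope with a distant harmonic floor:
#'     \code{E = -s x + 0.5 c max(0, x - x_f)^2}; params \code{slope},
#'     \code{floor_at}, \code{curvature}.  The flat sloped region
#'     reproduces the systematic-undershoot scenario.}
#'   \item{valley}{anisotropic quadratic valley with one soft mode:
#'     \code{E = 0.5 (soft x_1^2 + sum_{k>1} x_k^2)}; params \code{n},
#'     \code{soft}.}
#'   \item{rosenbrock}{2-D Rosenbrock function (nonconvex check).}
#' }
#'
#' @param name surface name.
#' @param params named list of surface parameters (see above).
#' @param x0 starting coordinates.
#' @return an object of classes \code{"analytic_backend"},
#'   \code{"scf_backend"}.
#' @export
analytic_surface <- function(name, params = list(), x0 = NULL) {
  defs <- list(
    quadratic = function(p) {
      A <- p$A; ctr <- p$center
      list(n = nrow(A),
           fn = function(x) 0.5 * sum((x - ctr) * (A %*% (x - ctr))),
           gr = function(x) as.numeric(A %*% (x - ctr)),
           curv = diag(A))
    },
    slope = function(p) {
      s <- p$slope %||% 0.1; xf <- p$floor_at %||% 10; cc <- p$curvature %||% 1
      list(n = 1L,
           fn = function(x) -s * x[1] + 0.5 * cc * max(0, x[1] - xf)^2,
           gr = function(x) -s + cc * max(0, x[1] - xf),
           curv = 1)
    },
    valley = function(p) {
      n <- p$n %||% 2L; soft <- p$soft %||% 1e-3
      w <- c(soft, rep(1, n - 1))
      list(n = n, fn = function(x) 0.5 * sum(w * x^2),
           gr = function(x) w * x, curv = w)
    },
    rosenbrock = function(p) {
      list(n = 2L,
           fn = function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2,
           gr = function(x) c(-2 * (1 - x[1]) - 400 * x[1] * (x[2] - x[1]^2),
                              200 * (x[2] - x[1]^2)),
           curv = c(2, 200))
    })
  if (!name %in% names(defs)) stop("analytic_surface: unknown surface: ", name)
  def <- defs[[name]](params)
  if (is.null(x0)) x0 <- numeric(def$n)
  stopifnot(length(x0) == def$n)
  structure(list(name = name, def = def, x = as.numeric(x0)),
            class = c("analytic_backend", "scf_backend"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
backend_dim.analytic_backend <- function(backend) backend$def$n
#' @export
backend_energy.analytic_backend <- function(backend) backend$def$fn(backend$x)
#' @export
backend_gradient.analytic_backend <- function(backend) backend$def$gr(backend$x)
#' @export
backend_step.analytic_backend <- function(backend, dx_full) {
  backend$x <- backend$x + dx_full
  backend
}
#' @export
backend_guess_hessian.analytic_backend <- function(backend, floor = 0.025) {
  pmax(rep_len(backend$def$curv, backend$def$n), floor)
}
#' @export
backend_grad_metric.analytic_backend <- function(backend)
  max(abs(backend_gradient(backend)))
#' @export
backend_block_dims.analytic_backend <- function(backend) NULL
#' @export
backend_occupied.analytic_backend <- function(backend) NULL
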