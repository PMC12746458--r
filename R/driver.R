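#' Optimizer control parameters
#'
#' Collects tunables for [scf_optimize()].  Defaults follow the method's
#' stated constants: at most 20 history points, prior mean 10 hartree
#' above the best data energy, golden-ratio loosening with the 5/20 degree
#' angle windows, and the standard SCF convergence triple (energy change
#' below 1e-9 hartree, max occupied-virtual Fock element below 1.5e-4,
#' step norm below 1e-3, all strict).
#'
#' @param max_history maximum stored previous iterations.
#' @param expansion cheap subspace-expansion direction: \code{"diis"},
#'   \code{"bfgs"} or \code{"none"}.
#' @param variance_coefficient proportionality constant of the variance
#'   limit (limit = coefficient * reduced gradient norm).
#' @param mu_offset prior-mean offset above the maximum data energy
#'   (hartree).
#' @param loosen_factor multiplier applied to the loosening factor under
#'   near-parallel steps (golden ratio).
#' @param loosen_angle steps closer than this angle (degrees) trigger
#'   loosening.
#' @param tighten_angle steps further apart than this angle reset the
#'   loosening factor to 1.
#' @param e_tol,fock_tol,step_tol convergence thresholds (energy change,
#'   gradient metric, step norm).
#' @param max_iter iteration cap; exceeding it flags nonconvergence.
#' @param hessian_floor lower bound for guess-Hessian entries and
#'   projected eigenvalues fed to the characteristic lengths.
#' @param orth_tol relative drop tolerance of the orthonormalizer.
#' @param sd_cap norm cap of the first (steepest-descent) step.
#' @param mitigate enable the systematic-undershoot mitigation.
#' @param seed optional RNG seed recorded for reproducibility.
#' @return a list of class \code{"scf_control"}.
#' @export
scf_control <- function(max_history = 20L,
                        expansion = c("diis", "bfgs", "none"),
                        variance_coefficient = 0.3,
                        mu_offset = 10,
                        loosen_factor = (1 + sqrt(5)) / 2,
                        loosen_angle = 5,
                        tighten_angle = 20,
                        e_tol = 1e-9,
                        fock_tol = 1.5e-4,
                        step_tol = 1e-3,
                        max_iter = 400L,
                        hessian_floor = 0.025,
                        orth_tol = 1e-8,
                        sd_cap = 0.3,
                        mitigate = TRUE,
                        seed = NULL) {
  expansion <- match.arg(expansion)
  stopifnot(e_tol > 0, fock_tol > 0, step_tol > 0, loosen_angle < tighten_angle,
            variance_coefficient > 0, max_history >= 1, hessian_floor > 0)
  structure(as.list(environment()), class = "scf_control")
}

## ------------------------------------------------------------ history ----

## A history record keeps the data needed to express a past SCF iterate in
## the CURRENT reference frame:
##   x, g     flattened current-frame coordinate and transported gradient
##   energy   the point's energy (frame independent)
##   blocks   per-spin list(X, L0, U_occ, U_vir): current coordinate block,
##            pristine own-frame gradient block, accumulated redundant
##            rotations (see rebase_coordinates)
## Analytic backends carry blocks = NULL and rebase by translation.
.new_record <- function(backend) {
  g <- backend_gradient(backend)
  dims <- backend_block_dims(backend)
  blocks <- NULL
  if (!is.null(dims)) {
    blocks <- list(); off <- 0L
    for (b in dims) {
      nb <- b$n_occ * b$n_vir
      L0 <- unflatten_block(g[off + seq_len(nb)], b$n_occ, b$n_vir)
      blocks[[length(blocks) + 1L]] <-
        list(X = matrix(0, b$n_occ, b$n_vir), L0 = L0,
             U_occ = diag(1, b$n_occ), U_vir = diag(1, b$n_vir))
      off <- off + nb
    }
  }
  list(x = numeric(length(g)), g = g, energy = backend_energy(backend),
       blocks = blocks)
}

## Rebase one record after an accepted step dx (full-space vector).
## HF: per-spin SVD retraction of coordinates, accumulation of U factors,
## and one-shot gradient transport from the point's own frame.
.rebase_record <- function(record, dx_full, dims) {
  if (is.null(record$blocks)) {
    record$x <- record$x - dx_full
    return(record)
  }
  off <- 0L
  x <- numeric(0); g <- numeric(0)
  for (k in seq_along(dims)) {
    b <- dims[[k]]; nb <- b$n_occ * b$n_vir
    dX <- unflatten_block(dx_full[off + seq_len(nb)], b$n_occ, b$n_vir)
    blk <- record$blocks[[k]]
    rb <- rebase_coordinates(blk$X, dX)
    blk$X <- rb$X_tilde
    blk$U_occ <- blk$U_occ %*% rb$U_occ
    blk$U_vir <- blk$U_vir %*% rb$U_vir
    Lt <- transport_gradient_closed(blk$L0, blk$X, blk$U_occ, blk$U_vir)
    record$blocks[[k]] <- blk
    x <- c(x, flatten_block(blk$X)); g <- c(g, flatten_block(Lt))
    off <- off + nb
  }
  record$x <- x; record$g <- g
  record
}

## ------------------------------------------------------------- pieces ----

#' Variance limit of the restricted-variance step
#'
#' \code{variance_coefficient * ||g_reduced||}: steps on the surrogate are
#' truncated where the predicted variance reaches this bound, so step
#' length adapts to how well the model is trusted rather than to a fixed
#' radius.
#'
#' @param g_reduced reduced-space gradient at the current point.
#' @param control an [scf_control()].
#' @return nonnegative scalar.
#' @export
variance_limit <- function(g_reduced, control = scf_control()) {
  control$variance_coefficient * sqrt(sum(g_reduced^2))
}

#' RS-RFO microiterations on the surrogate under a variance wall
#'
#' Searches for a stationary point of the GEK surrogate by repeated
#' rational-function steps (lowest eigenpair of the gradient-augmented
#' Hessian, a level-shifted Newton step).  Whenever a trial point's
#' predicted variance exceeds \code{var_max}, the step is shortened by
#' bisection until the variance meets the wall (relative tolerance
#' \code{var_tol}) and the microiterations stop.
#'
#' @param model a [gek()] surrogate.
#' @param x0 starting reduced coordinates.
#' @param var_max maximum admissible predicted variance.
#' @param g_tol surrogate gradient norm declaring a stationary point.
#' @param max_micro,max_bisect iteration guards.
#' @param var_tol relative tolerance on meeting the variance wall.
#' @return list with \code{step} (reduced displacement) and \code{reason}
#'   (\code{"stationary"}, \code{"variance_truncated"} or
#'   \code{"max_micro"}).
#' @export
rsrfo_microiterations <- function(model, x0, var_max, g_tol = 1e-8,
                                  max_micro = 200L, max_bisect = 30L,
                                  var_tol = 1e-6) {
  if (var_max <= 0)
    return(list(step = numeric(length(x0)), reason = "variance_truncated"))
  z <- x0
  trust <- max(model$lengths)
  for (it in seq_len(max_micro)) {
    p <- predict(model, z, order = 2L)
    gn <- sqrt(sum(p$gradient^2))
    if (gn < g_tol) return(list(step = z - x0, reason = "stationary"))
    aug <- rbind(c(0, p$gradient), cbind(p$gradient, p$hessian))
    ev <- eigen((aug + t(aug)) / 2, symmetric = TRUE)
    v <- ev$vectors[, which.min(ev$values)]
    if (abs(v[1]) < 1e-12) {
      dz <- -p$gradient / gn * min(trust, gn)
    } else {
      dz <- v[-1] / v[1]
    }
    ndz <- sqrt(sum(dz^2))
    if (ndz > trust) dz <- dz * trust / ndz
    z_try <- z + dz
    vtry <- predict(model, z_try, order = 0L)$variance
    if (vtry > var_max) {
      lo <- 0; hi <- 1
      for (b in seq_len(max_bisect)) {
        mid <- (lo + hi) / 2
        vm <- predict(model, z + mid * dz, order = 0L)$variance
        if (vm > var_max) hi <- mid else lo <- mid
        if (abs(vm - var_max) <= var_tol * max(var_max, 1e-300)) {
          lo <- mid
          break
        }
      }
      return(list(step = z + lo * dz - x0, reason = "variance_truncated"))
    }
    z <- z_try
  }
  list(step = z - x0, reason = "max_micro")
}

#' Update the loosening factor from consecutive step directions
#'
#' Near-parallel successive steps (angle below \code{loosen_angle})
#' signal systematic undershooting on a flat sloped surface: the factor
#' is multiplied by \code{loosen_factor} (golden ratio), which softens
#' the guess curvature along the repeated direction in the next
#' surrogate.  Directions further apart than \code{tighten_angle} reset
#' it to 1; in between it is kept.
#'
#' @param f_L current loosening factor (>= 1).
#' @param prev_step,new_step full-space steps (NULL prev leaves f_L
#'   unchanged).
#' @param control an [scf_control()].
#' @return updated loosening factor.
#' @export
update_loosening <- function(f_L, prev_step, new_step,
                             control = scf_control()) {
  if (is.null(prev_step)) return(f_L)
  np <- sqrt(sum(prev_step^2)); nn <- sqrt(sum(new_step^2))
  if (np == 0 || nn == 0) return(f_L)
  cosang <- min(max(sum(prev_step * new_step) / (np * nn), -1), 1)
  ang <- acos(cosang) * 180 / pi
  if (ang < control$loosen_angle) f_L * control$loosen_factor
  else if (ang > control$tighten_angle) 1
  else f_L
}

## strict three-criterion convergence test
.converged <- function(d_energy, grad_metric, step_norm, control) {
  is.finite(d_energy) &&
    abs(d_energy) < control$e_tol &&
    grad_metric < control$fock_tol &&
    step_norm < control$step_tol
}

## first-iteration preconditioned steepest-descent step, norm-capped
.sd_step <- function(g, h, cap) {
  dx <- -g / h
  n <- sqrt(sum(dx^2))
  if (n > cap) dx <- dx * cap / n
  dx
}

## trace row constructor (keeps column set in one place)
.trace_row <- function(iter, energy, d_energy, g_max, step_norm, variance,
                       f_L, K, method) {
  data.frame(iter = iter, energy = energy, d_energy = d_energy,
             g_max = g_max, step_norm = step_norm, variance = variance,
             f_L = f_L, K = K, method = method)
}

## shared result wrapper
.make_fit <- function(method, backend, trace, control, converged, history) {
  structure(list(method = method, backend = backend, trace = trace,
                 control = control, converged = converged,
                 iterations = nrow(trace), energy = backend_energy(backend),
                 history = history),
            class = "scf_fit")
}

## ------------------------------------------------------- S-GEK driver ----

## One outer S-GEK/RVO iteration given current backend + state; returns the
## updated state.  Split out for testability.
.sgek_step <- function(state, control) {
  backend <- state$backend
  g <- backend_gradient(backend)
  h <- backend_guess_hessian(backend, floor = control$hessian_floor)
  record <- .new_record(backend)
  history <- state$history

  if (length(history) == 0) {
    dx <- .sd_step(g, h, control$sd_cap)
    K <- NA_integer_; var_used <- NA_real_
  } else {
    expansion <- switch(control$expansion,
                        diis = diis_direction(c(history, list(record)), h),
                        bfgs = bfgs_direction(c(history, list(record)), h),
                        none = NULL)
    vecs <- collect_vectors(history, g, expansion = expansion)
    B <- orthonormalize(vecs, tol = control$orth_tol)
    q_dir <- NULL; f_L <- if (control$mitigate) state$f_L else 1
    if (f_L != 1) {
      q_dir <- state$prev_step / sqrt(sum(state$prev_step^2))
    } else f_L <- 1
    basis <- project_hessian(B, h, f_L = f_L, q_dir = q_dir)
    eps <- pmax(basis$eps, 1e-12)
    energies <- c(vapply(history, `[[`, 0, "energy"), record$energy)
    e_max <- max(energies)
    mu <- e_max + control$mu_offset
    lengths <- lengths_from_eigenvalues(eps, mu, e_max)
    pts <- c(history, list(record))
    coords <- t(vapply(pts, function(r) project_point(basis, r$x),
                       numeric(ncol(basis$P_hat))))
    grads <- t(vapply(pts, function(r) project_point(basis, r$g),
                      numeric(ncol(basis$P_hat))))
    if (ncol(basis$P_hat) == 1) { coords <- t(coords); grads <- t(grads) }
    model <- gek(coords, energies, grads, lengths, mu)
    x0 <- coords[nrow(coords), ]
    var_used <- variance_limit(grads[nrow(grads), ], control)
    micro <- rsrfo_microiterations(model, x0, var_used)
    dx <- back_transform(basis, micro$step)
    K <- ncol(basis$P_hat)
  }

  new_backend <- backend_step(backend, dx)
  state$f_L <- if (control$mitigate)
    update_loosening(state$f_L, state$prev_step, dx, control)
  else 1

  ## rebase all records (including the just-created current point) into the
  ## new reference frame; on failure restart history from the new point
  dims <- backend_block_dims(backend)
  history <- tryCatch({
    lapply(c(history, list(record)), .rebase_record, dx_full = dx, dims = dims)
  }, error = function(e) NULL)
  if (is.null(history)) {
    history <- list()
    state$f_L <- 1
  }
  if (length(history) > control$max_history)
    history <- history[(length(history) - control$max_history + 1L):length(history)]

  state$history <- history
  state$prev_step <- dx
  state$iteration <- state$iteration + 1L
  state$last <- list(energy_prev = backend_energy(backend),
                     energy = backend_energy(new_backend),
                     g_max = backend_grad_metric(new_backend),
                     step_norm = sqrt(sum(dx^2)),
                     variance = var_used, K = K)
  state$backend <- new_backend
  state
}

## ------------------------------------------------------------ drivers ----

.run_optimizer <- function(backend, control, method, stepper) {
  if (!is.null(control$seed)) set.seed(control$seed)
  state <- list(backend = backend, history = list(), f_L = 1,
                prev_step = NULL, iteration = 0L)
  trace <- NULL
  converged <- FALSE
  for (i in seq_len(control$max_iter)) {
    state <- stepper(state, control)
    li <- state$last
    trace <- rbind(trace, .trace_row(i, li$energy, li$energy - li$energy_prev,
                                     li$g_max, li$step_norm, li$variance,
                                     state$f_L, li$K, method))
    if (.converged(li$energy - li$energy_prev, li$g_max, li$step_norm,
                   control)) {
      converged <- TRUE
      break
    }
  }
  .make_fit(method, state$backend, trace, control, converged, state$history)
}

#' r-GDIIS baseline optimizer step (internal)
#'
#' DIIS extrapolation over quasi-Newton-preconditioned gradients with a
#' reset when extrapolation coefficients blow up; shares the history,
#' rebase and convergence machinery of the surrogate driver.
#' @noRd
.rgdiis_step <- function(state, control) {
  backend <- state$backend
  g <- backend_gradient(backend)
  h <- backend_guess_hessian(backend, floor = control$hessian_floor)
  record <- .new_record(backend)
  history <- state$history

  if (length(history) == 0) {
    dx <- .sd_step(g, h, control$sd_cap)
  } else {
    pts <- c(history, list(record))
    n <- length(h)
    E <- matrix(vapply(pts, function(r) -r$g / h, numeric(n)), nrow = n)
    cf <- .diis_coefficients(E)
    if (is.null(cf)) {
      history <- list()             # resetting procedure
      dx <- .sd_step(g, h, control$sd_cap)
    } else {
      X <- matrix(vapply(pts, function(r) r$x, numeric(n)), nrow = n)
      dx <- as.numeric((X + E) %*% cf)
    }
  }

  new_backend <- backend_step(backend, dx)
  dims <- backend_block_dims(backend)
  history <- tryCatch({
    lapply(c(history, list(record)), .rebase_record, dx_full = dx, dims = dims)
  }, error = function(e) list())
  if (length(history) > control$max_history)
    history <- history[(length(history) - control$max_history + 1L):length(history)]

  state$history <- history
  state$prev_step <- dx
  state$iteration <- state$iteration + 1L
  state$last <- list(energy_prev = backend_energy(backend),
                     energy = backend_energy(new_backend),
                     g_max = backend_grad_metric(new_backend),
                     step_norm = sqrt(sum(dx^2)),
                     variance = NA_real_, K = NA_integer_)
  state$backend <- new_backend
  state
}

#' Optimize an SCF (or analytic) objective
#'
#' The package's fitting front-end.  \code{method} selects the surrogate
#' driver with r-GDIIS or BFGS subspace expansion, or the r-GDIIS baseline
#' itself.  Iterations stop when, simultaneously and strictly, the energy
#' change is below \code{e_tol}, the gradient metric (max occupied-virtual
#' Fock element, or max gradient component for analytic surfaces) is below
#' \code{fock_tol}, and the step norm is below \code{step_tol}; hitting
#' \code{max_iter} first yields \code{converged = FALSE}, not an error.
#'
#' @param backend an objective backend ([hf_backend()],
#'   [analytic_surface()]).
#' @param method \code{"sgek-diis"}, \code{"sgek-bfgs"} or
#'   \code{"rgdiis"}.
#' @param control an [scf_control()].
#' @return an object of class \code{"scf_fit"}: final backend, per
#'   iteration trace (iter, energy, d_energy, g_max, step_norm, variance,
#'   f_L, K, method), convergence flag.
#' @examples
#' surf <- analytic_surface("quadratic",
#'                          list(A = diag(c(1, 4)), center = c(1, -2)),
#'                          x0 = c(0, 0))
#' fit <- scf_optimize(surf, method = "sgek-diis")
#' coef(fit)
#' @export
scf_optimize <- function(backend,
                         method = c("sgek-diis", "sgek-bfgs", "rgdiis"),
                         control = scf_control()) {
  method <- match.arg(method)
  stopifnot(inherits(backend, "scf_backend"), inherits(control, "scf_control"))
  if (method == "rgdiis") {
    .run_optimizer(backend, control, method, .rgdiis_step)
  } else {
    control$expansion <- if (method == "sgek-diis") "diis" else "bfgs"
    .run_optimizer(backend, control, method, .sgek_step)
  }
}

## --------------------------------------------------------- fit methods ----

#' @export
print.scf_fit <- function(x, ...) {
  cat(sprintf("%s: %s in %d iteration(s), final energy %.10f\n",
              x$method, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$energy))
  invisible(x)
}

#' @export
summary.scf_fit <- function(object, ...) {
  tr <- object$trace
  cat(sprintf("Method:      %s\n", object$method))
  cat(sprintf("Converged:   %s (%d iterations)\n", object$converged,
              object$iterations))
  cat(sprintf("Energy:      %.10f hartree\n", object$energy))
  cat(sprintf("|g| metric:  %.3e (threshold %.1e)\n",
              tr$g_max[nrow(tr)], object$control$fock_tol))
  cat(sprintf("Last step:   %.3e (threshold %.1e)\n",
              tr$step_norm[nrow(tr)], object$control$step_tol))
  cat(sprintf("Max f_L:     %.4f\n", max(tr$f_L)))
  invisible(object)
}

#' @export
coef.scf_fit <- function(object, ...) {
  if (inherits(object$backend, "analytic_backend")) object$backend$x
  else object$backend$C
}

#' @importFrom stats pnorm predict coef residuals
#' @importFrom graphics plot
#' @export
plot.scf_fit <- function(x, ...) {
  tr <- x$trace
  e <- tr$energy - min(tr$energy)
  graphics::plot(tr$iter, pmax(e, 1e-16), type = "b", log = "y",
       xlab = "iteration", ylab = "energy above best (hartree)",
       main = sprintf("%s convergence", x$method), ...)
  invisible(x)
}

#' @export
residuals.scf_fit <- function(object, ...) object$trace$g_max
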