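test_that("variance limit is proportional to the reduced gradient norm", {
  ctl <- scf_control()
  expect_equal(variance_limit(c(1, 0, 0), ctl), 0.3)
  expect_equal(variance_limit(numeric(3), ctl), 0)
  g <- c(0.3, -0.4)
  expect_equal(variance_limit(10 * g, ctl), 10 * variance_limit(g, ctl))
})

test_that("microiterations find quadratic stationary points or hit the wall", {
  set.seed(61)
  K <- 3
  A <- diag(c(1, 2, 4))
  xstar <- c(0.5, -0.3, 0.2)
  eq <- function(x) 0.5 * sum((x - xstar) * (A %*% (x - xstar)))
  gq <- function(x) as.numeric(A %*% (x - xstar))
  ## training includes the minimizer itself, so the interpolating surrogate
  ## has an exact stationary point there
  pts <- c(lapply(1:5, function(i) rnorm(K, sd = 0.4)), list(xstar))
  coords <- do.call(rbind, pts)
  en <- vapply(pts, eq, 0); gr <- t(vapply(pts, gq, numeric(K)))
  mu <- max(en) + 10
  mod <- gek(coords, en, gr, lengths_from_eigenvalues(diag(A), mu, max(en)), mu)
  ## generous wall: reach the analytic minimizer
  out <- rsrfo_microiterations(mod, coords[1, ], var_max = 1e6)
  expect_equal(coords[1, ] + out$step, xstar, tolerance = 1e-6)
  expect_equal(out$reason, "stationary")
  ## zero wall: zero step
  out0 <- rsrfo_microiterations(mod, coords[5, ], var_max = 0)
  expect_equal(out0$step, numeric(K))
  expect_equal(out0$reason, "variance_truncated")
  ## finite wall: the returned point sits on the wall
  outw <- rsrfo_microiterations(mod, coords[5, ], var_max = 1e-4)
  expect_equal(outw$reason, "variance_truncated")
  vr <- predict(mod, coords[5, ] + outw$step, order = 0L)$variance
  expect_equal(vr, 1e-4, tolerance = 1e-2)
})

test_that("a single-point model steps along the damped Newton direction", {
  K <- 2
  eps <- c(1, 4)
  e1 <- 0; g1 <- c(0.3, 0.8)
  mu <- e1 + 10
  mod <- gek(matrix(0, 1, K), e1, matrix(g1, 1),
             lengths_from_eigenvalues(eps, mu, e1), mu)
  out <- rsrfo_microiterations(mod, c(0, 0), var_max = 1e-3)
  expect_equal(out$reason, "variance_truncated")
  dirs <- out$step / sqrt(sum(out$step^2))
  want <- -g1 / eps; want <- want / sqrt(sum(want^2))
  expect_equal(abs(sum(dirs * want)), 1, tolerance = 1e-2)
})

test_that("loosening factor follows the golden-ratio angle rules", {
  ctl <- scf_control()
  phi <- (1 + sqrt(5)) / 2
  a <- c(1, 0)
  expect_equal(update_loosening(1, NULL, a, ctl), 1)
  expect_equal(update_loosening(1, a, 2 * a, ctl), phi)
  expect_equal(update_loosening(phi, a, a, ctl), phi^2)
  rot <- function(deg) {
    th <- deg * pi / 180
    c(cos(th), sin(th))
  }
  expect_equal(update_loosening(phi, a, rot(30), ctl), 1)    # reset
  expect_equal(update_loosening(phi, a, rot(10), ctl), phi)  # dead zone
})

test_that("Hessian loosening scales curvature only along the step direction", {
  h <- rep(1, 4)
  q <- c(1, 0, 0, 0)
  B <- diag(4)[, 1:2]
  sb <- project_hessian(B, h, f_L = 2, q_dir = q)
  ## along q: 1/f_L^2; orthogonal: unchanged
  expect_equal(sort(sb$eps), c(0.25, 1))
  ## f_L = 1 leaves everything alone
  sb1 <- project_hessian(B, h, f_L = 1)
  expect_equal(sb1$eps, c(1, 1))
  ## general h, direction mixed into the subspace
  set.seed(62)
  h2 <- runif(4, 0.5, 2)
  q2 <- rnorm(4); q2 <- q2 / sqrt(sum(q2^2))
  W <- diag(4) + (1 / 3 - 1) * tcrossprod(q2)
  Ht <- t(W) %*% diag(h2) %*% W
  B2 <- orthonormalize(lapply(1:2, function(i) rnorm(4)))
  sb2 <- project_hessian(B2, h2, f_L = 3, q_dir = q2)
  expect_equal(sort(eigen(crossprod(B2, Ht %*% B2))$values), sb2$eps,
               tolerance = 1e-10)
})

test_that("all optimizers reach the analytic minimizer of an SPD quadratic", {
  set.seed(63)
  n <- 6
  A <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
  ctr <- rnorm(n)
  surf <- analytic_surface("quadratic", list(A = A, center = ctr),
                           x0 = numeric(n))
  ctl <- scf_control(fock_tol = 1e-6)
  for (m in c("sgek-diis", "sgek-bfgs", "rgdiis")) {
    fit <- scf_optimize(surf, method = m, control = ctl)
    expect_true(fit$converged, info = m)
    expect_equal(coef(fit), ctr, tolerance = 1e-5, ignore_attr = TRUE)
    ## strictly decreasing energy on a convex problem
    expect_lt(fit$trace$energy[2], fit$trace$energy[1])
  }
})

test_that("accepted surrogate steps lie in the span of the projection map", {
  ## instrument one S-GEK iteration by reproducing its subspace and
  ## checking the full-space step has no residual outside span(P_hat)
  set.seed(64)
  sys <- fix_h4("sz")
  b <- hf_backend(sys)
  fit <- scf_optimize(b, method = "sgek-diis",
                      control = scf_control(max_iter = 6))
  tr <- fit$trace
  expect_true(all(tr$K[-1] >= 1, na.rm = TRUE))
  ## the driver's step is back_transform(P_hat, z): verify the projector
  ## round trip on random reduced steps for a typical basis
  history <- fit$history
  g <- backend_gradient(fit$backend)
  h <- backend_guess_hessian(fit$backend)
  vecs <- collect_vectors(history[-length(history)], g,
                          expansion = diis_direction(history, h))
  B <- orthonormalize(vecs)
  sb <- project_hessian(B, h)
  for (rep in 1:5) {
    z <- rnorm(ncol(sb$P_hat))
    dx <- back_transform(sb, z)
    resid <- dx - sb$P_hat %*% project_point(sb, dx)
    expect_lt(max(abs(resid)), 1e-10)
  }
})

test_that("convergence test is strict in all three criteria", {
  ctl <- scf_control()
  expect_true(rvoscf:::.converged(1e-10, 1e-5, 1e-4, ctl))
  expect_false(rvoscf:::.converged(1e-10, 1e-3, 1e-4, ctl))   # Fock fails
  expect_false(rvoscf:::.converged(1e-8, 1e-5, 1e-4, ctl))    # energy fails
  expect_false(rvoscf:::.converged(1e-10, 1e-5, 1e-2, ctl))   # step fails
  ## exactly at thresholds: not converged
  expect_false(rvoscf:::.converged(1e-9, 1e-5, 1e-4, ctl))
  expect_false(rvoscf:::.converged(1e-10, 1.5e-4, 1e-4, ctl))
  expect_false(rvoscf:::.converged(1e-10, 1e-5, 1e-3, ctl))
})

test_that("undershoot mitigation escapes a flat slope faster", {
  run_slope <- function(mitigate) {
    surf <- analytic_surface("slope",
                             list(slope = 0.1, floor_at = 50, curvature = 1))
    scf_optimize(surf, method = "sgek-diis",
                 control = scf_control(mitigate = mitigate, max_iter = 10))
  }
  with_m <- run_slope(TRUE)
  without_m <- run_slope(FALSE)
  expect_gt(coef(with_m), coef(without_m))
  ## f_L grows by golden-ratio multiples under near-parallel steps
  phi <- (1 + sqrt(5)) / 2
  fl <- with_m$trace$f_L
  expect_equal(fl[2:5], phi^(1:4), tolerance = 1e-10)
  expect_true(all(without_m$trace$f_L == 1))
})

test_that("identical configuration yields bit-identical traces", {
  sys <- fix_h2()
  b <- hf_backend(sys)
  ctl <- scf_control(seed = 99L)
  f1 <- scf_optimize(b, method = "sgek-bfgs", control = ctl)
  f2 <- scf_optimize(b, method = "sgek-bfgs", control = ctl)
  expect_identical(f1$trace, f2$trace)
})

test_that("nonconvergence at max_iter is a reported status, not an error", {
  surf <- analytic_surface("slope",
                           list(slope = 0.1, floor_at = 50, curvature = 1))
  fit <- scf_optimize(surf, method = "sgek-diis",
                      control = scf_control(max_iter = 3))
  expect_false(fit$converged)
  expect_equal(fit$iterations, 3)
})

test_that("fit methods print, summarize and expose residual metrics", {
  surf <- analytic_surface("quadratic",
                           list(A = diag(2), center = c(1, 1)), x0 = c(0, 0))
  fit <- scf_optimize(surf, method = "rgdiis")
  expect_output(print(fit), "converged")
  expect_output(summary(fit), "Energy")
  expect_equal(length(residuals(fit)), fit$iterations)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
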