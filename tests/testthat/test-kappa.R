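test_that("blocked exponential matches closed forms and a generic oracle", {
  ## zero rotation
  expect_equal(expm_blocked(matrix(0, 2, 3)), diag(5))
  ## 1x1 block: plane rotation by theta
  th <- 0.731
  expect_equal(expm_blocked(matrix(th, 1, 1)),
               matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2),
               tolerance = 1e-14)
  ## random block vs scaling-and-squaring oracle
  skip_if_not_installed("Matrix")
  set.seed(41)
  for (rep in 1:5) {
    X <- rand_block(3, 4, sd = 0.5)
    Q <- expm_blocked(X)
    expect_equal(max(abs(crossprod(Q) - diag(7))), 0, tolerance = 1e-12)
    Qo <- as.matrix(Matrix::expm(Matrix::Matrix(antisym_embed(X))))
    expect_equal(Q, Qo, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("orbital rotation preserves S-orthonormality and the energy path", {
  sys <- fix_h2()
  b <- hf_backend(sys)
  C <- b$C
  expect_equal(rotate_orbitals(C, sys$S, matrix(0, 1, 3)), C)
  set.seed(42)
  X <- rand_block(1, 3, sd = 0.4)
  C2 <- rotate_orbitals(C, sys$S, X)
  expect_equal(crossprod(C2, sys$S %*% C2), diag(4), tolerance = 1e-10)
  ## energy from the Fock build equals the determinant-expansion oracle
  expect_equal(energy_and_fock(sys, C2)$energy, hf_energy_determinant(sys, C2),
               tolerance = 1e-10)
  expect_error(rotate_orbitals(2 * C, sys$S, X), "orthonormal")
})

test_that("scos is continuous through its removable singularity", {
  expect_equal(scos(0), pi / 2)
  expect_equal(scos(1), 1)
  ## 8th-order series about x = 1: scos(1-t) with theta = acos(x)
  x <- 0.999
  th <- acos(x)
  series <- 1 + th^2 / 6 + 7 * th^4 / 360 + 31 * th^6 / 15120 +
    127 * th^8 / 604800
  expect_equal(scos(x), series, tolerance = 1e-10)
  expect_error(scos(1.1), "outside")
})

test_that("rebasing identities: null step, self step, orbital equivalence", {
  set.seed(43)
  no <- 3; nv <- 5
  X <- rand_block(no, nv, sd = 0.2)
  rb0 <- rebase_coordinates(X, matrix(0, no, nv))
  expect_equal(rb0$X_tilde, X, tolerance = 1e-12)
  expect_equal(rb0$U_occ, diag(no), tolerance = 1e-12)
  expect_equal(rb0$U_vir, diag(nv), tolerance = 1e-12)
  rbX <- rebase_coordinates(X, X)
  expect_lt(max(abs(rbX$X_tilde)), 1e-10)
  for (rep in 1:10) {
    X <- rand_block(no, nv, sd = 0.15)
    dX <- rand_block(no, nv, sd = 0.15)
    rb <- rebase_coordinates(X, dX)
    expect_equal(crossprod(rb$U_occ), diag(no), tolerance = 1e-10)
    expect_equal(crossprod(rb$U_vir), diag(nv), tolerance = 1e-10)
    ## exp(dk) exp(kt) = exp(k) blockdiag(U_occ, U_vir)
    lhs <- expm_blocked(dX) %*% expm_blocked(rb$X_tilde)
    U <- rbind(cbind(rb$U_occ, matrix(0, no, nv)),
               cbind(matrix(0, nv, no), rb$U_vir))
    expect_equal(lhs, expm_blocked(X) %*% U, tolerance = 1e-10)
  }
  ## 90-degree occupied rotation cannot be rebased
  expect_error(rebase_coordinates(matrix(0, 1, 1), matrix(pi / 2, 1, 1)),
               "singular value")
})

test_that("series and closed transports are mutual oracles", {
  set.seed(44)
  for (dims in list(c(3, 5), c(4, 6))) {
    for (rep in 1:50) {
      L <- rand_block(dims[1], dims[2], sd = 1)
      X <- rand_block(dims[1], dims[2], sd = 0.4)
      ts <- transport_gradient_series(L, X)
      tc <- transport_gradient_closed(L, X)
      expect_equal(ts, tc, tolerance = 1e-12)
    }
  }
  ## constructed repeated singular values
  L <- rand_block(3, 5)
  Xr <- cbind(0.37 * diag(3), matrix(0, 3, 2))
  expect_equal(transport_gradient_series(L, Xr),
               transport_gradient_closed(L, Xr), tolerance = 1e-12)
  ## trivial cases
  expect_equal(transport_gradient_series(L, matrix(0, 3, 5)), L)
  expect_equal(transport_gradient_closed(L, matrix(0, 3, 5)), L,
               tolerance = 1e-14)
  ## first-order dominance for tiny rotations with U factors
  U_o <- qr.Q(qr(matrix(rnorm(9), 3)))
  U_v <- qr.Q(qr(matrix(rnorm(25), 5)))
  tiny <- rand_block(3, 5, sd = 1e-8)
  expect_equal(transport_gradient_series(L, tiny, U_o, U_v),
               crossprod(U_o, L) %*% U_v, tolerance = 1e-12)
})

test_that("blocked transport equals the nested-commutator oracle", {
  set.seed(45)
  ## k = 1 truncation is G + [nu, G]/2
  G <- antisym_embed(rand_block(2, 3))
  nu <- antisym_embed(rand_block(2, 3))
  expect_equal(commutator_series_oracle(G, nu, terms = 1),
               G + (nu %*% G - G %*% nu) / 2)
  expect_equal(commutator_series_oracle(G, 0 * nu, terms = 5), G)
  ## full embedding: ov block matches the blocked formulas, either sign
  for (rep in 1:10) {
    L <- rand_block(3, 5)
    X <- rand_block(3, 5, sd = 0.3)
    ov <- commutator_series_oracle(antisym_embed(L), antisym_embed(X),
                                   terms = 40)[1:3, 4:8]
    ov_neg <- commutator_series_oracle(antisym_embed(L), -antisym_embed(X),
                                       terms = 40)[1:3, 4:8]
    expect_equal(transport_gradient_series(L, X), ov, tolerance = 1e-10)
    expect_equal(ov, ov_neg, tolerance = 1e-12)
  }
})

test_that("occupied-space overlap separates identical, rotated and orthogonal spans", {
  sys <- fix_h4("sz")
  b <- hf_backend(sys)
  Cocc <- b$C[, 1:2]
  S <- sys$S
  expect_equal(occupied_space_overlap(Cocc, Cocc, S), 1, tolerance = 1e-12)
  ## redundant occupied rotation leaves the overlap at 1
  th <- 0.4
  U <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(occupied_space_overlap(Cocc, Cocc %*% U, S), 1,
               tolerance = 1e-12)
  ## replacing one occupied orbital by a virtual gives overlap 0
  Cmix <- cbind(Cocc[, 1], b$C[, 3])
  expect_equal(occupied_space_overlap(Cocc, Cmix, S), 0, tolerance = 1e-10)
  ## analytic two-orbital mixing angle
  Cth <- cbind(Cocc[, 1], cos(th) * Cocc[, 2] + sin(th) * b$C[, 3])
  expect_equal(occupied_space_overlap(Cocc, Cth, S), cos(th),
               tolerance = 1e-10)
})

test_that("rebasing preserves spans, energies and transported gradients", {
  set.seed(46)
  sys <- fix_h4("sz")
  b <- hf_backend(sys)
  S <- sys$S
  no <- sys$n_alpha; nv <- sys$nbf - no
  for (rep in 1:10) {
    X <- rand_block(no, nv, sd = 0.15)
    dX <- rand_block(no, nv, sd = 0.15)
    rb <- rebase_coordinates(X, dX)
    C_point <- rotate_orbitals(b$C, S, X)
    C_new_ref <- rotate_orbitals(b$C, S, dX)
    C_rebased <- rotate_orbitals(C_new_ref, S, rb$X_tilde)
    expect_equal(occupied_space_overlap(C_point[, 1:no], C_rebased[, 1:no], S),
                 1, tolerance = 1e-10)
    expect_equal(energy_and_fock(sys, C_rebased)$energy,
                 energy_and_fock(sys, C_point)$energy, tolerance = 1e-10)
  }
})

test_that("transported history gradients match finite differences in the new frame", {
  ## the decisive frame-consistency invariant: walk several steps, rebase
  ## the stored points each time, then compare each transported gradient
  ## with a central-difference gradient of the backend energy at the
  ## point's rebased coordinates
  set.seed(47)
  for (fix in list(fix_h4("sz"), fix_h3_doublet("sz"))) {
    b <- hf_backend(fix)
    n <- backend_dim(b)
    dims <- backend_block_dims(b)
    history <- list()
    for (it in 1:3) {
      recd <- rvoscf:::.new_record(b)
      dx <- rnorm(n, sd = 0.1)
      b <- backend_step(b, dx)
      history <- lapply(c(history, list(recd)), rvoscf:::.rebase_record,
                        dx_full = dx, dims = dims)
    }
    for (r in history) {
      bb <- backend_step(b, r$x)
      expect_equal(backend_energy(bb), r$energy, tolerance = 1e-10)
      fd <- fd_grad(function(z) backend_energy(backend_step(b, z)), r$x,
                    h = 1e-5)
      expect_equal(r$g, fd, tolerance = 1e-5)
    }
  }
})
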