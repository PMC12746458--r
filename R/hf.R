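#' Minimal Hartree-Fock backend
#'
#' A self-contained RHF/UHF engine for toy systems built from H and He
#' atoms with uncontracted s-type Gaussian basis functions (at most 10
#' functions).  All integrals follow the closed-form s-orbital expressions
#' with the Boys function F0; the engine exists to provide genuine SCF
#' energy surfaces for the orbital optimizer, not production chemistry.
#'
#' @name hf-backend
#' @keywords internal
NULL

BOHR_PER_ANGSTROM <- 1.8897259886

.element_Z <- c(H = 1, He = 2)

## package-chosen uncontracted s exponents (even-tempered split of an
## STO-1G-like single exponent); "sz" = 1 function/atom, "dz" = 2
.basis_sets <- list(
  sz = list(H = 0.41662, He = 1.18637),
  dz = list(H = c(1.20, 0.25), He = c(3.00, 0.65))
)

## Boys function F0(t) = erf(sqrt(t)) * sqrt(pi/t) / 2, series for small t
.boys0 <- function(t) {
  small <- t < 1e-12
  out <- numeric(length(t))
  out[small] <- 1 - t[small] / 3 + t[small]^2 / 10
  tb <- t[!small]
  out[!small] <- 0.5 * sqrt(pi / tb) * (2 * pnorm(sqrt(2 * tb)) - 1)
  out
}

#' Assemble integrals and a core-guess state for a toy H/He system
#'
#' @param geometry data frame with columns \code{element}, \code{x},
#'   \code{y}, \code{z}, or a path to an XYZ file (see [read_xyz()]).
#' @param basis \code{"sz"} (one s function per atom) or \code{"dz"} (two),
#'   or a named list mapping element to exponent vectors.
#' @param charge total charge.
#' @param multiplicity spin multiplicity (1 = RHF; otherwise UHF).
#' @param unit \code{"angstrom"} (XYZ convention) or \code{"bohr"}.
#' @return an object of class \code{"hf_system"} holding S, hcore, the ERI
#'   tensor, nuclear repulsion, electron counts and core-guess orbitals.
#' @export
build_toy_system <- function(geometry, basis = "dz", charge = 0,
                             multiplicity = 1, unit = "angstrom") {
  if (is.character(geometry)) geometry <- read_xyz(geometry)
  stopifnot(all(c("element", "x", "y", "z") %in% names(geometry)))
  if (!all(geometry$element %in% names(.element_Z)))
    stop("build_toy_system: only H and He are supported")
  if (is.character(basis)) {
    if (!basis %in% names(.basis_sets)) stop("unknown basis set: ", basis)
    basis <- .basis_sets[[basis]]
  }
  scale <- if (unit == "angstrom") BOHR_PER_ANGSTROM else 1
  centers <- as.matrix(geometry[, c("x", "y", "z")]) * scale
  Z <- unname(.element_Z[geometry$element])

  exps <- numeric(0); at <- integer(0)
  for (a in seq_len(nrow(geometry))) {
    e <- basis[[geometry$element[a]]]
    exps <- c(exps, e); at <- c(at, rep(a, length(e)))
  }
  nbf <- length(exps)
  if (nbf > 10) stop("build_toy_system: more than 10 basis functions")
  norm <- (2 * exps / pi)^0.75
  R <- centers[at, , drop = FALSE]

  S <- Tk <- V <- matrix(0, nbf, nbf)
  for (i in seq_len(nbf)) for (j in 1:i) {
    a <- exps[i]; b <- exps[j]; p <- a + b
    ab2 <- sum((R[i, ] - R[j, ])^2)
    pre <- norm[i] * norm[j] * exp(-a * b / p * ab2)
    S[i, j] <- S[j, i] <- pre * (pi / p)^1.5
    Tk[i, j] <- Tk[j, i] <- a * b / p * (3 - 2 * a * b / p * ab2) * S[i, j]
    P <- (a * R[i, ] + b * R[j, ]) / p
    v <- 0
    for (c_ in seq_len(nrow(centers))) {
      v <- v - Z[c_] * 2 * pi / p * pre * .boys0(p * sum((P - centers[c_, ])^2))
    }
    V[i, j] <- V[j, i] <- v
  }
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    stop("build_toy_system: linearly dependent basis")

  eri <- array(0, rep(nbf, 4))
  for (i in seq_len(nbf)) for (j in 1:i) {
    a <- exps[i]; b <- exps[j]; p <- a + b
    Pij <- (a * R[i, ] + b * R[j, ]) / p
    pre_ij <- norm[i] * norm[j] * exp(-a * b / p * sum((R[i, ] - R[j, ])^2))
    for (k in seq_len(i)) for (l in 1:(if (k == i) j else k)) {
      c2 <- exps[k]; d2 <- exps[l]; q <- c2 + d2
      Qkl <- (c2 * R[k, ] + d2 * R[l, ]) / q
      pre_kl <- norm[k] * norm[l] * exp(-c2 * d2 / q * sum((R[k, ] - R[l, ])^2))
      val <- 2 * pi^2.5 / (p * q * sqrt(p + q)) * pre_ij * pre_kl *
        .boys0(p * q / (p + q) * sum((Pij - Qkl)^2))
      for (idx in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                       c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                       c(k, l, j, i), c(l, k, j, i)))
        eri[idx[1], idx[2], idx[3], idx[4]] <- val
    }
  }

  E_nuc <- 0
  if (nrow(centers) > 1) {
    for (a in 2:nrow(centers)) for (b in 1:(a - 1))
      E_nuc <- E_nuc + Z[a] * Z[b] / sqrt(sum((centers[a, ] - centers[b, ])^2))
  }

  n_elec <- sum(Z) - charge
  if (n_elec < 1) stop("build_toy_system: no electrons")
  restricted <- multiplicity == 1
  if (restricted && n_elec %% 2 != 0)
    stop("build_toy_system: odd electron count needs multiplicity > 1")
  n_alpha <- (n_elec + multiplicity - 1) / 2
  n_beta <- n_elec - n_alpha
  if (n_alpha != round(n_alpha) || n_beta < 0 || n_alpha > nbf)
    stop("build_toy_system: inconsistent charge/multiplicity")

  hcore <- Tk + V
  ## core guess: symmetric orthogonalization, diagonalize hcore
  se <- eigen(S, symmetric = TRUE)
  Shalf <- se$vectors %*% (1 / sqrt(se$values) * t(se$vectors))
  hg <- eigen(Shalf %*% hcore %*% Shalf, symmetric = TRUE)
  ord <- order(hg$values)                  # ascending orbital energies
  C0 <- Shalf %*% hg$vectors[, ord, drop = FALSE]

  structure(list(S = S, hcore = hcore, eri = eri, E_nuc = E_nuc,
                 nbf = nbf, n_alpha = as.integer(n_alpha),
                 n_beta = as.integer(n_beta), restricted = restricted,
                 C_guess = C0, geometry = geometry, Z = Z),
            class = "hf_system")
}

## Coulomb/exchange contraction of the ERI tensor with a density matrix
.jk <- function(eri, D) {
  nbf <- dim(eri)[1]
  J <- matrix(0, nbf, nbf); Kx <- matrix(0, nbf, nbf)
  for (i in seq_len(nbf)) for (j in seq_len(nbf)) {
    J[i, j] <- sum(eri[i, j, , ] * D)
    Kx[i, j] <- sum(eri[i, , , j] * t(D))
  }
  list(J = J, K = Kx)
}

#' Energy and MO-basis Fock matrices for given orbitals
#'
#' @param sys an \code{"hf_system"}.
#' @param C coefficient matrix (RHF) or list with elements \code{a},
#'   \code{b} (UHF), S-orthonormal.
#' @return list with \code{energy} and \code{F_mo} (RHF: matrix; UHF: list
#'   per spin).
#' @export
energy_and_fock <- function(sys, C) {
  if (sys$restricted) {
    Cocc <- C[, seq_len(sys$n_alpha), drop = FALSE]
    D <- 2 * tcrossprod(Cocc)
    jk <- .jk(sys$eri, D)
    F_ao <- sys$hcore + jk$J - 0.5 * jk$K
    energy <- 0.5 * sum(D * (sys$hcore + F_ao)) + sys$E_nuc
    list(energy = energy, F_mo = crossprod(C, F_ao %*% C))
  } else {
    Ca <- C$a; Cb <- C$b
    Da <- tcrossprod(Ca[, seq_len(sys$n_alpha), drop = FALSE])
    Db <- if (sys$n_beta > 0)
      tcrossprod(Cb[, seq_len(sys$n_beta), drop = FALSE])
    else matrix(0, sys$nbf, sys$nbf)
    jka <- .jk(sys$eri, Da); jkb <- .jk(sys$eri, Db)
    J <- jka$J + jkb$J
    Fa <- sys$hcore + J - jka$K
    Fb <- sys$hcore + J - jkb$K
    energy <- 0.5 * sum(Da * (sys$hcore + Fa)) +
      0.5 * sum(Db * (sys$hcore + Fb)) + sys$E_nuc
    list(energy = energy,
         F_mo = list(a = crossprod(Ca, Fa %*% Ca),
                     b = crossprod(Cb, Fb %*% Cb)))
  }
}

#' Brute-force determinant-expansion energy oracle
#'
#' Independent evaluation of the single-determinant energy by explicit
#' loops over MO-transformed integrals; used to cross-check the
#' density-matrix Fock path.
#'
#' @inheritParams energy_and_fock
#' @return the total energy (hartree).
#' @export
hf_energy_determinant <- function(sys, C) {
  contract1 <- function(T4, Cm) {
    ## contract the first tensor index with Cm and cycle axes
    d <- dim(T4)
    out <- crossprod(Cm, matrix(T4, d[1], prod(d[-1])))
    aperm(array(out, c(ncol(Cm), d[-1])), c(2, 3, 4, 1))
  }
  mo_tensor <- function(C1, C2, C3, C4) {
    T4 <- sys$eri
    for (Cm in list(C1, C2, C3, C4)) T4 <- contract1(T4, Cm)
    T4
  }
  if (sys$restricted) {
    Cocc <- C[, seq_len(sys$n_alpha), drop = FALSE]
    no <- sys$n_alpha
    h_mo <- crossprod(Cocc, sys$hcore %*% Cocc)
    O <- mo_tensor(Cocc, Cocc, Cocc, Cocc)
    e <- 2 * sum(diag(h_mo))
    for (i in seq_len(no)) for (j in seq_len(no))
      e <- e + 2 * O[i, i, j, j] - O[i, j, j, i]
    e + sys$E_nuc
  } else {
    Ca <- C$a[, seq_len(sys$n_alpha), drop = FALSE]
    spin_e <- function(Cocc) {
      no <- ncol(Cocc)
      O <- mo_tensor(Cocc, Cocc, Cocc, Cocc)
      e <- sum(diag(crossprod(Cocc, sys$hcore %*% Cocc)))
      for (i in seq_len(no)) for (j in seq_len(no))
        e <- e + 0.5 * (O[i, i, j, j] - O[i, j, j, i])
      e
    }
    e <- spin_e(Ca)
    if (sys$n_beta > 0) {
      Cb <- C$b[, seq_len(sys$n_beta), drop = FALSE]
      e <- e + spin_e(Cb)
      Oab <- mo_tensor(Ca, Ca, Cb, Cb)
      for (i in seq_len(sys$n_alpha)) for (j in seq_len(sys$n_beta))
        e <- e + Oab[i, i, j, j]
    }
    e + sys$E_nuc
  }
}
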