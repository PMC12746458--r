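## fixture builders shared across test files; all geometry in Angstrom

fix_h2 <- function(basis = "dz") {
  build_toy_system(data.frame(element = c("H", "H"), x = c(0, 0.74),
                              y = 0, z = 0), basis = basis)
}

fix_heh_cation <- function(basis = "dz") {
  build_toy_system(data.frame(element = c("He", "H"), x = c(0, 0.93),
                              y = 0, z = 0), basis = basis, charge = 1)
}

fix_h4 <- function(basis = "dz", multiplicity = 1) {
  build_toy_system(h_chain_geometry(4, 0.9), basis = basis,
                   multiplicity = multiplicity)
}

fix_h3_doublet <- function(basis = "dz") {
  build_toy_system(h_chain_geometry(3, 0.9), basis = basis,
                   multiplicity = 2)
}

## random blocked rotation with controlled magnitude
rand_block <- function(no, nv, sd = 0.1) matrix(rnorm(no * nv, sd = sd), no, nv)

## embed an occupied-virtual block as a full antisymmetric matrix
antisym_embed <- function(X) {
  no <- nrow(X); nv <- ncol(X)
  rbind(cbind(matrix(0, no, no), X), cbind(-t(X), matrix(0, nv, nv)))
}

## finite-difference gradient of a scalar function of an n-vector
fd_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}
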