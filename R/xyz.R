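#' Read an XYZ geometry file
#'
#' Standard format: atom count line, comment line, then one
#' \code{element x y z} row per atom (coordinates in Angstrom).
#'
#' @param path file path.
#' @return data frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("read_xyz: malformed file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || length(lines) < n + 2)
    stop("read_xyz: malformed file: ", path)
  rows <- strsplit(trimws(lines[2 + seq_len(n)]), "\\s+")
  data.frame(element = vapply(rows, `[`, "", 1),
             x = as.numeric(vapply(rows, `[`, "", 2)),
             y = as.numeric(vapply(rows, `[`, "", 3)),
             z = as.numeric(vapply(rows, `[`, "", 4)))
}

#' Write an XYZ geometry file
#'
#' @param geometry data frame with columns \code{element,x,y,z} (Angstrom).
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(geometry, path, comment = "") {
  lines <- c(nrow(geometry), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f", geometry$element,
                     geometry$x, geometry$y, geometry$z))
  writeLines(lines, path)
  invisible(path)
}

#' Hydrogen-chain fixture geometries
#'
#' Generates a linear H-chain with a fixed bond length, optionally
#' jittered to break symmetry (reproducible via \code{seed}).
#'
#' @param n_atoms number of H atoms.
#' @param bond_length nearest-neighbour distance in Angstrom.
#' @param jitter standard deviation of Gaussian coordinate noise.
#' @param seed RNG seed used when \code{jitter > 0}.
#' @return data frame suitable for [build_toy_system()].
#' @export
h_chain_geometry <- function(n_atoms, bond_length = 0.9, jitter = 0,
                             seed = 1L) {
  g <- data.frame(element = rep("H", n_atoms),
                  x = bond_length * (seq_len(n_atoms) - 1), y = 0, z = 0)
  if (jitter > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    g$x <- g$x + rnorm(n_atoms, sd = jitter)
    g$y <- g$y + rnorm(n_atoms, sd = jitter)
    g$z <- g$z + rnorm(n_atoms, sd = jitter)
  }
  g
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
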