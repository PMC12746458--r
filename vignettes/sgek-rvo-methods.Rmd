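---
title: "Surrogate-driven SCF orbital optimization: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-driven SCF orbital optimization: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvoscf)
```

## The problem

Self-consistent field (SCF) orbital optimization minimizes the
Hartree–Fock (or Kohn–Sham) energy over sets of occupied molecular
orbitals.  In the exponential parametrization a trial orbital set is
`C' = C exp(kappa)` with `kappa` the blocked antisymmetric generator built
from the occupied–virtual rotation block `X` (`n_occ x n_vir`); the
entries of `X` are the only nonredundant variables, and at the reference
orbitals the gradient is proportional to the occupied–virtual block of the
Fock matrix.  Every outer iteration costs a Fock build, so the economics
of SCF favor methods that squeeze the most out of each (energy, gradient)
evaluation.

`rvoscf` implements a surrogate-model driver for this problem: a
gradient-enhanced Kriging (GEK) interpolant is built over the iteration
history in a compressed subspace, cheap microiterations locate a step on
the surrogate, and the step length is governed by the surrogate's own
predicted variance (restricted-variance optimization, RVO) rather than a
fixed trust radius.  An r-GDIIS optimizer — DIIS over quasi-Newton
preconditioned gradients with a reset guard — is included as the baseline
comparator, sharing the history and convergence machinery.

## The surrogate

The model is a Gaussian-process interpolant conditioned on energies *and*
gradients:

    E*(x) = mu + v(x)^T M^{-1} (y - 1 mu)

`M` is the covariance matrix over all observations (values and gradient
components), `v(x)` the covariance of the prediction point with those
observations, `y` stacks all energies first and then the gradients point
by point, and `1` marks the energy positions.  The covariance function is
Matérn 5/2 on the anisotropically scaled distance
`d = sqrt(sum_k ((x_k - x'_k)/l_k)^2)`.  Matérn 5/2 is the minimum
smoothness that supports gradient conditioning and still yields a
predictor Hessian, which the RS-RFO microiterations need; the closed-form
first/second/third kernel derivatives are validated against finite
differences in the test suite.

Two readings of the prediction equation are possible because the variance
expression uses the centered residual `(y - 1 mu)` while the prediction
line prints plain `y`; the centered form is used throughout, which makes
the model interpolate its data exactly and relax to `mu` far away.

The predicted variance

    s^2(x) = (y - 1 mu)^T M^{-1} (y - 1 mu) / m * [1 - v^T M^{-1} v]

is zero at every data point and approaches the first factor far from all
data.  The step search is truncated where `s^2` reaches
`variance_coefficient * ||g^r||`: the limit scales with the gradient, so
steps shorten automatically as convergence approaches.  The
proportionality constant is not fixed by the method's description; the
package default is 0.3, exposed as `scf_control(variance_coefficient=)`.
All fixture systems converge in 4–8 iterations under this choice, and the
property suite (not a tuned benchmark) is the only calibration evidence.

**Prior mean.** `mu = E_max + 10` hartree, with `E_max` the maximum
training energy.  The offset makes the surrogate bounded with positive
curvature far from the data — the same property that causes systematic
undershooting on flat sloped surfaces (below).

**Characteristic lengths.** Set noniteratively from the eigenvalues
`eps_k` of the projected guess Hessian, `l_k = sqrt(5 (mu - E_max) / (3
eps_k))`, so a single-data-point surrogate has predictor curvature
exactly `eps_k` along dimension `k` (unit-tested by finite differences).
Eigenvalues are floored at `hessian_floor = 0.025` before inversion; the
floor is a package choice (the method's description requires only a
positive-definite guess) and is exposed in the control object.

**Conditioning.** `M` is Cholesky-factorized; on failure a `1e-10` nugget
is added once, and if that fails the oldest data point is dropped and the
model reassembled (age pruning; condition-number pruning was considered
and rejected for predictability).  History is capped at 20 previous
points.

## Subspace compression

The full rotation space (dimension `n_occ x n_vir`, summed over spins for
UHF) is compressed to at most `2m + 2` directions: the `m` history
displacements, the `m` history gradients, the current gradient, and one
cheap expansion direction — either an r-GDIIS extrapolation or a BFGS
quasi-Newton prediction, of which only the direction is used.  Vectors
are orthonormalized by modified Gram–Schmidt with one re-orthogonalization
pass and a relative drop tolerance of `1e-8`; the fixed insertion order
(displacements oldest-first, gradients, current gradient, expansion)
determines which near-dependent vectors are dropped and is part of the
package's reproducibility contract.

The diagonal guess Hessian (`2 (eps_a - eps_i)` per spin for UHF,
`4 (eps_a - eps_i)` for RHF, floored — the factor matches the pinned
gradient convention so the first step is a proper quasi-Newton step) is
projected onto the subspace and diagonalized; its eigenvector basis
defines the reduced coordinates, its eigenvalues the characteristic
lengths.  Steps computed in the subspace are back-transformed with the
same orthonormal map, so every accepted step lies in the subspace span by
construction.

## Coordinate and gradient transport

The surrogate is only meaningful if all its data refer to one reference
orbital set.  The package keeps the *current* iterate as the reference
(the exponential map is best behaved near the origin), which means every
accepted step changes the frame and all stored points must be
re-expressed:

* **Coordinates** are rebased through the SVD of the occupied–occupied
  block of `exp(-dkappa) exp(kappa)`, yielding blocked coordinates
  `X~` plus redundant occupied/virtual rotations `U^o, U^v` that absorb
  the part of the rotation the blocked form cannot represent.  The
  package orients these factors so that
  `exp(dkappa) exp(kappa~) = exp(kappa) blockdiag(U^o, U^v)` holds
  exactly (verified to machine precision); note this is the transpose of
  one common way of printing the SVD factors.  A vanishing singular value
  (a 90-degree occupied rotation) makes the retraction impossible; the
  driver then restarts its history from the current point.

* **Gradients** are parallel transported either by the nested-commutator
  series in its blocked recursion form, or by a closed sinc-based formula
  built on the SVD of the rotation block; the two agree to `1e-12` and
  both match a brute-force commutator oracle on full antisymmetric
  embeddings.  The occupied–virtual block of the commutator series is
  *even* in the rotation argument (odd nestings land in the redundant
  blocks), so the sign convention that often plagues such formulas is
  immaterial here — a fact the tests assert explicitly.

**Design choice — one-shot transport.** Each history record stores its
pristine own-frame gradient and accumulated `U` factors, and the
current-frame gradient is recomputed in one transport per frame change
using the record's *current* coordinates.  The alternative incremental
reading (transport by the step `dkappa` alone) is exact only for the point
that was just the reference; for older points it drifts.  The decisive
arbiter is a frame-consistency invariant in the test suite: after several
rebases, each stored gradient must match a central-difference gradient of
the backend energy at the record's rebased coordinates (observed
agreement ~1e-10 on toy systems, asserted at 1e-5).

## Undershoot mitigation

On a flat but sloped energy region the bounded surrogate systematically
undershoots: each step stops at the variance wall well short of where the
surface keeps descending.  The mitigation softens the *model*, not the
step: a loosening factor `f_L` starts at 1, multiplies by the golden
ratio when successive steps are within 5 degrees of each other, and
resets to 1 when they differ by more than 20 degrees.  The guess Hessian
is scaled by `W = I + (1/f_L - 1) q q^T` along the previous step
direction `q` before projection, which divides the curvature along `q`
by `f_L^2`, lengthens the corresponding characteristic length, and lets
the surrogate extrapolate further.  On the package's 1-D slope surface
the mitigated run covers ~16x the distance of the unmitigated one in 10
iterations while `f_L` climbs the golden-ratio ladder.

## Backends

The optimizer sees objectives through a small contract (energy, gradient,
displacement, curvature guess, convergence metric).  Two families ship:

* **Toy Hartree–Fock**: H/He systems with uncontracted s-type Gaussians
  (closed-form integrals via the Boys function, at most 10 basis
  functions), RHF and UHF.  The gradient prefactor (-4 `F_ov` for RHF,
  -2 per spin for UHF) is pinned against finite differences rather than
  trusted from convention, and the Fock-path energy is cross-checked
  against an independent determinant-expansion oracle.  These systems
  produce genuine SCF surfaces — including spin-polarized ones — but are
  not production chemistry: no p/d functions, no correlation, tiny bases.
* **Analytic surfaces**: SPD quadratics (exactness checks), the 1-D
  slope-with-floor (mitigation scenario), a soft-mode valley, and
  Rosenbrock.

What a green test establishes, therefore, is the correctness of the
optimizer machinery — interpolation, transport, subspace algebra,
convergence logic — on faithful small instances; it says nothing about
wall-time competitiveness or behavior on production-size molecules, which
would require a real integral engine and thousands of systems.

## Convergence and numerical choices

Convergence requires simultaneously, with strict inequalities: energy
change `< 1e-9` hartree, maximum occupied–virtual Fock element
`< 1.5e-4` (analytic backends substitute the max gradient component), and
step norm `< 1e-3`.  Hitting `max_iter` (default 400) is a reported
status, not an error.  Microiterations on the surrogate use augmented
Hessian (RFO) steps capped at the largest characteristic length, stop at
a surrogate gradient norm of `1e-8`, and approach the variance wall by
bisection on the step scale (at most 30 halvings, relative tolerance
`1e-6`).  The first iteration, with no history, takes a preconditioned
steepest-descent step capped at norm 0.3.  All algorithms are
deterministic: identical control objects give bit-identical traces (the
`seed` slot exists for fixture generation and reproducibility metadata).

## Known limitations

* The r-GDIIS comparator approximates its published namesake (error
  vectors are preconditioned gradients; reset on coefficient magnitude
  15); only direction information feeds the surrogate subspace, which
  bounds the sensitivity, but iteration-count comparisons against the
  original implementation should not be over-read.
* The full-space RS-RFO subspace expansion of the original second-order
  method is deliberately not implemented (it is what the cheap expansion
  replaces).
* Preliminary-iteration schemes (Fermi aufbau, level shifting, damping)
  are out of scope; optimizations start from the core guess.
* Basis sets are s-only and elements H/He, so degeneracy-rich cases
  (symmetry-induced multiple minima) are under-represented relative to
  transition-metal chemistry.

## A worked run

```{r example}
sys <- build_toy_system(h_chain_geometry(4, 0.9), multiplicity = 3)
fit <- scf_optimize(hf_backend(sys), method = "sgek-diis")
fit
head(fit$trace[, c("iter", "energy", "g_max", "step_norm", "f_L", "K")])
```
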