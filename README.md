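# rvoscf — restricted-variance surrogate optimization for SCF orbitals

`rvoscf` is an R implementation of surrogate-driven self-consistent-field
(SCF) orbital optimization for people who study SCF convergence
acceleration: a gradient-enhanced Kriging (GEK) model is trained on the
iteration history in a compressed subspace, and each SCF step is found by
cheap microiterations on that model, limited by the model's own predicted
variance instead of a fixed trust radius (S-GEK/RVO).  The package also
provides the r-GDIIS baseline it is meant to beat, a minimal Hartree–Fock
engine (H/He, s-type Gaussians) so the optimizer runs on genuine SCF
surfaces, analytic test surfaces, and a small CLI.

## The method in brief

Orbitals are parametrized as `C' = C exp(κ)` with
`κ = [[0, X], [-Xᵀ, 0]]`; the occupied–virtual block `X` holds the
optimization variables and the gradient at the reference is the
occupied–virtual Fock block (up to a pinned constant).  Each iteration:

1. **Rebase** all stored points into the frame of the current orbitals:
   coordinates via an SVD retraction of `exp(-Δκ) exp(κ)`, gradients via
   commutator-series / closed sinc-formula parallel transport.
2. **Compress**: span the `m` history displacements and gradients, the
   current gradient, and one cheap expansion direction (r-GDIIS or BFGS
   prediction) — at most `2m + 2` vectors; project the diagonal guess
   Hessian onto this span and diagonalize it.
3. **Model**: build the GEK surrogate
   `E*(x) = μ + v(x)ᵀ M⁻¹ (y − 1μ)` with a Matérn 5/2 kernel whose
   characteristic lengths `l_k = sqrt(5(μ − E_max)/(3 ε_k))` come from the
   projected-Hessian eigenvalues; `μ = E_max + 10` hartree.
4. **Step**: RS-RFO microiterations on the surrogate until a stationary
   point, or until the predicted variance `s²(x)` hits
   `0.3·‖g^r‖`; back-transform and rotate the orbitals.
5. **Mitigate undershoot**: if successive steps are nearly parallel
   (< 5°), soften the guess curvature along that direction by a
   golden-ratio loosening factor; reset it when steps turn (> 20°).

Convergence requires energy change < 1e-9 hartree, max |F_ov| < 1.5e-4,
and step norm < 1e-3, all strict.

## Worked example

Triplet H4 chain (UHF), surrogate optimizer with DIIS expansion:

```r
library(rvoscf)
sys <- build_toy_system(h_chain_geometry(4, 0.9), multiplicity = 3)
fit <- scf_optimize(hf_backend(sys), method = "sgek-diis")
fit
#> sgek-diis: converged in 7 iteration(s), final energy -1.9083383728
head(fit$trace[, c("iter", "energy", "g_max", "step_norm", "f_L", "K")])
#>   iter energy     g_max step_norm f_L  K
#> 1    1 -1.894 7.208e-02 3.000e-01   1 NA
#> 2    2 -1.908 2.411e-02 9.688e-02   1  4
#> 3    3 -1.908 3.123e-03 2.374e-02   1  6
#> 4    4 -1.908 6.940e-04 5.474e-03   1  8
#> 5    5 -1.908 1.387e-04 1.236e-03   1 10
#> 6    6 -1.908 9.513e-06 2.990e-04   1 10
```

`energy` is the UHF total energy in hartree after each Fock build,
`g_max` the largest occupied–virtual Fock element (the gradient metric),
`K` the dimension of the compressed subspace, and `f_L` the loosening
factor (1 throughout: no flat-region stalling here).  The r-GDIIS
baseline converges to the same minimum (energy difference < 1e-8,
occupied-space overlap 1):

```r
scf_optimize(hf_backend(sys), method = "rgdiis")
#> rgdiis: converged in 7 iteration(s), final energy -1.9083383728
```

The command-line wrapper lives at `inst/cli/rvoscf`
(`system.file("cli/rvoscf", package = "rvoscf")`):

```sh
rvoscf run --system h2.xyz --method sgek-diis --out traces/
rvoscf compare --system h2.xyz
rvoscf demo-fig1          # slope-surface undershoot mitigation demo
rvoscf selftest
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch: it builds the five toy fixtures (H2, HeH+, H4 singlet, H3
doublet, H4 triplet), optimizes each with r-GDIIS, S-GEK(DIIS)/RVO and
S-GEK(BFGS)/RVO, prints the cross-method comparison table (convergence,
iteration counts, energies, same-minimum flags), runs the flat-slope
mitigation scenario, and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/matern.R`, `R/gek.R` — Matérn 5/2 kernel with derivatives; the GEK
  surrogate (`gek()`, `predict()`, `variance_far_field()`).
* `R/subspace.R` — subspace assembly, Gram–Schmidt, Hessian projection,
  r-GDIIS/BFGS expansion directions.
* `R/kappa.R` — blocked matrix exponential, SVD rebase, gradient
  transport, occupied-space overlap.
* `R/hf.R`, `R/backends.R`, `R/xyz.R` — toy HF engine with a
  determinant-expansion oracle, backend contract, analytic surfaces,
  XYZ I/O and fixture geometries.
* `R/driver.R` — `scf_optimize()` / `scf_control()`, RS-RFO
  microiterations, undershoot mitigation, r-GDIIS baseline.
* `R/cli.R` — `scf_run()`, `scf_compare()`, `rvoscf_main()`.
* `vignettes/sgek-rvo-methods.Rmd` — the methods vignette: model
  assumptions, conventions, tunables, limitations.
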