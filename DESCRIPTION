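Package: rvoscf
Title: Restricted-Variance Surrogate Optimization for SCF Orbitals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Self-consistent-field (SCF) orbital optimization driven by a
    gradient-enhanced Kriging (GEK) surrogate model on a compressed subspace
    with restricted-variance steps (S-GEK/RVO).  The subspace is spanned by
    iteration history plus one cheap expansion direction (r-GDIIS or BFGS);
    steps are found by restricted-step rational-function (RS-RFO)
    microiterations on the surrogate and limited by its predicted variance.
    Orbital rotations use the exponential parametrization, with exact
    rebasing of coordinates via SVD retraction and gradient parallel
    transport by a commutator series or a closed sinc formula.  Includes a
    systematic-undershoot mitigation for flat sloped regions, a minimal
    Hartree-Fock backend for H/He systems with s-type Gaussian bases,
    analytic test surfaces, an r-GDIIS baseline optimizer, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
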