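Package: mwdmrg
Title: Wavefunction Optimization with Multiwavelets and DMRG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-consistent orbital optimization at the complete-basis-set
    limit. Molecular orbitals are represented as adaptive multiwavelet
    (multiresolution analysis) functions on a cubic domain; the correlated
    ground-state energy and its gradients with respect to the one- and
    two-electron integrals are obtained from a density matrix
    renormalization group (DMRG) solve of the second-quantized chemical
    Hamiltonian.  Orbitals are updated by inverting the shifted kinetic
    operator with a bound-state Helmholtz Green's function, rotated to the
    natural-orbital (gradient-diagonal) basis, and Loewdin-orthonormalized
    each iteration.  Includes separated (sum-of-Gaussians) Poisson and
    Helmholtz convolution operators in non-standard form, FCIDUMP
    import/export, a determinant-space full configuration interaction
    oracle, and an integral-equation Hartree-Fock reference solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
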