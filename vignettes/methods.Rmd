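---
title: "Wavefunction optimization with multiwavelets and DMRG: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavefunction optimization with multiwavelets and DMRG: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Correlated electronic-structure methods built on tensor networks — the
density matrix renormalization group (DMRG) in particular — converge
rapidly to the full configuration interaction (FCI) limit in a *given*
orbital basis, but inherit that basis's error.  Gaussian atomic-orbital
bases converge slowly to the complete-basis-set (CBS) limit; plane waves
struggle with nuclear cusps.  `mwdmrg` removes the fixed basis
altogether: each of the `M` occupied-space orbitals is an adaptive
multiwavelet function, refined wherever the orbital has structure, with a
guaranteed representation precision `p`.  The orbitals themselves are
then optimized variationally, so the result approaches the CBS limit of
an `M`-orbital correlated wavefunction — typically well below an FCI
energy computed in an atomic-orbital basis of comparable size.

## The model and one optimization cycle

For real orbitals $\{\phi_m\}_{m=1}^M$ the second-quantized Hamiltonian
is
$$\hat H = \sum_{ij\sigma} h_{ij}\, a^\dagger_{i\sigma} a_{j\sigma}
  + \tfrac12 \sum_{ijkl\sigma\tau} g_{ijkl}\,
    a^\dagger_{i\sigma} a^\dagger_{j\tau} a_{l\tau} a_{k\sigma},$$
with $h_{ij}$ the kinetic-plus-nuclear one-electron integrals and
$g_{ijkl} = (ik|jl)$ the two-electron Coulomb integrals.  One cycle of
`mw_optimize()` performs:

1. **Integrals.**  Kinetic energies through weak first derivatives
   ($T_{ij} = \tfrac12\sum_{d}\langle\partial_d\phi_i,
   \partial_d\phi_j\rangle$), nuclear attraction from a smoothed Coulomb
   potential, and two-electron integrals through pair potentials
   $\hat g_{jl} = \int \phi_j(r')\phi_l(r')/|r-r'|\,dr'$ obtained by
   Poisson convolution.
2. **Ground state.**  A two-site DMRG solve of $\hat H$ on $M$
   spatial-orbital sites (local dimension 4) gives the energy $E$ and a
   matrix product state.
3. **Gradients.**  The derivatives of $E$ with respect to the integrals
   are read off the converged network: $\partial E/\partial h_{ij} =
   \gamma_{ij}$ (the spin-free 1-RDM) and, elementwise, the spin-free
   2-RDM $\Gamma_{ijkl}$ for the two-body part.
4. **Multipliers and rotation.**  The orthonormality constraints enter
   through a symmetric multiplier matrix $\bar\varepsilon$; diagonalizing
   the symmetrized one-body gradient (the 1-RDM) rotates the set to
   natural orbitals with occupations $\Lambda_m$.
5. **Orbital update.**  Each rotated orbital is updated by inverting the
   shifted kinetic operator with a bound-state Helmholtz Green's
   function, $\phi_m' \leftarrow -2\,\hat G_{\mu_m}[\text{source}_m]$
   with $\mu_m = \sqrt{-2\,\varepsilon'_{mm}/\Lambda_m}$; the source
   collects the nuclear potential term, the two-body pair-potential
   forces, and the off-diagonal multiplier couplings.
6. **Löwdin orthonormalization** of the updated set, and back to step 1
   until the total energy changes by less than `delta`.

### The factor convention for the two-body gradient

With $E = \sum h\gamma + \tfrac12\sum g\,\Gamma$, the literal derivative
of $E$ with respect to one (independent) two-body coefficient is
$\tfrac12\Gamma_{ijkl}$, not $\Gamma_{ijkl}$.  `extract_gradients()`
reports `dE_dg` on the $\Gamma$ scale because that is the scale on which
the trace rules ($\mathrm{tr}\,\gamma = N$, partial traces, energy
reconstruction) take their standard forms; `symmetrize_gradients()` then
converts to the true per-coefficient derivative (`dE2 = sym(Gamma)/2`)
before the multipliers and the update source are formed.  The convention
is pinned down by the determinant limit: for a doubly occupied single
orbital the update equation must reduce exactly to the Hartree–Fock fixed
point $(\hat h + \hat J)\phi = (h_{11} + g_{1111})\phi$, which it does
with this choice and does not with the doubled two-body force that a
naive $\Gamma$-scale substitution produces.  The package's independent
integral-equation Hartree–Fock solver (`mw_hf()`) verifies this
equivalence to $10^{-5}$ Ha in the test suite.

## The multiwavelet layer

Functions live on the cube $[-L, L]^3$ (default `L = 32` bohr, molecule
centered; all represented functions are assumed negligible at the
boundary).  The scaling space of order `k` uses the `k+1` normalized
Legendre polynomials per dimension on each dyadic box; a node of the
adaptive tree stores a $(k+1)^3$ coefficient block.  A node is refined
while its wavelet-block norm exceeds $p\,\|f\|\,2^{-n/2}$ at scale $n$,
estimated from a one-level-deeper quadrature projection — so the
discarded detail is bounded by the thresholding contract.  Defaults
mirror the production settings `k = 9`, `p = 1e-5`; the test suite uses
reduced orders and precisions chosen so each check still exercises the
full code path.

Numerical choices worth knowing:

* **Differentiation** uses the central (averaged-flux) first-derivative
  stencil on the leaf grid, with one-sided fluxes at the domain faces.
  Because the stencil error is one order lower than the projection
  error, kinetic matrix elements are evaluated on a once-refined copy of
  the tree (an exact two-scale descent), which pushes the derivative
  error well below `p`.  Kinetic energies therefore come from
  $\tfrac12\langle\nabla\phi_i,\nabla\phi_j\rangle$; no Laplacian is
  ever applied.
* **Nuclear potential.**  The attractive $-\sum_a Z_a/|r-R_a|$ is
  represented in the standard regularized form
  $-Z\,u(r/c)/c$ with $c_a = (0.00435\,p/Z_a^5)^{1/3}$, so the induced
  energy error per nucleus is of order `p`; the potential is projected at
  `p/10`.  A bare $1/r$ would force unbounded refinement at the cusp.
* **Separated kernels.**  The Poisson and bound-state Helmholtz kernels
  are expanded as $\sum_t c_t e^{-a_t r^2}$ by trapezoid discretization
  of their integral representations.  Accuracy is enforced strictly
  (relative) where $\mu r \le 5$ and relative to the Poisson kernel
  $1/(4\pi r)$ beyond, which bounds the absolute convolution error by
  `eps` times a Coulomb integral of the source — the short range is what
  the orbital updates actually probe, and demanding relative accuracy
  where the kernel is below $10^{-26}$ of its peak would inflate the
  expansion for no benefit.
* **Non-standard-form application.**  Each Gaussian term is separable,
  so a 3D operator block is a tensor product of 1D blocks.  At every
  scale the operator acts on a node's joint child-representation block
  and the part already representable at the parent scale is subtracted;
  the telescoped sum over scales plus the full coarsest-scale term
  reconstructs the convolution while touching only a narrow displacement
  band per scale.  Bands and per-node contributions are screened at a
  small fraction of the target precision (defaults `0.02 * prec`
  relative, `0.08 * prec * |f|` absolute, adjustable through
  `options(mwdmrg.conv_cuts = )`).
* **Operator reuse.**  The Helmholtz exponent changes every iteration,
  so kernel coefficients are snapped onto a 2.5 % logarithmic grid and
  the (exactly compensated) residual is moved into the update source —
  the same level-shift mechanism that handles a non-negative
  coefficient, where the floor value is $-0.05$ Ha.

## The tensor-network layer

The Hamiltonian MPO is assembled from elementary operator strings
(Jordan–Wigner parities inside the site-major, up-before-down mode
order) and reduced to its minimal bond dimension by exact rank
revelation at every bond: string columns are compressed from both chain
ends toward the middle through balanced Gram factorizations with
tolerance far below the rounding noise, so the construction is a
deduplication, not an approximation — the dense contraction of the MPO
agrees with the brute-force operator sum to $10^{-12}$ in the tests.

Sector selection uses a quadratic penalty
$w[(\hat N - N)^2 + (\hat S_z - S_z)^2]$ (default `w = 25` Ha) added to
the MPO.  The penalty commutes with $\hat H$, so in-sector eigenstates
are unchanged; together with a random in-sector initial state (a seeded
superposition of sector determinants, default seed 0) it lets the
two-site sweeps run without quantum-number bookkeeping while conserving
$\langle\hat N\rangle$ and $\langle\hat S_z\rangle$ to $10^{-10}$, which
the converged state is checked against.  The bond-dimension schedule
defaults to 16, 32, 64 with two sweeps each, discarded-weight cutoff
$10^{-13}$, and sweep-energy tolerance $10^{-9}$; for the instance sizes
the package targets ($M \le 6$ in the oracle-checked tests) the final
bond dimension saturates the sector and the energies match dense FCI at
the $10^{-10}$ level.

Gradients are extracted twice, by construction: the default route
evaluates the spin-free RDMs as transfer-matrix correlation functions of
the left-canonical state (with cached right environments, so a string
costs only its spanned sites); the cross-check route contracts the
energy network with one coefficient's operator family isolated — the
network with that coefficient removed.  Both routes agree to $10^{-10}$
in the tests, and either reconstructs the sweep energy through
$E = \sum h\gamma + \tfrac12\sum g\Gamma$.

## Design decisions in the open

* **Natural-orbital ordering and signs.**  $\Lambda$ is sorted
  descending (occupation-like); eigenvector signs are fixed by making
  each column's largest-magnitude component positive.  Degeneracies in
  $\Lambda$ are rare for the systems exercised here and are left to the
  deterministic eigensolver ordering; an occupation numerically at zero
  aborts with advice to reduce `M`, since the corresponding Helmholtz
  exponent is undefined.
* **No convergence acceleration.**  The loop is plain fixed-point
  iteration plus Löwdin orthonormalization; mixing/DIIS-style
  acceleration is deliberately deferred.  Observed convergence on the
  shipped systems is linear with ratio about 0.25 per iteration.
* **Initial guess.**  One normalized Gaussian per nucleus with exponent
  $0.2709\,Z^2$ (the best single-Gaussian fit to a hydrogenic 1s), then
  a fixed deterministic sequence of polynomial-times-Gaussian shells at
  the molecular centroid until `M` functions, Löwdin-orthonormalized.
  The optimizer is insensitive to this choice in practice; it only sets
  the starting point of the monotone descent.
* **Integral refresh.**  Integrals and the DMRG solve are refreshed
  every iteration — a single self-consistent loop with no frozen-integral
  inner iterations.
* **Orthonormalization placement.**  The updated set is
  Löwdin-orthonormalized before the next iteration's integrals and
  energy; the convergence test compares successive post-orthonormalization
  energies.
* **Command-line surface.**  `inst/exec/mwdmrg` exposes `run`, `dmrg`
  (FCIDUMP in, energy and gradients out), `scan` (diatomic dissociation
  curves) and `check` over a flat `key: value` configuration format; all
  of it is a thin layer over the exported functions.

## What the shipped test systems do and do not show

The oracle-checked random integral sets (4–6 orbitals, 2–6 electrons,
positive-semidefinite two-body tensors with the full 8-fold symmetry)
exercise the tensor-network machinery across sectors, including
open-shell ones, at couplings stronger than typical molecular integrals;
they validate energies and gradients against dense determinant-space
diagonalization to $10^{-8}$.  The end-to-end fixtures are small by
design: hydrogen (exact answer $-0.5$ Ha), helium and dihydrogen at the
determinant limit (against the independent Hartree–Fock solver), and
helium/dihydrogen with `M = 2` for the correlated loop, where every
iteration's Helmholtz kernel coefficients are confirmed negative — on
these systems the bound-state form always held without the fallback.
Larger molecules (more orbitals, heavier nuclei) run through exactly the
same code paths but need hours rather than minutes; nothing in the small
fixtures probes deep-core smoothing for high `Z`, near-degenerate
natural-orbital occupations, or dissociation-range multireference
character beyond what `M = 2` dihydrogen exposes.  Energy improvements
over fixed-basis FCI grow with `M` and tighten with `p`; at matched `M`
the optimized energies here sit below the single-determinant limit by
the expected 2-orbital correlation energies (about 6 mHa for He, 18 mHa
for H$_2$ at 1.4 bohr at the reduced test precisions).

Problem sizes in `scripts/acceptance.R` — ten random oracle instances,
production-precision kernel checks, hydrogen at `k = 7, p = 1e-5`,
helium/dihydrogen at `k = 6, p = 1e-4`, and the `M = 2` helium fixture
at `k = 5, p = 1e-3` — are the package's chosen desk-scale
demonstration set; all of its numbers are recomputed at run time.

## Known limitations

* Spatial-orbital sites without spin adaptation; excited states are out
  of scope.
* The orbital count is the practical cost driver: two-electron integrals
  need $O(M^2)$ Poisson convolutions per iteration and the update source
  $O(M^3)$ tree products.
* Orbital localization and second-order (Newton) optimization are not
  implemented; convergence is first-order.
* Periodic systems, pseudopotentials, and complex orbitals are not
  supported.
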