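---
title: "Correction-vector RAS simulation of L-edge XAS and 2p3d RIXS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correction-vector RAS simulation of L-edge XAS and 2p3d RIXS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `rascv`, in the spirit of a methods section: what is computed,
under which assumptions, which knobs matter, and what the test suite
does and does not demonstrate.

## The Hamiltonian and its representation

The electronic structure is described in a space of spatial active
orbitals carrying a label, a RAS partition tag (`RAS1`, `RAS1P`,
`RAS2`) and a shell tag (`core`, `valence`, `ligand`).  The Hamiltonian
contains the spin-free one- and two-electron terms (chemist-notation
integrals `(ij|kl)` with 8-fold permutational symmetry) plus a one-body
mean-field Breit–Pauli spin–orbit term: three Cartesian matrices, purely
imaginary and antisymmetric in a real orbital basis, contracted with the
Cartesian triplet operators

$$\hat T^x_{ij} = \tfrac12 (a^\dagger_{i\alpha} a_{j\beta} +
  a^\dagger_{i\beta} a_{j\alpha}), \quad
  \hat T^y_{ij} = -\tfrac{i}{2} (a^\dagger_{i\alpha} a_{j\beta} -
  a^\dagger_{i\beta} a_{j\alpha}), \quad
  \hat T^z_{ij} = \tfrac12 (a^\dagger_{i\alpha} a_{j\alpha} -
  a^\dagger_{i\beta} a_{j\beta}).$$

All internal energies are Hartree; every user-facing energy (grids,
broadenings, model parameters, spectra axes) is eV, with the conversion
constant fixed at 27.211386245988.

The determinant basis realizes the RAS occupation-number ansatz exactly:
all determinants with the requested electron count whose per-partition
hole counts respect the limits (conventionally: at most one 2p core
hole, at most one hole in the optional sigma-bonding partition, valence
unrestricted).  Spin orbitals are ordered alpha block then beta block
(`|D> = a+_{p1} ... a+_{pN}|vac>`, ascending), and the canonical
determinant order is lexicographic on the bitstring with the alpha block
most significant — a total, hash-free order, so indices and output files
are reproducible across runs.  Because the spin–orbit term changes
$M_s$ by $\pm 1$, the space is not restricted to a single $M_s$ sector;
an optional filter exists for spin-free runs.  The Hamiltonian matrix is
built once per (integral set, space) pair by Slater–Condon rules in
compiled code and cached as a sparse operator; excitations that violate
the hole limits are dropped, which *is* the projected RAS Hamiltonian.
The whole construction is verified against an independent brute-force
second-quantization engine (operator strings composed over the full
Fock sector, then projected) in the test suite.

## Spectra from correction vectors

With $|X_\lambda\rangle = \hat\mu_\lambda |\Psi_0\rangle$, the XAS
spectral function at incident energy $\omega$ is
$-\tfrac{1}{\pi}\sum_\lambda \mathrm{Im}\,\langle X_\lambda |
A_\lambda(\omega)\rangle$ with
$(E_0 + \omega + i\eta - \hat H)\,|A_\lambda(\omega)\rangle =
|X_\lambda\rangle$.  RIXS fixes $\omega_{ex}$ (by default the maximum of
the L3 band), forms $\hat\mu_\rho |A_\lambda(\omega_{ex})\rangle$, and
applies a second resolvent at the energy loss with broadening $\eta'$;
only the resonant term is computed, the Cartesian pairs
$(\rho, \lambda)$ are summed with no additional interference structure,
and the overall prefactor is not claimed (intensities are relative; the
`normalize_spectrum()` helper implements the usual
window-maximum-to-a-constant conventions).  Defaults
$\eta = 0.3$ eV and $\eta' = 0.1$ eV are the customary L-edge
broadenings; default grid steps (0.02 eV incident, 0.01 eV loss) resolve
the $\eta'$ features.

**Solver.**  The shifted systems are solved by a multi-shift Lanczos
method: a single Hermitian Krylov space built from each right-hand side
serves *every* shift, since $(z - \hat H)$ restricted to the space is a
shifted real-symmetric tridiagonal, solved per shift by a vectorized
Thomas sweep.  The residual of the full-space system is available in
closed form, $\|(z-\hat H)C_m - X\| = \|X\|\,\beta_m |y_m(z)|$, so the
basis is grown (with full reorthogonalization) until the worst shift
meets the tolerance; exhausting the space makes the solve exact.  This
replaces a per-shift preconditioned Krylov solve, which meets the same
residual contract but costs a factor of the grid size more on dense
frequency grids; `shifted_solve()` still exposes the single-shift
interface with an explicit verified residual.  Two identities make the
downstream analyses numerically exact rather than tolerance-limited:
within the Krylov approximation, $-\mathrm{Im}\langle X|C\rangle =
\eta\langle C|C\rangle$ holds identically, and the adjoint resolvent on
the same basis is the conjugate-shift tridiagonal solve.

**Oracle.**  `sos_xas()`/`sos_rixs()` evaluate the same quantities by
full diagonalization (dense cap 2000 determinants by default, a desk-scale
budget) and explicit sums over eigenstates.  Correction-vector and
sum-over-states spectra agree pointwise to better than $10^{-8}$
relative on every fixture; this is asserted in the acceptance tests at
solver tolerance $10^{-11}$.

## Ground states and degenerate manifolds

The ground state is found by a block Davidson iteration in complex
arithmetic with deterministic start vectors: unit determinants of lowest
diagonal energy, spread across $M_s$ sectors, plus a few dense
fixed-pattern auxiliary vectors.  The auxiliary vectors matter: a unit
determinant can be *exactly* orthogonal to part of a degenerate ground
manifold protected by hidden model symmetries, and a Krylov iteration
can never leave an invariant subspace.  After convergence the solver
runs verification rounds that inject fresh unit vectors and resume until
the spectrum is stable.  Residual tolerance defaults to $10^{-9}$;
requesting much tighter tolerances runs into the Gram–Schmidt
reorthogonalization floor and is not useful, since eigenvalue errors
scale as the residual squared over the gap.

All eigenvectors within `degeneracy_tol` (default $10^{-6}$ Hartree) of
the lowest eigenvalue form the ground manifold, and every spectrum is
averaged uniformly over it.  This removes any dependence on the
arbitrary choice of basis within a Kramers doublet or an orbitally
degenerate multiplet.  Averaging (rather than picking one state) is this
package's documented choice; a single-state calculation can be forced by
passing a truncated `ground_state` object.

## Deconvolution

**Particle–hole.**  The deconvolution basis defaults to the natural
orbitals of the (manifold-averaged) one-particle density matrix,
diagonalized within each shell block so that core/valence/ligand labels
survive; occupations are sorted descending and each orbital's phase is
fixed by making its largest coefficient real positive.  The dipole
operator is then expanded into its elementary one-body pieces
$d_{pq} \tilde E_{pq}$, one correction vector is solved per piece with
right-hand side $\tilde E_{pq}|\Psi_0\rangle$, and each component
spectrum is the dipole-weighted overlap with the full dipole-excited
bra.  Two readings of the component equation circulate (weight on the
right-hand side versus weight in the assembly); they differ only by a
linear re-weighting, and the implemented form is the one that satisfies
the sum rule $\sum_{ia} S^{(ph)}_{ia} = S$ *by construction* — the total
is assembled from the same component vectors, so the sum rule holds to
rounding, independent of solver convergence.  Components are signed
(interference between pieces is real); only the total is guaranteed
nonnegative.

For RIXS both dipole steps are expanded, and the pieces are grouped by
the net particle–hole character of the final state.  The classification
is by shell, not by orbital index: an absorption that annihilates *any*
core orbital and an emission that refills *any* core orbital is a net
valence$\to$valence transition, because the 2p spin–orbit coupling
migrates the core hole between the 2p orbitals inside the intermediate
manifold and those paths are physically the same final-state excitation.
Emission that exactly reverses the absorption is the elastic channel.
The reported valence-to-valence fraction counts the off-diagonal valence
keys plus the elastic (valence-diagonal) channel over the integrated
total.  `average_ph()` averages components over hole/particle orbital
sets, $\bar\sigma_{H\to P} = \frac{1}{N_H N_P}\sum_{i\in H, a\in P}
\sigma^{(ph)}_{ia}$.

**Spin.**  Channels are
$S^{(s)}_S = (\eta/\pi)\sum_\lambda \|P_S A_\lambda\|^2$ with the Löwdin
product projector applied through repeated $\hat S^2$ action
($\hat S^2 = S_-S_+ + S_z(S_z{+}1)$ on the sparse operators), with the
excluded spins taken in descending order to limit intermediate growth.
Because the projectors resolve the identity over the attainable spins,
the channels sum to the total exactly.  The projected-norm form is
chosen over the mixed-overlap form $-\tfrac1\pi\mathrm{Im}\langle X|P_S
A\rangle$ (which sums equally well) because it is nonnegative and reads
directly as the spin-$S$ content of the final states.  Integrated
channel percentages are trapezoidal integrals over the computed grid
divided by the integrated total; percentages therefore refer to the
plotted window, which should cover the whole edge.

## The ligand-field generator

`build_model()` stands in for ab initio integrals so that everything
builds and tests offline.  It emulates the 2p→3d physics of a
first-row transition-metal L edge:

* core p shell at `core_energy` (default −710 eV, placing the edge near
  the iron L3 region) with spin–orbit term $\zeta\, \mathbf{L}\cdot
  \mathbf{S}$, $\zeta_{2p} = 8.2$ eV by default (the iron 2p value);
* valence d shell with per-orbital crystal-field energies (the standard
  fixtures use a weak tetrahedral-like splitting, 10Dq = 0.65 eV, e
  below t2);
* two-electron structure: direct $U = 4$ eV between all valence pairs,
  exchange $J_H = 0.9$ eV (the full 8-fold-symmetric orbit of each
  exchange integral is populated, so Hund's coupling and pair hopping
  are both present), and a core–valence direct term (1.5 eV) that makes
  core-hole states feel the valence occupation;
* dipole matrices coupling core↔valence pairs only, with the exact
  real-orbital $\langle p_a | r_c | d_b\rangle$ angular factors
  (hardcoded from a symbolic derivation) times a radial strength;
* optional filled sigma-type ligand orbitals (default energy −3 eV,
  hopping 1 eV onto the d shell) for charge-transfer correlation,
  tagged `RAS1P`.

These defaults were chosen once from standard iron L-edge values and
define the study conditions of the test suite and acceptance script.
The angular-momentum matrices for the real p and d bases are likewise
hardcoded from a symbolic derivation.  What the generator does *not*
emulate: ligand-metal orbital mixing in the dipole matrices, radial
integral variation across the shell, charge-transfer multiplet
structure beyond one-electron hopping, and any molecule-specific energy
scale.  Passing tests on these models therefore demonstrates the
correctness of the machinery (operator algebra, solvers, sum rules,
selection rules, degeneracies), not agreement with any measured
spectrum.

Ab initio integrals enter through the extended FCIDUMP dialect (the
standard header and `value i j k l` body, plus `&SOC x|y|z` sections
carrying the imaginary parts of the spin–orbit matrices and
`&DIP x|y|z` sections for the dipoles, with orbital metadata in a YAML
sidecar) or through `from_adapter()`, which selects active orbitals from
external natural-orbital occupations inside a configurable window
(default $0.02 < n < 1.98$), optionally localizes them by Pipek-style
Jacobi sweeps over a user-supplied basis-to-atom map, and transforms the
full-space integrals.  The occupation window and the localization
scheme are configurable defaults of this package, not prescriptions;
spectra totals are invariant to any unitary rotation confined to the
active space, so localization only affects the interpretability of
particle–hole labels.

## Numerical conventions and degenerate inputs

* `select_omega_ex()` breaks ties toward lower energy (the first grid
  maximum).
* Natural-orbital degeneracies: dominant-label duplicates are suffixed
  (`#1`, `#2`, ...) so component keys stay unique.
* Zero right-hand sides short-circuit to zero correction vectors; zero
  dipole matrices yield identically zero spectra.
* Spectra are reported per eV; the two-level model then peaks exactly at
  $m^2/(\pi\eta)$, which the tests assert to 0.1% on a grid step of
  $\eta/20$.
* The default pipeline contains no randomness; the run configuration's
  seed exists for optional randomized starts and is recorded in the run
  report.

## Problem sizes

The shipped fixtures span the RAS spaces used throughout the tests and
the acceptance script: a 6-determinant single-hole p shell, a
61-determinant one-particle edge model, a 135-determinant reduced
multiplet model, the 930- and 1512-determinant 2p$^6$3d$^6$ and
2p$^6$3d$^5$ models, and a 2490-determinant sigma-extended model.  Dense
oracle comparisons are run up to that largest fixture; the
correction-vector path itself has no dense step and scales with the
sparse matrix–vector cost.

## Known limitations

* Desk scale by design: direct determinant CI with dense oracle checks;
  no tensor-network compression, so spaces beyond ~$10^5$ determinants
  are out of intended scope.
* Resonant-only RIXS; no absorption–emission interference terms, no
  non-resonant scattering, no temperature/Boltzmann ensemble beyond the
  uniform degenerate-manifold average.
* Relative intensities only; no absolute cross-section prefactor.
* The built-in models carry no LMCT states unless ligand orbitals are
  added explicitly, so high-loss charge-transfer features are absent by
  construction.
* Complex (spin–orbit-adapted) orbital rotations of the two-electron
  tensor are not supported; deconvolution bases may be complex because
  only one-body quantities are rotated.
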