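# rascv

Correction-vector restricted-active-space simulation of L2,3-edge X-ray
absorption (XAS) and 2p3d resonant inelastic X-ray scattering (RIXS)
spectra of open-shell transition-metal systems, in R.

## The problem and the method

L-edge XAS probes the dipole-allowed 2p -> 3d excitation of a transition
metal; 2p3d RIXS absorbs into the same core-excited manifold and emits,
leaving a valence (d-d or charge-transfer) excited final state.  Both
spectra are shaped by ligand fields, multiplet (Hund) couplings and the
strong 2p spin-orbit interaction that splits the core hole into j = 3/2
(L3) and j = 1/2 (L2) components.  A faithful simulation therefore needs a
correlated many-electron treatment with spin-orbit coupling.

`rascv` models the electronic structure with a restricted-active-space
(RAS) configuration-interaction ansatz: the active orbitals are
partitioned into a core 2p set with at most one hole, an optional filled
sigma-bonding set with at most one hole, and an unrestricted valence 3d
set.  The Hamiltonian is

    H = sum_ij h_ij E_ij + 1/2 sum_ijkl (ij|kl) (E_ij E_kl - d_jk E_il)
        + sum_ij h^BP_ij . T_ij

with spin-summed excitation operators `E_ij`, chemist-notation
two-electron integrals `(ij|kl)`, and the mean-field Breit-Pauli
spin-orbit matrices `h^BP` (purely imaginary, antisymmetric, one per
Cartesian component) contracted against the Cartesian triplet operators
`T^{x,y,z}_ij`.

Spectra are computed without ever enumerating excited states.  With
`|X> = mu_lambda |Psi0>`, the XAS spectral function is

    S(w)  = -(1/pi) sum_lambda Im <X_lambda| A_lambda(w)>,
    (E0 + w + i eta - H) |A_lambda(w)> = |X_lambda>,

and the resonant RIXS cross section applies a second resolvent at the
energy loss to `mu_rho |A_lambda>`.  These correction-vector (CV) linear
systems are solved by a multi-shift Lanczos method: one Hermitian Krylov
space per right-hand side serves every frequency on the grid, with exact
per-shift residuals.  A dense sum-over-states (SOS) reference path is
built in and agrees with the CV path to machine precision on every model;
this equivalence is the package's central correctness property.

Two deconvolution analyses interpret the spectra and obey exact sum
rules (components add up to the total pointwise):

* **particle-hole**: the dipole excitation is expanded into elementary
  one-body components in the natural-orbital basis of the ground state,
  attributing XAS intensity to core -> valence pairs and RIXS intensity
  to net valence -> valence transitions (including the core-hole
  migration paths opened by 2p spin-orbit coupling);
* **spin**: Lowdin product projectors
  `P_S = prod_{S' != S} (S^2 - S'(S'+1)) / (S(S+1) - S'(S'+1))`
  resolve the correction vectors into total-spin channels, separating
  spin-allowed from spin-flip (Delta S != 0) intensity.

A ligand-field model generator (`build_model()` /
`ligand_field_params()`) synthesizes 2p/3d multiplet integral sets --
crystal field, Hund exchange, core-valence interaction, 2p spin-orbit
constant, exact real-orbital p -> d dipole angular factors -- so that the
whole machinery builds and tests without external data.  Ab initio
integrals enter through an extended FCIDUMP dialect
(`read_integrals()` / `write_integrals()`) or the natural-orbital
adapter (`from_adapter()`).

## Worked example

A ferrous-like 2p6 3d6 high-spin model (tetrahedral crystal field
10Dq = 0.65 eV, U = 4 eV, J_H = 0.9 eV, zeta_2p = 8.2 eV, edge at
710 eV):

```r
library(rascv)

fx <- model_fixture("ferrous")
fx$space
#> <determinant_space> 930 determinants, 12 electrons in 8 orbitals

gs <- ground_state(fx$ints, fx$space)
gs
#> <ground_state> E0 = -152.621772462 Ha (-4153.05 eV), manifold size 10

grid <- frequency_grid_seq(715, 748, 0.05, eta = 0.3)
xas  <- xas_spectrum(fx$ints, gs, grid)
select_omega_ex(xas, c(715, 734))
#> [1] 728.15

sd <- spin_decompose(fx$ints, gs, grid)
round(sd$meta$percent, 1)
#> spin:S=0 spin:S=1 spin:S=2
#>      0.0     22.4     77.6
sumrule_check(sd)$max_rel_dev
#> [1] 2.470292e-16
```

The ground manifold is the (quasi-degenerate) S = 2 high-spin multiplet;
the L3 band peaks at 728.15 eV; 77.6% of the integrated XAS intensity is
spin-allowed (Delta S = 0) and 22.4% is spin-flip intensity enabled by the
2p spin-orbit coupling, and the spin channels reproduce the total
spectrum to 2e-16.

RIXS follows the same pattern:

```r
loss <- frequency_grid_seq(-0.5, 6, 0.01, eta = 0.3, eta_prime = 0.1)
rixs <- rixs_spectrum(fx$ints, gs, 728.15, loss)
ph   <- ph_decompose_rixs(fx$ints, gs, 728.15, loss)
avg  <- average_ph(ph, H = "3d_z2", P = c("3d_xy", "3d_yz", "3d_xz"))
```

A thin command-line driver over the same functions lives in
`inst/cli/rascv` (subcommands `xas`, `rixs`, `deconvolve`,
`oracle-compare`, `make-model`, `make-fixtures`, `run`).

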