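# Correction-vector spectra.  The XAS spectral function at incident energy
# w is -(1/pi) Im sum_l <mu_l Psi0| (E0 + w - H + i eta)^{-1} |mu_l Psi0>,
# evaluated by solving the shifted linear systems; the RIXS cross section
# applies a second resolvent at the loss energy to mu_r |A_l>.  Totals are
# averaged uniformly over the ground manifold and reported per eV.

.EV <- 27.211386245988

#' XAS spectrum from correction vectors
#'
#' For every incident energy on the grid and every Cartesian dipole
#' component, solves the correction-vector equation
#' `(E0 + w + i eta - H) |A_l(w)> = mu_l |Psi0>` and accumulates the
#' spectral function, averaged over the ground manifold.  One Krylov space
#' per right-hand side serves the whole grid.
#'
#' @param ints an [integral_set()].
#' @param gs a [ground_state()].
#' @param grid a [frequency_grid()] of incident energies (eV).
#' @param tol relative residual tolerance of the correction-vector solves.
#' @param m_max optional cap on the Krylov dimension.
#' @return an `xray_spectrum` (intensity per eV).
#' @export
xas_spectrum <- function(ints, gs, grid, tol = 1e-9, m_max = NULL) {
  space <- gs$states[[1]]$space
  op <- hamiltonian_operator(ints, space)
  eta_ha <- ev_to_hartree(grid$eta)
  zs <- gs$energy + ev_to_hartree(grid$values) + 1i * eta_ha
  g <- length(gs$states)
  total <- numeric(length(zs))
  for (st in gs$states) {
    for (comp in c("x", "y", "z")) {
      X <- op_apply(dipole_operator(ints, space, comp), st$amp)
      kr <- krylov_resolvent(op, X, zs, tol = tol, m_max = m_max)
      total <- total - Im(kr$scalars) / (pi * .EV * g)
    }
  }
  new_spectrum(grid, total,
               meta = list(kind = "xas", manifold = g,
                           e0_hartree = gs$energy))
}

#' RIXS spectrum from correction vectors
#'
#' Fixes the incident energy `omega_ex` (typically the L3 maximum from
#' [select_omega_ex()]), solves for the absorption correction vectors
#' `A_l(omega_ex)`, then for every Cartesian pair `(r, l)` and every energy
#' loss on the grid solves the emission correction-vector equation
#' `(E0 + w_loss + i eta' - H) |B_rl> = mu_r |A_l>` and accumulates the
#' orientation-summed resonant cross section, averaged over the ground
#' manifold.  The x axis is energy loss `omega_ex - omega_em`.
#'
#' @param ints an [integral_set()].
#' @param gs a [ground_state()].
#' @param omega_ex incident energy (eV).
#' @param loss_grid a [frequency_grid()] of energy-loss values (eV); its
#'   `eta` broadens the absorption resolvent and `eta_prime` the loss
#'   resolvent.
#' @param tol relative residual tolerance.
#' @param m_max optional cap on the Krylov dimension.
#' @return an `xray_spectrum` on the loss axis (relative intensity).
#' @export
rixs_spectrum <- function(ints, gs, omega_ex, loss_grid, tol = 1e-9,
                          m_max = NULL) {
  space <- gs$states[[1]]$space
  op <- hamiltonian_operator(ints, space)
  eta_ha <- ev_to_hartree(loss_grid$eta)
  etap_ha <- ev_to_hartree(loss_grid$eta_prime)
  z_ex <- gs$energy + ev_to_hartree(omega_ex) + 1i * eta_ha
  zs_loss <- gs$energy + ev_to_hartree(loss_grid$values) + 1i * etap_ha
  g <- length(gs$states)
  total <- numeric(length(zs_loss))
  for (st in gs$states) {
    for (lam in c("x", "y", "z")) {
      X <- op_apply(dipole_operator(ints, space, lam), st$amp)
      krA <- krylov_resolvent(op, X, z_ex, tol = tol, m_max = m_max)
      A <- krv_vector(krA, 1L)
      for (rho in c("x", "y", "z")) {
        W <- op_apply(dipole_operator(ints, space, rho), A)
        krB <- krylov_resolvent(op, W, zs_loss, tol = tol, m_max = m_max)
        total <- total - Im(krB$scalars) / (pi * .EV * g)
      }
    }
  }
  new_spectrum(loss_grid, total,
               meta = list(kind = "rixs", omega_ex = omega_ex, manifold = g,
                           e0_hartree = gs$energy))
}
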