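# Dense sum-over-states reference spectra.  The Hamiltonian is fully
# diagonalized once (cached on the space) and the XAS/RIXS expressions are
# evaluated as explicit sums over eigenstates.  This is the verification
# oracle for the correction-vector path: both must agree pointwise.

#' Dense eigendecomposition of the RAS Hamiltonian
#'
#' Full diagonalization, cached on the determinant space.  Guarded by a
#' dimension cap to keep the oracle desk-scale.
#'
#' @param ints an [integral_set()].
#' @param space a [determinant_space()].
#' @param cap maximum space dimension accepted.
#' @return list with `values` (ascending) and `vectors`.
#' @export
dense_eigen <- function(ints, space, cap = 2000) {
  if (length(space$dets) > cap)
    stop("space dimension ", length(space$dets),
         " exceeds the dense oracle cap (", cap, ")")
  space_cache_get(space, paste0("eig_", ints$id), function() {
    H <- op_dense(hamiltonian_operator(ints, space))
    e <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
    ord <- order(e$values)
    list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
  })
}

#' Sum-over-states XAS spectrum (oracle)
#'
#' `S(w) = (1/pi) sum_{I,l} |<Psi_I|mu_l|Psi0>|^2 eta / ((E0+w-E_I)^2 +
#' eta^2)`, averaged over the ground manifold, by dense diagonalization.
#'
#' @param ints an [integral_set()].
#' @param space a [determinant_space()].
#' @param gs a [ground_state()] (the same manifold the CV path uses).
#' @param grid a [frequency_grid()].
#' @param cap dense-diagonalization dimension cap.
#' @return an `xray_spectrum`.
#' @export
sos_xas <- function(ints, space, gs, grid, cap = 2000) {
  e <- dense_eigen(ints, space, cap)
  eta_ha <- ev_to_hartree(grid$eta)
  w_ha <- ev_to_hartree(grid$values)
  g <- length(gs$states)
  total <- numeric(length(w_ha))
  for (st in gs$states) {
    for (comp in c("x", "y", "z")) {
      X <- op_apply(dipole_operator(ints, space, comp), st$amp)
      M <- Mod(Conj(t(e$vectors)) %*% X)^2  # |<I|mu|0>|^2
      for (j in seq_along(w_ha)) {
        d <- gs$energy + w_ha[j] - e$values
        total[j] <- total[j] +
          sum(M * eta_ha / (d^2 + eta_ha^2)) / (pi * .EV * g)
      }
    }
  }
  new_spectrum(grid, total, meta = list(kind = "xas_sos", manifold = g))
}

#' Sum-over-states RIXS spectrum (oracle)
#'
#' Resonant Kramers-Heisenberg double sum: intermediate states weighted by
#' `1/(E0 + w_ex - E_I + i eta)`, final states by the loss Lorentzian of
#' width `eta'`, with the same Cartesian orientation sum and ground-manifold
#' averaging as [rixs_spectrum()].
#'
#' @inheritParams sos_xas
#' @param omega_ex incident energy (eV).
#' @param loss_grid a [frequency_grid()] of energy losses.
#' @return an `xray_spectrum` on the loss axis.
#' @export
sos_rixs <- function(ints, space, gs, omega_ex, loss_grid, cap = 2000) {
  e <- dense_eigen(ints, space, cap)
  eta_ha <- ev_to_hartree(loss_grid$eta)
  etap_ha <- ev_to_hartree(loss_grid$eta_prime)
  loss_ha <- ev_to_hartree(loss_grid$values)
  g <- length(gs$states)
  total <- numeric(length(loss_ha))
  U <- e$vectors
  for (st in gs$states) {
    for (lam in c("x", "y", "z")) {
      X <- op_apply(dipole_operator(ints, space, lam), st$amp)
      Tlam <- as.vector(Conj(t(U)) %*% X)
      denom <- 1 / (gs$energy + ev_to_hartree(omega_ex) - e$values +
                      1i * eta_ha)
      A <- as.vector(U %*% (Tlam * denom))  # intermediate-resolvent state
      for (rho in c("x", "y", "z")) {
        W <- op_apply(dipole_operator(ints, space, rho), A)
        WF <- Mod(as.vector(Conj(t(U)) %*% W))^2
        for (j in seq_along(loss_ha)) {
          d <- gs$energy + loss_ha[j] - e$values
          total[j] <- total[j] +
            sum(WF * etap_ha / (d^2 + etap_ha^2)) / (pi * .EV * g)
        }
      }
    }
  }
  new_spectrum(loss_grid, total,
               meta = list(kind = "rixs_sos", omega_ex = omega_ex,
                           manifold = g))
}

#' Maximum pointwise deviation between two spectra
#'
#' Deviation relative to the maximum of the reference total; used to compare
#' the correction-vector and sum-over-states paths.
#'
#' @param a,b `xray_spectrum` objects on the same grid (`b` = reference).
#' @return maximum relative deviation (scalar).
#' @export
spectrum_deviation <- function(a, b) {
  if (length(a$total) != length(b$total) ||
      max(abs(a$grid$values - b$grid$values)) > 1e-12)
    stop("spectra are on different grids")
  max(abs(a$total - b$total)) / max(b$total, 1e-300)
}
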