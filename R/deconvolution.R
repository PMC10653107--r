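# Particle-hole and spin deconvolution of XAS/RIXS spectra.
#
# Particle-hole components: the dipole operator is expanded into its
# one-body pieces in a chosen (by default natural-orbital) basis,
# mu_l = sum_pq d^l_pq E_pq, a correction vector is solved for every
# elementary excitation E_pq |Psi0>, and the spectrum contribution of each
# piece is the dipole-weighted overlap with the full dipole-excited bra.
# Because the pieces sum linearly to the full right-hand side, the
# components sum to the total spectrum exactly (the Eq-25-type sum rule),
# independent of physical interpretation.
#
# Spin components: the Lowdin projector onto total spin S is applied to the
# correction vectors; the projectors resolve the identity over the
# attainable spins, so these components also sum to the total exactly.

#' Natural orbitals of the ground-state wave function
#'
#' Diagonalizes the (manifold-averaged) one-particle reduced density matrix
#' within each shell block (core/valence/ligand), so that shell labels stay
#' meaningful.  Occupations are sorted descending within each shell and the
#' phase of each orbital is fixed by making its largest coefficient real
#' and positive.
#'
#' @param gs a [ground_state()].
#' @param space_labels optional [orbital_space()] (defaults to the one the
#'   integral set carried, if present on the determinant space).
#' @return list with the unitary `C` (columns = natural orbitals in the
#'   input basis), `occupations`, and `labels`.
#' @export
natural_orbital_basis <- function(gs, space_labels = NULL) {
  space <- gs$states[[1]]$space
  n <- space$n_orb
  orb <- space_labels %||% space$space
  rdm <- matrix(0 + 0i, n, n)
  for (st in gs$states)
    rdm <- rdm + cpp_rdm1(space$dets, n, st$amp) / length(gs$states)
  rdm <- (rdm + Conj(t(rdm))) / 2
  C <- diag(1 + 0i, n)
  occ <- Re(diag(rdm))
  shells <- if (!is.null(orb)) orb$shell else rep("valence", n)
  for (sh in unique(shells)) {
    idx <- which(shells == sh)
    blk <- rdm[idx, idx, drop = FALSE]
    e <- eigen(blk, symmetric = TRUE)
    ord <- order(e$values, decreasing = TRUE)
    U <- e$vectors[, ord, drop = FALSE]
    for (k in seq_len(ncol(U))) {
      j <- which.max(Mod(U[, k]))
      ph <- U[j, k] / Mod(U[j, k])
      U[, k] <- U[, k] / ph
    }
    C[idx, idx] <- U
    occ[idx] <- e$values[ord]
  }
  if (max(abs(Im(C))) < 1e-12) C <- Re(C)
  labels <- if (!is.null(orb)) {
    vapply(seq_len(n), function(k) {
      w <- Mod(C[, k])^2
      orb$labels[which.max(w)]
    }, character(1))
  } else paste0("no_", seq_len(n))
  # disambiguate duplicated dominant labels
  dup <- duplicated(labels) | duplicated(labels, fromLast = TRUE)
  labels[dup] <- paste0(labels[dup], "#", ave(seq_along(labels),
                                              labels, FUN = seq_along)[dup])
  list(C = C, occupations = occ, labels = labels,
       shells = shells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resolve the deconvolution basis argument: "natural", "input", or a matrix
resolve_basis <- function(basis, gs, ints) {
  n <- gs$states[[1]]$space$n_orb
  if (is.character(basis) && basis == "input") {
    lab <- if (!is.null(ints$space)) ints$space$labels else paste0("orb", 1:n)
    return(list(C = diag(1, n), labels = lab,
                shells = ints$space$shell))
  }
  if (is.character(basis) && basis == "natural") {
    return(natural_orbital_basis(gs, ints$space))
  }
  C <- basis
  if (max(abs(Conj(t(C)) %*% C - diag(n))) > 1e-8)
    stop("deconvolution basis must be unitary")
  lab <- colnames(C) %||% paste0("orb", seq_len(n))
  sh <- ints$space$shell
  list(C = C, labels = lab, shells = sh)
}

# one-body spin-orbital operator for the elementary excitation
# E_{p<-q} = sum_s a+_{p s} a_{q s} of basis columns p, q (E_pq of the
# chemist-convention expansion mu = sum d_pq E_pq annihilates q, creates p)
excitation_operator <- function(space, C, p, q) {
  O1 <- C[, p] %*% Conj(t(C[, q, drop = FALSE]))
  onebody_operator(space, spinorb_spinfree(O1))
}

# dipole matrices in the rotated basis
rotated_dipoles <- function(ints, C) {
  lapply(ints$dip, function(d) Conj(t(C)) %*% d %*% C)
}

# ordered pairs (p, q) with a nonzero rotated dipole element d_pq
dipole_pairs <- function(dips, thresh = 1e-12) {
  n <- nrow(dips$x)
  amax <- pmax(Mod(dips$x), Mod(dips$y), Mod(dips$z))
  which(amax > thresh, arr.ind = TRUE)
}

ph_key <- function(labels, hole, particle) {
  paste0("ph:", labels[hole], "->", labels[particle])
}

#' Particle-hole deconvolution of the XAS spectrum
#'
#' Expands the dipole excitation into elementary one-body components in the
#' chosen orbital basis (Eq-20-style correction vectors, one per ordered
#' orbital pair with a nonzero dipole element), and attributes the spectrum
#' to core-hole/valence-particle pairs.  The components sum to the total
#' spectrum pointwise.  Valence (particle) sums over the core holes are
#' returned in `meta$valence_sums`.
#'
#' @param ints an [integral_set()].
#' @param gs a [ground_state()].
#' @param grid a [frequency_grid()] (eV).
#' @param basis `"natural"` (default), `"input"`, or a unitary matrix.
#' @param tol correction-vector residual tolerance.
#' @return an `xray_spectrum` with one component per particle-hole key
#'   `ph:<hole>-><particle>` (de-excitation pieces are folded into the same
#'   unordered key; diagonal pieces appear as `elastic`).
#' @export
ph_decompose_xas <- function(ints, gs, grid, basis = "natural",
                             tol = 1e-10) {
  space <- gs$states[[1]]$space
  op <- hamiltonian_operator(ints, space)
  bs <- resolve_basis(basis, gs, ints)
  dips <- rotated_dipoles(ints, bs$C)
  pairs <- dipole_pairs(dips)
  eta_ha <- ev_to_hartree(grid$eta)
  zs <- gs$energy + ev_to_hartree(grid$values) + 1i * eta_ha
  g <- length(gs$states)
  nw <- length(zs)
  comps <- list()
  total <- numeric(nw)
  for (st in gs$states) {
    X <- lapply(c(x = "x", y = "y", z = "z"), function(l)
      op_apply(dipole_operator(ints, space, l), st$amp))
    for (r in seq_len(nrow(pairs))) {
      p <- pairs[r, 1]
      q <- pairs[r, 2]
      rhs <- op_apply(excitation_operator(space, bs$C, p, q), st$amp)
      kr <- krylov_resolvent(op, rhs, zs, tol = tol)
      if (kr$m == 0L) next
      contrib <- numeric(nw)
      for (l in c("x", "y", "z")) {
        d <- dips[[l]][p, q]
        if (Mod(d) < 1e-14) next
        h <- Conj(t(kr$V)) %*% X[[l]]          # V^H X
        ov <- kr$beta0 * as.vector(Conj(t(h)) %*% kr$y)  # <X|A_pq>(w)
        contrib <- contrib - Im(d * ov) / (pi * .EV * g)
      }
      key <- if (p == q) "elastic"
             else if (bs$shells[q] == "core" || bs$shells[p] != "core")
               ph_key(bs$labels, q, p)   # excitation q -> p
             else ph_key(bs$labels, p, q) # de-excitation folded back
      comps[[key]] <- (comps[[key]] %||% numeric(nw)) + contrib
      total <- total + contrib
    }
  }
  vs <- list()
  core_lab <- bs$labels[bs$shells == "core"]
  for (a in bs$labels[bs$shells == "valence"]) {
    keys <- paste0("ph:", core_lab, "->", a)
    keys <- keys[keys %in% names(comps)]
    if (length(keys))
      vs[[paste0("phsum:", a)]] <- Reduce(`+`, comps[keys])
  }
  new_spectrum(grid, total, components = comps,
               meta = list(kind = "xas_ph", manifold = g,
                           basis_labels = bs$labels,
                           valence_sums = vs))
}

#' Particle-hole deconvolution of the RIXS spectrum
#'
#' Expands both dipole steps into elementary one-body components and groups
#' the pieces by the net particle-hole character of the final state: the
#' emission step filling the absorption core hole yields net
#' valence-to-valence keys; emission exactly reversing the absorption gives
#' the `elastic` key; remaining combinations are collected under `other`.
#' The components sum to the total pointwise; the integrated
#' valence-to-valence fraction is reported in `meta$vv_fraction`.
#'
#' @param ints an [integral_set()].
#' @param gs a [ground_state()].
#' @param omega_ex incident energy (eV).
#' @param loss_grid a [frequency_grid()] of energy losses.
#' @param basis `"natural"` (default), `"input"`, or a unitary matrix.
#' @param tol correction-vector residual tolerance.
#' @return an `xray_spectrum` on the loss axis with particle-hole
#'   components; every valence-to-valence ordered pair is present (zero if
#'   not contributing).
#' @export
ph_decompose_rixs <- function(ints, gs, omega_ex, loss_grid,
                              basis = "natural", tol = 1e-10) {
  space <- gs$states[[1]]$space
  op <- hamiltonian_operator(ints, space)
  bs <- resolve_basis(basis, gs, ints)
  dips <- rotated_dipoles(ints, bs$C)
  pairs <- dipole_pairs(dips)
  npair <- nrow(pairs)
  eta_ha <- ev_to_hartree(loss_grid$eta)
  etap_ha <- ev_to_hartree(loss_grid$eta_prime)
  z_ex <- gs$energy + ev_to_hartree(omega_ex) + 1i * eta_ha
  zs <- gs$energy + ev_to_hartree(loss_grid$values) + 1i * etap_ha
  g <- length(gs$states)
  nw <- length(zs)
  comps <- list()
  # make sure all valence-valence keys exist even when zero
  val <- which(bs$shells == "valence")
  for (i in val) for (a in val)
    if (i != a) comps[[ph_key(bs$labels, i, a)]] <- numeric(nw)
  comps[["elastic"]] <- numeric(nw)
  total <- numeric(nw)
  dim <- length(space$dets)
  # Net particle-hole key of (absorption q->p, emission qq->pp), classified
  # by shell character: a core-hole path (absorb core q -> valence p, emit
  # valence qq -> core pp) has net valence character qq -> p for ANY core
  # pair (q, pp) -- the spin-orbit coupling migrates the core hole between
  # the 2p orbitals, and those paths are physically the same final-state
  # excitation.  qq == p closes the loop on the valence side: elastic.
  is_core <- bs$shells == "core"
  net_key <- function(pp, qq, p, q) {
    if (is_core[q] && is_core[pp] && !is_core[p] && !is_core[qq]) {
      if (qq == p) "elastic" else ph_key(bs$labels, qq, p)
    } else if (is_core[p] && is_core[qq] && !is_core[q] && !is_core[pp]) {
      if (pp == q) "elastic" else ph_key(bs$labels, q, pp)
    } else if (pp == qq || p == q) "diag"
    else "other"
  }
  for (st in gs$states) {
    # absorption correction vectors, one per elementary pair
    A_pq <- vector("list", npair)
    for (r in seq_len(npair)) {
      rhs <- op_apply(excitation_operator(space, bs$C, pairs[r, 1],
                                          pairs[r, 2]), st$amp)
      kr <- krylov_resolvent(op, rhs, z_ex, tol = tol)
      A_pq[[r]] <- krv_vector(kr, 1L)
    }
    # emission step applied to every absorption piece, cached across
    # Cartesian components
    piece <- vector("list", npair)
    for (e in seq_len(npair)) {
      Eop <- excitation_operator(space, bs$C, pairs[e, 1], pairs[e, 2])
      piece[[e]] <- lapply(A_pq, function(a) op_apply(Eop, a))
    }
    for (lam in c("x", "y", "z")) {
      wl <- dips[[lam]][cbind(pairs[, 1], pairs[, 2])]
      act <- which(Mod(wl) > 1e-14)
      if (!length(act)) next
      A <- Reduce(`+`, Map(function(w, v) w * v, wl[act], A_pq[act]))
      for (rho in c("x", "y", "z")) {
        wr <- dips[[rho]][cbind(pairs[, 1], pairs[, 2])]
        W <- op_apply(dipole_operator(ints, space, rho), A)
        krW <- krylov_resolvent(op, W, zs, tol = tol)
        if (krW$m == 0L) next
        total <- total - Im(krW$scalars) / (pi * .EV * g)
        # adjoint resolvent on the same Krylov basis
        ytil <- solve_tridiag_shifted(krW$alpha, krW$beta, Conj(zs))
        # group the elementary (emission x absorption) pieces by net key
        rhs_groups <- list()
        for (e in which(Mod(wr) > 1e-14)) {
          pp <- pairs[e, 1]
          qq <- pairs[e, 2]
          for (rr in act) {
            key <- net_key(pp, qq, pairs[rr, 1], pairs[rr, 2])
            rhs_groups[[key]] <- (rhs_groups[[key]] %||%
                                    rep(0 + 0i, dim)) +
              (wr[e] * wl[rr]) * piece[[e]][[rr]]
          }
        }
        for (key in names(rhs_groups)) {
          h <- Conj(t(krW$V)) %*% rhs_groups[[key]]
          ov <- krW$beta0 * as.vector(Conj(t(ytil)) %*% h)
          comps[[key]] <- (comps[[key]] %||% numeric(nw)) -
            Im(ov) / (pi * .EV * g)
        }
      }
    }
  }
  # valence-to-valence fraction: off-diagonal valence keys plus the
  # elastic (valence-diagonal) channel, over the integrated total
  vv_keys <- unlist(lapply(val, function(i)
    vapply(setdiff(val, i), function(a) ph_key(bs$labels, i, a),
           character(1))))
  vv_keys <- c(intersect(vv_keys, names(comps)), "elastic")
  num <- trapz(loss_grid$values, Reduce(`+`, comps[vv_keys]))
  den <- trapz(loss_grid$values, total)
  new_spectrum(loss_grid, total, components = comps,
               meta = list(kind = "rixs_ph", omega_ex = omega_ex,
                           manifold = g, basis_labels = bs$labels,
                           vv_fraction = if (den > 0) num / den else NA_real_))
}

#' Average particle-hole contribution over orbital sets
#'
#' Averages the particle-hole components over a hole set `H` and particle
#' set `P`: `sigma_bar = sum_{i in H, a in P} sigma_ia / (N_H N_P)`.
#'
#' @param spec an `xray_spectrum` from a particle-hole deconvolution.
#' @param H,P character vectors of orbital labels (hole and particle sets).
#' @return numeric intensity array on the spectrum grid.
#' @export
average_ph <- function(spec, H, P) {
  keys <- as.vector(outer(H, P, function(i, a) paste0("ph:", i, "->", a)))
  missing <- setdiff(keys, names(spec$components))
  if (length(missing))
    stop("missing particle-hole components: ",
         paste(missing, collapse = ", "))
  Reduce(`+`, spec$components[keys]) / (length(H) * length(P))
}

#' Attainable total spins of a determinant space
#'
#' @param space a [determinant_space()].
#' @return numeric vector of S values (ascending, step 1).
#' @export
attainable_spins <- function(space) {
  ne <- space$n_elec
  smax <- min(ne, 2 * space$n_orb - ne) / 2
  smin <- (ne %% 2) / 2
  if (smax < smin) return(numeric(0))
  seq(smin, smax, by = 1)
}

# Lowdin projector applied to a vector/matrix of amplitudes
lowdin_project_raw <- function(space, S, x, spins = NULL) {
  if (is.null(spins)) spins <- attainable_spins(space)
  if (!any(abs(spins - S) < 1e-9))
    stop("spin S = ", S, " is not attainable in this space")
  others <- sort(spins[abs(spins - S) > 1e-9], decreasing = TRUE)
  y <- x
  cs <- S * (S + 1)
  for (sp in others) {
    cp <- sp * (sp + 1)
    y <- (s2_apply_raw(space, y) - cp * y) / (cs - cp)
  }
  y
}

#' Loewdin spin projection of a state vector
#'
#' Applies the product projector
#' `P_S = prod_{S' != S} (S^2 - S'(S'+1)) / (S(S+1) - S'(S'+1))`
#' over all attainable `S'` of the space (descending order), via repeated
#' application of `S^2`.  Idempotent; annihilates pure-S' components.
#'
#' @param S total spin of the target channel.
#' @param v a [state_vector()].
#' @param spins optional explicit list of attainable spins.
#' @return the projected [state_vector()].
#' @export
spin_project <- function(S, v, spins = NULL) {
  state_vector(v$space, lowdin_project_raw(v$space, S, v$amp, spins))
}

#' Spin deconvolution of XAS or RIXS spectra
#'
#' Projects the correction vectors onto each attainable total spin with the
#' Loewdin projector and accumulates per-channel intensities
#' `(eta/pi) ||P_S C||^2`.  The projectors resolve the identity, so the
#' channels sum to the total spectrum pointwise; integrated channel
#' percentages are reported in `meta$percent`.
#'
#' @param ints an [integral_set()].
#' @param gs a [ground_state()].
#' @param grid for XAS, a [frequency_grid()] of incident energies; for
#'   RIXS, the loss grid (and `omega_ex` must be given).
#' @param omega_ex if not `NULL`, RIXS at this incident energy (eV).
#' @param channels spin values; defaults to every attainable S.
#' @param tol correction-vector residual tolerance.
#' @return an `xray_spectrum` with one component per key `spin:S=<S>`.
#' @export
spin_decompose <- function(ints, gs, grid, omega_ex = NULL, channels = NULL,
                           tol = 1e-10) {
  space <- gs$states[[1]]$space
  op <- hamiltonian_operator(ints, space)
  spins <- attainable_spins(space)
  if (is.null(channels)) channels <- spins
  if (length(setdiff(spins, channels)))
    warning("channel list does not cover all attainable spins; ",
            "the sum rule will not hold")
  eta_ha <- ev_to_hartree(grid$eta)
  etap_ha <- ev_to_hartree(grid$eta_prime)
  g <- length(gs$states)
  nw <- length(grid$values)
  comps <- setNames(rep(list(numeric(nw)), length(channels)),
                    paste0("spin:S=", format(channels)))
  total <- numeric(nw)
  accumulate <- function(kr, weight_ha) {
    if (kr$m == 0L) return()
    Cm <- krv_vectors(kr)
    for (k in seq_along(channels)) {
      P <- lowdin_project_raw(space, channels[k], Cm, spins)
      comps[[k]] <<- comps[[k]] +
        weight_ha * colSums(Mod(P)^2) / (pi * .EV * g)
    }
    total <<- total + weight_ha * colSums(Mod(Cm)^2) / (pi * .EV * g)
  }
  for (st in gs$states) {
    for (lam in c("x", "y", "z")) {
      X <- op_apply(dipole_operator(ints, space, lam), st$amp)
      if (is.null(omega_ex)) {
        zs <- gs$energy + ev_to_hartree(grid$values) + 1i * eta_ha
        kr <- krylov_resolvent(op, X, zs, tol = tol)
        accumulate(kr, eta_ha)
      } else {
        z_ex <- gs$energy + ev_to_hartree(omega_ex) + 1i * eta_ha
        krA <- krylov_resolvent(op, X, z_ex, tol = tol)
        A <- krv_vector(krA, 1L)
        zs <- gs$energy + ev_to_hartree(grid$values) + 1i * etap_ha
        for (rho in c("x", "y", "z")) {
          W <- op_apply(dipole_operator(ints, space, rho), A)
          kr <- krylov_resolvent(op, W, zs, tol = tol)
          accumulate(kr, etap_ha)
        }
      }
    }
  }
  spec <- new_spectrum(grid, total, components = comps,
                       meta = list(kind = if (is.null(omega_ex)) "xas_spin"
                                          else "rixs_spin",
                                   omega_ex = omega_ex, manifold = g))
  if (max(total) > 0) spec$meta$percent <- channel_percentages(spec)
  spec
}
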