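# Davidson iterative eigensolver for the complex Hermitian Hamiltonian and
# the ground-state driver.

# Lowest `nroots` eigenpairs of a Hermitian operator.  Deterministic start:
# unit vectors on low-diagonal determinants, spread over the `groups`
# classes (e.g. S_z sectors) so that degenerate copies living in different
# invariant subspaces are seeded.  After convergence, verification rounds
# inject fresh unit vectors from so-far-unseeded determinants and resume
# iterating until the spectrum is stable -- Krylov subspaces cannot see
# across invariant subspaces, so this guards against missed degeneracies.
# Falls back to dense diagonalization for small spaces.
davidson <- function(op, nroots = 1, tol = 1e-8, max_iter = 300,
                     max_subspace = NULL, dense_cutoff = 128,
                     groups = NULL, verify_rounds = 3L) {
  dim <- op$dim
  nroots <- min(nroots, dim)
  if (dim <= dense_cutoff || 3 * nroots >= dim) {
    H <- op_dense(op)
    e <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
    ord <- order(e$values)[seq_len(nroots)]
    return(list(values = e$values[ord],
                vectors = e$vectors[, ord, drop = FALSE],
                residuals = rep(0, nroots), iterations = 0L))
  }
  if (is.null(max_subspace)) max_subspace <- min(dim, max(20 * nroots, 240))
  d <- Re(op_diag(op))
  if (is.null(groups)) groups <- rep(1L, dim)
  # pick `k` unseeded unit-vector indices: lowest diagonal per group first,
  # then by global diagonal order
  used <- logical(dim)
  pick_seeds <- function(k) {
    sel <- integer(0)
    byg <- split(seq_len(dim)[!used], groups[!used])
    byg <- byg[order(vapply(byg, function(ix) min(d[ix]), numeric(1)))]
    for (ix in byg) {
      if (length(sel) >= k) break
      sel <- c(sel, ix[which.min(d[ix])])
    }
    rest <- setdiff(order(d), c(sel, which(used)))
    sel <- c(sel, head(rest, max(0L, k - length(sel))))
    used[sel] <<- TRUE
    sel
  }
  nb <- min(dim, nroots + 2L)
  B <- matrix(0 + 0i, dim, nb)
  B[cbind(pick_seeds(nb), seq_len(nb))] <- 1
  # dense deterministic auxiliary vectors: unit determinants can be exactly
  # orthogonal to degenerate eigenstates protected by hidden model
  # symmetries, while a fixed quasi-random dense pattern has generic
  # overlap with every eigenvector
  n_aux <- min(dim - nb, max(2L, ceiling(nroots / 2)))
  if (n_aux > 0) {
    idx <- seq_len(dim)
    for (j in seq_len(n_aux)) {
      v <- complex(real = sin(0.5 + 0.7390851332 * j * idx),
                   imaginary = cos(1.3 + 0.3819660113 * j * idx))
      for (pass in 1:2) v <- v - B %*% (Conj(t(B)) %*% v)
      nrm <- sqrt(sum(Mod(v)^2))
      if (nrm > 1e-8) B <- cbind(B, v / nrm)
    }
  }
  W <- matrix(0 + 0i, dim, 0)
  iter <- 0L
  rounds_left <- verify_rounds
  prev_theta <- NULL
  repeat {
    iter <- iter + 1L
    if (ncol(W) < ncol(B))
      for (k in (ncol(W) + 1L):ncol(B))
        W <- cbind(W, op_apply(op, B[, k]))
    S <- Conj(t(B)) %*% W
    S <- (S + Conj(t(S))) / 2
    es <- eigen(S, symmetric = TRUE)
    ord <- order(es$values)[seq_len(nroots)]
    theta <- es$values[ord]
    Y <- es$vectors[, ord, drop = FALSE]
    X <- B %*% Y
    R <- W %*% Y - X %*% diag(theta, nroots)
    rn <- sqrt(colSums(Mod(R)^2))
    if (all(rn < tol) || iter >= max_iter) {
      stable <- !is.null(prev_theta) &&
        max(abs(theta - prev_theta)) < 10 * tol
      if ((stable || rounds_left == 0L || all(used)) || iter >= max_iter)
        return(list(values = theta, vectors = X, residuals = rn,
                    iterations = iter))
      # verification round: inject unseeded unit vectors and resume
      prev_theta <- theta
      rounds_left <- rounds_left - 1L
      extra <- pick_seeds(min(dim - sum(used), max(4L, nroots)))
      for (k in extra) {
        t_new <- rep(0 + 0i, dim)
        t_new[k] <- 1
        for (pass in 1:2) t_new <- t_new - B %*% (Conj(t(B)) %*% t_new)
        nrm <- sqrt(sum(Mod(t_new)^2))
        if (nrm > 1e-8) B <- cbind(B, t_new / nrm)
      }
      next
    }
    prev_theta <- NULL
    if (ncol(B) + nroots > max_subspace) {  # restart with Ritz vectors
      B <- X
      W <- W %*% Y
      qrB <- qr(B)
      B <- qr.Q(qrB)
      W <- W %*% solve(qr.R(qrB))
    }
    added <- 0L
    for (k in seq_len(nroots)) {
      if (rn[k] < tol) next
      denom <- d - theta[k]
      denom[abs(denom) < 1e-8] <- 1e-8
      t_new <- R[, k] / denom
      for (pass in 1:2) t_new <- t_new - B %*% (Conj(t(B)) %*% t_new)
      nrm <- sqrt(sum(Mod(t_new)^2))
      if (nrm > 1e-10) {
        B <- cbind(B, t_new / nrm)
        added <- added + 1L
      }
    }
    if (added == 0L) {
      if (all(used))
        return(list(values = theta, vectors = X, residuals = rn,
                    iterations = iter))
      k <- pick_seeds(1L)
      t_new <- rep(0 + 0i, dim)
      t_new[k] <- 1
      for (pass in 1:2) t_new <- t_new - B %*% (Conj(t(B)) %*% t_new)
      nrm <- sqrt(sum(Mod(t_new)^2))
      if (nrm < 1e-10)
        return(list(values = theta, vectors = X, residuals = rn,
                    iterations = iter))
      B <- cbind(B, t_new / nrm)
    }
  }
}

#' Lowest eigenvalues of the RAS Hamiltonian
#'
#' Iterative (Davidson) computation of the `n` lowest eigenvalues; used for
#' Kramers-degeneracy checks and level diagrams.
#'
#' @param ints an [integral_set()].
#' @param space a [determinant_space()].
#' @param n number of eigenvalues.
#' @param tol residual tolerance.
#' @return numeric vector of eigenvalues (Hartree), ascending.
#' @export
lowest_eigenvalues <- function(ints, space, n = 10, tol = 1e-9) {
  op <- hamiltonian_operator(ints, space)
  davidson(op, nroots = n, tol = tol, groups = ms_groups(space))$values
}

# 2*M_s per determinant, used to spread eigensolver seeds over sectors
ms_groups <- function(space) as.integer(round(2 * spin_parts(space)$sz))

#' Ground state of the RAS Hamiltonian
#'
#' Solves for the lowest eigenvalue and an orthonormal basis of every
#' eigenvector within `degeneracy_tol` of it (the ground manifold, e.g. a
#' Kramers doublet for odd-electron systems).  Downstream spectra are
#' averaged uniformly over this manifold.
#'
#' @param ints an [integral_set()].
#' @param space a [determinant_space()].
#' @param degeneracy_tol energy window (Hartree) defining the degenerate
#'   manifold.
#' @param tol eigensolver residual tolerance.
#' @param max_manifold upper bound on the manifold size searched for.
#' @return an object of class `ground_state`: `energy` (Hartree), `states`
#'   (list of [state_vector()]), `values` (all computed eigenvalues),
#'   `degeneracy_tol`.
#' @export
ground_state <- function(ints, space, degeneracy_tol = 1e-6, tol = 1e-9,
                         max_manifold = 12) {
  dim <- length(space$dets)
  op <- hamiltonian_operator(ints, space)
  grp <- ms_groups(space)
  k <- 2L
  repeat {
    res <- davidson(op, nroots = min(dim, k + 1L), tol = tol, groups = grp)
    in_manifold <- which(res$values - res$values[1] <= degeneracy_tol)
    if (max(in_manifold) < length(res$values) || length(res$values) == dim ||
        k >= max_manifold) break
    k <- min(max_manifold, 2L * k)
  }
  g <- max(in_manifold)
  states <- lapply(seq_len(g), function(j)
    state_vector(space, res$vectors[, j]))
  structure(list(energy = res$values[1], states = states,
                 values = res$values, degeneracy_tol = degeneracy_tol,
                 residuals = res$residuals),
            class = "ground_state")
}

#' @export
print.ground_state <- function(x, ...) {
  cat("<ground_state> E0 = ", format(x$energy, digits = 12), " Ha (",
      hartree_to_ev(x$energy), " eV), manifold size ", length(x$states),
      "\n", sep = "")
  invisible(x)
}
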