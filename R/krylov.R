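# Multi-shift Lanczos solver for resolvent equations (z - H) C = X with
# Hermitian H and complex shifts z (Im z != 0).  One Krylov space per
# right-hand side serves every shift: the projected systems are shifted
# tridiagonals solved by a vectorized Thomas sweep, and the residual of the
# full-space system is available in closed form,
#   (z - H) C_m - X = -|X| beta_m y_m v_{m+1},
# so convergence is monitored exactly and the basis is grown until the
# worst shift meets the tolerance (or the space is exhausted, where the
# solve is exact).

# y solves (diag(zs) - T) y = e1 columnwise; T symmetric tridiagonal with
# diagonal `alpha` (length m) and off-diagonal `beta` (length m-1)
solve_tridiag_shifted <- function(alpha, beta, zs) {
  m <- length(alpha)
  nz <- length(zs)
  cp <- matrix(0 + 0i, m, nz)
  dp <- matrix(0 + 0i, m, nz)
  b1 <- zs - alpha[1]
  if (m > 1) cp[1, ] <- -beta[1] / b1
  dp[1, ] <- 1 / b1
  if (m > 1) {
    for (j in 2:m) {
      a <- -beta[j - 1]
      mlt <- (zs - alpha[j]) - a * cp[j - 1, ]
      if (j < m) cp[j, ] <- -beta[j] / mlt
      dp[j, ] <- (-a * dp[j - 1, ]) / mlt
    }
  }
  y <- matrix(0 + 0i, m, nz)
  y[m, ] <- dp[m, ]
  if (m > 1)
    for (j in (m - 1):1) y[j, ] <- dp[j, ] - cp[j, ] * y[j + 1, ]
  y
}

# Lanczos factorization H V = V T + beta_m v_{m+1} e_m^T with full
# reorthogonalization, grown adaptively until every shift converges.
# Returns basis, tridiagonal coefficients, per-shift solution coefficients
# y, and exact residual norms.
krylov_resolvent <- function(op, x, zs, tol = 1e-9, m_max = NULL,
                             check_every = 25L) {
  dim <- op$dim
  if (is.null(m_max)) m_max <- dim
  m_max <- min(m_max, dim)
  beta0 <- sqrt(sum(Mod(x)^2))
  if (beta0 == 0)
    return(list(beta0 = 0, m = 0L, y = matrix(0 + 0i, 0, length(zs)),
                V = matrix(0 + 0i, dim, 0), alpha = numeric(0),
                beta = numeric(0), residual = rep(0, length(zs)),
                scalars = rep(0 + 0i, length(zs))))
  V <- matrix(0 + 0i, dim, min(m_max, 64L))
  V[, 1] <- x / beta0
  alpha <- numeric(0)
  beta <- numeric(0)
  m <- 0L
  beta_last <- NA_real_
  repeat {
    m <- m + 1L
    w <- op_apply(op, V[, m])
    if (m > 1) w <- w - beta[m - 1] * V[, m - 1]
    a <- Re(Conj(V[, m]) %*% w)[1]
    alpha <- c(alpha, a)
    w <- w - a * V[, m]
    # full reorthogonalization (two passes)
    for (pass in 1:2)
      w <- w - V[, seq_len(m), drop = FALSE] %*%
        (Conj(t(V[, seq_len(m), drop = FALSE])) %*% w)
    b <- sqrt(sum(Mod(w)^2))
    beta_last <- b
    exhausted <- (m >= m_max) || (b < 1e-13 * beta0)
    if (m %% check_every == 0L || exhausted) {
      y <- solve_tridiag_shifted(alpha, beta, zs)
      residual <- beta0 * b * Mod(y[m, ])
      if (exhausted && b < 1e-13 * beta0) residual[] <- 0
      if (all(residual <= tol * beta0) || exhausted) {
        return(list(beta0 = beta0, m = m,
                    V = V[, seq_len(m), drop = FALSE],
                    alpha = alpha, beta = beta, y = y,
                    residual = residual,
                    scalars = beta0^2 * y[1, ]))
      }
    }
    beta <- c(beta, b)
    if (m + 1L > ncol(V))
      V <- cbind(V, matrix(0 + 0i, dim,
                           max(1L, min(64L, m_max - ncol(V) + 1L))))
    V[, m + 1L] <- w / b
  }
}

# correction vector for shift k from a krylov_resolvent() result
krv_vector <- function(kr, k) {
  if (kr$m == 0L) return(rep(0 + 0i, nrow(kr$V)))
  kr$beta0 * as.vector(kr$V %*% kr$y[, k])
}

# all correction vectors as a dim x nz matrix
krv_vectors <- function(kr) {
  kr$beta0 * (kr$V %*% kr$y)
}

# re-solve the projected systems for new shifts on the same Krylov space
# (used for the adjoint resolvent: same basis, conjugated shifts)
krv_resolve <- function(kr, zs) {
  y <- solve_tridiag_shifted(kr$alpha, kr$beta, zs)
  list(y = y, scalars = kr$beta0^2 * y[1, ])
}

#' Solve a correction-vector (shifted linear) equation
#'
#' Solves `(z - H) C = X` for one complex shift `z` (`Im(z) != 0`, e.g.
#' `z = E0 + w + i eta`), returning the correction vector `C` with a
#' verified relative residual `||(z-H)C - X|| / ||X|| <= tol`.
#'
#' @param ints an [integral_set()].
#' @param space a [determinant_space()].
#' @param z complex shift.
#' @param rhs right-hand side [state_vector()].
#' @param tol relative residual tolerance.
#' @param m_max maximum Krylov dimension (defaults to the space dimension,
#'   where the solve is exact).
#' @return a [state_vector()] holding `C`.
#' @export
shifted_solve <- function(ints, space, z, rhs, tol = 1e-6, m_max = NULL) {
  if (Im(z) == 0) stop("shift must have a nonzero imaginary part")
  nrm <- sqrt(sum(Mod(rhs$amp)^2))
  if (nrm == 0) return(state_vector(space, 0 + 0i))
  op <- hamiltonian_operator(ints, space)
  kr <- krylov_resolvent(op, rhs$amp, z, tol = tol, m_max = m_max)
  C <- krv_vector(kr, 1L)
  # explicit residual of the original system
  res <- sqrt(sum(Mod(z * C - op_apply(op, C) - rhs$amp)^2)) / nrm
  if (res > 10 * tol)
    stop("shifted solver stagnated: achieved relative residual ",
         format(res))
  state_vector(space, C)
}
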