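#' Integral set defining the Hamiltonian and dipole operator
#'
#' Container for everything needed to build the active-space Hamiltonian and
#' the dipole operator: the core energy, the spin-free one-electron matrix,
#' the two-electron tensor in chemist notation `(ij|kl)` with 8-fold
#' permutational symmetry, the three Cartesian mean-field Breit-Pauli
#' spin-orbit matrices (purely imaginary, antisymmetric in a real orbital
#' basis), and the three Cartesian dipole matrices (real symmetric).  All
#' energies are in Hartree, dipoles in atomic units.
#'
#' @param space an [orbital_space()].
#' @param e_core scalar core energy (Hartree).
#' @param h1 real symmetric `n x n` one-electron matrix.
#' @param eri `n^4` two-electron array `(ij|kl)`, chemist notation; may be
#'   `NULL` for zero.
#' @param h_soc list of three complex `n x n` matrices named `x`, `y`, `z`;
#'   may be `NULL` for zero.
#' @param dip list of three real `n x n` matrices named `x`, `y`, `z`; may be
#'   `NULL` for zero.
#' @param check validate all symmetry invariants (default `TRUE`).
#' @return an object of class `integral_set`.
#' @export
integral_set <- function(space, e_core = 0, h1 = NULL, eri = NULL,
                         h_soc = NULL, dip = NULL, check = TRUE) {
  stopifnot(inherits(space, "orbital_space"))
  n <- space$n_orb
  if (is.null(h1)) h1 <- matrix(0, n, n)
  if (is.null(eri)) eri <- array(0, c(n, n, n, n))
  zero_c <- function() matrix(0 + 0i, n, n)
  zero_r <- function() matrix(0, n, n)
  if (is.null(h_soc)) h_soc <- list(x = zero_c(), y = zero_c(), z = zero_c())
  if (is.null(dip)) dip <- list(x = zero_r(), y = zero_r(), z = zero_r())
  h_soc <- lapply(h_soc, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "complex"
    m
  })
  ints <- structure(list(space = space, e_core = as.numeric(e_core),
                         h1 = as.matrix(h1), eri = eri, h_soc = h_soc,
                         dip = lapply(dip, as.matrix),
                         id = .next_integral_id()),
                    class = "integral_set")
  if (check) validate_integrals(ints)
  ints
}

#' Validate the symmetry invariants of an integral set
#'
#' Checks `h1` symmetry, the 8-fold permutational symmetry of `(ij|kl)`,
#' that every spin-orbit component is purely imaginary and antisymmetric,
#' and that the dipole components are real symmetric.
#'
#' @param ints an [integral_set()].
#' @param tol absolute tolerance for the symmetry checks.
#' @return `ints`, invisibly; errors on violation.
#' @export
validate_integrals <- function(ints, tol = 1e-10) {
  n <- ints$space$n_orb
  stopifnot(all(dim(ints$h1) == c(n, n)),
            all(dim(ints$eri) == c(n, n, n, n)))
  if (max(abs(ints$h1 - t(ints$h1))) > tol) stop("h1 is not symmetric")
  e <- ints$eri
  perms <- list(aperm(e, c(2, 1, 3, 4)), aperm(e, c(1, 2, 4, 3)),
                aperm(e, c(3, 4, 1, 2)))
  for (p in perms)
    if (max(abs(e - p)) > tol)
      stop("eri violates 8-fold permutational symmetry")
  for (cc in c("x", "y", "z")) {
    m <- ints$h_soc[[cc]]
    if (max(abs(Re(m))) > tol)
      stop("h_soc[", cc, "] must be purely imaginary")
    if (max(abs(m + t(m))) > tol)
      stop("h_soc[", cc, "] must be antisymmetric")
    d <- ints$dip[[cc]]
    if (max(abs(d - t(d))) > tol)
      stop("dip[", cc, "] must be symmetric")
  }
  invisible(ints)
}

#' @export
print.integral_set <- function(x, ...) {
  n <- x$space$n_orb
  nnz_eri <- sum(x$eri != 0)
  soc <- max(vapply(x$h_soc, function(m) max(abs(m)), numeric(1)))
  cat("<integral_set> ", n, " orbitals, e_core = ", format(x$e_core),
      " Ha\n  nonzero eri: ", nnz_eri, ", max |h_soc| = ", format(soc),
      " Ha\n", sep = "")
  invisible(x)
}

#' Rotate an integral set by a unitary within the active space
#'
#' Applies the orbital rotation `C` (columns = new orbitals in the old
#' basis) to all one-body matrices and the two-electron tensor.  Used for
#' natural-orbital and localized bases; spectra totals are invariant under
#' such rotations.
#'
#' @param ints an [integral_set()].
#' @param C real (or complex) unitary `n x n` matrix.
#' @param labels optional new orbital labels.
#' @param tol unitarity tolerance.
#' @return a rotated [integral_set()].
#' @export
rotate_integrals <- function(ints, C, labels = NULL, tol = 1e-8) {
  n <- ints$space$n_orb
  stopifnot(all(dim(C) == c(n, n)))
  if (max(abs(Conj(t(C)) %*% C - diag(n))) > tol)
    stop("rotation matrix is not unitary")
  tr1 <- function(m) Conj(t(C)) %*% m %*% C
  eri <- ints$eri
  # four quarter transformations (ij|kl) -> (pq|rs); bra indices (1,3) get
  # the conjugate coefficients
  eri <- apply_mode(eri, C, 1, conjugate = TRUE)
  eri <- apply_mode(eri, C, 2, conjugate = FALSE)
  eri <- apply_mode(eri, C, 3, conjugate = TRUE)
  eri <- apply_mode(eri, C, 4, conjugate = FALSE)
  if (is.complex(eri)) {
    if (max(abs(Im(eri))) > 1e-10)
      stop("complex rotations of the two-electron tensor are not supported")
    eri <- Re(eri)
  }
  space <- ints$space
  if (!is.null(labels)) space$labels <- labels
  h1 <- tr1(ints$h1)
  dip <- lapply(ints$dip, tr1)
  if (is.complex(C)) {
    # keep container types honest for real inputs rotated by a real unitary
    h1 <- if (max(abs(Im(h1))) < 1e-12) Re(h1) else h1
    dip <- lapply(dip, function(m) if (max(abs(Im(m))) < 1e-12) Re(m) else m)
  }
  integral_set(space, e_core = ints$e_core, h1 = Re_if_real(h1),
               eri = Re_if_real(eri), h_soc = lapply(ints$h_soc, tr1),
               dip = dip, check = FALSE)
}

Re_if_real <- function(x) {
  if (is.complex(x) && max(abs(Im(x))) < 1e-12) Re(x) else x
}

# contract mode k of a 4-index array with C (ket) or Conj(C) (bra);
# C may be rectangular (old basis x new basis)
apply_mode <- function(e, C, k, conjugate = FALSE) {
  perm <- c(k, setdiff(1:4, k))
  m <- matrix(aperm(e, perm), nrow = dim(e)[k])
  Ck <- if (conjugate) Conj(C) else C
  m <- t(t(Ck) %*% m)  # new index last
  e2 <- array(m, dim = c(dim(e)[setdiff(1:4, k)], ncol(C)))
  aperm(e2, order(c(setdiff(1:4, k), k)))
}

# full spin-orbital one-body matrix: spin-free h plus the SOC contraction
# with the spin-1/2 matrices; blocked (alpha 1..n, beta 1..n)
spinorb_onebody <- function(ints) {
  n <- ints$space$n_orb
  t2n <- matrix(0 + 0i, 2 * n, 2 * n)
  aa <- 1:n
  bb <- n + 1:n
  t2n[aa, aa] <- ints$h1
  t2n[bb, bb] <- t2n[bb, bb] + ints$h1
  sx <- ints$h_soc$x
  sy <- ints$h_soc$y
  sz <- ints$h_soc$z
  # s_x = [[0, 1/2], [1/2, 0]], s_y = [[0, -i/2], [i/2, 0]],
  # s_z = [[1/2, 0], [0, -1/2]] in the (alpha, beta) basis
  t2n[aa, aa] <- t2n[aa, aa] + sz / 2
  t2n[bb, bb] <- t2n[bb, bb] - sz / 2
  t2n[aa, bb] <- t2n[aa, bb] + sx / 2 - 1i * sy / 2
  t2n[bb, aa] <- t2n[bb, aa] + sx / 2 + 1i * sy / 2
  t2n
}

# spin-free one-body operator (e.g. a dipole component) over spin orbitals
spinorb_spinfree <- function(mat) {
  n <- nrow(mat)
  t2n <- matrix(0 + 0i, 2 * n, 2 * n)
  t2n[1:n, 1:n] <- mat
  t2n[n + 1:n, n + 1:n] <- mat
  t2n
}
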