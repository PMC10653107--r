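#' State vector over a determinant space
#'
#' A complex amplitude per determinant, in the canonical determinant order.
#' Used for the ground state and for correction vectors.
#'
#' @param space a [determinant_space()].
#' @param amp complex amplitudes (recycled scalar allowed).
#' @return an object of class `state_vector`.
#' @export
state_vector <- function(space, amp) {
  amp <- as.complex(amp)
  if (length(amp) == 1L) amp <- rep(amp, length(space$dets))
  if (length(amp) != length(space$dets))
    stop("amplitude length does not match the space dimension")
  if (any(!is.finite(amp))) stop("amplitudes must be finite")
  structure(list(space = space, amp = amp), class = "state_vector")
}

#' @export
print.state_vector <- function(x, ...) {
  cat("<state_vector> dim ", length(x$amp), ", norm ",
      format(sqrt(sum(Mod(x$amp)^2))), "\n", sep = "")
  invisible(x)
}

# ---- sparse operator plumbing -------------------------------------------

# A linear operator on the determinant space stored as real and imaginary
# sparse parts (Matrix::dgCMatrix); `im` may be NULL for real operators.
make_operator <- function(triplets, dim) {
  re <- Matrix::sparseMatrix(i = triplets$i, j = triplets$j,
                             x = triplets$re, dims = c(dim, dim))
  has_im <- any(triplets$im != 0)
  im <- if (has_im)
    Matrix::sparseMatrix(i = triplets$i, j = triplets$j, x = triplets$im,
                         dims = c(dim, dim))
  else NULL
  structure(list(re = Matrix::drop0(re),
                 im = if (!is.null(im)) Matrix::drop0(im), dim = dim),
            class = "ras_operator")
}

# y = O x for complex x (vector or matrix of column vectors)
op_apply <- function(op, x) {
  vec <- is.null(dim(x))
  xr <- Re(x)
  xi <- Im(x)
  yr <- as.matrix(op$re %*% xr)
  yi <- as.matrix(op$re %*% xi)
  if (!is.null(op$im)) {
    yr <- yr - as.matrix(op$im %*% xi)
    yi <- yi + as.matrix(op$im %*% xr)
  }
  y <- yr + 1i * yi
  if (vec) as.vector(y) else y
}

op_diag <- function(op) {
  d <- Matrix::diag(op$re)
  if (!is.null(op$im)) d <- complex(real = d, imaginary = Matrix::diag(op$im))
  d
}

op_dense <- function(op) {
  m <- as.matrix(op$re)
  if (!is.null(op$im)) m <- m + 1i * as.matrix(op$im)
  m
}

space_cache_get <- function(space, key, build) {
  if (is.null(space$cache[[key]])) space$cache[[key]] <- build()
  space$cache[[key]]
}

#' Hamiltonian operator on a determinant space
#'
#' Builds (and caches on the space) the sparse RAS Hamiltonian: spin-free
#' one- and two-electron terms plus the spin-orbit one-body term contracted
#' with the Cartesian triplet operators.  Excitations that violate the RAS
#' hole limits are projected out by construction.
#'
#' @param ints an [integral_set()].
#' @param space a [determinant_space()] over the same orbital count.
#' @return a sparse operator (internal class `ras_operator`).
#' @export
hamiltonian_operator <- function(ints, space) {
  if (ints$space$n_orb != space$n_orb)
    stop("integral set and determinant space have different orbital counts")
  space_cache_get(space, paste0("H_", ints$id), function() {
    tr <- cpp_build_hamiltonian(space$dets, space$n_orb,
                                spinorb_onebody(ints),
                                as.numeric(ints$eri), ints$e_core, TRUE)
    make_operator(tr, length(space$dets))
  })
}

# generic one-body spin-orbital operator on the space (not cached)
onebody_operator <- function(space, O) {
  storage.mode(O) <- "complex"
  tr <- cpp_build_onebody(space$dets, space$n_spin, O)
  make_operator(tr, length(space$dets))
}

dipole_operator <- function(ints, space, component) {
  space_cache_get(space, paste0("dip_", component, "_", ints$id), function()
    onebody_operator(space, spinorb_spinfree(ints$dip[[component]])))
}

#' Apply the Hamiltonian to a state vector
#'
#' @param ints an [integral_set()].
#' @param v a [state_vector()].
#' @return `H v` as a [state_vector()] (includes the core energy).
#' @export
apply_h <- function(ints, v) {
  op <- hamiltonian_operator(ints, v$space)
  state_vector(v$space, op_apply(op, v$amp))
}

#' Apply a Cartesian dipole component to a state vector
#'
#' Spin-free one-body operator with the matrix `dip[[component]]`.
#'
#' @param ints an [integral_set()].
#' @param component `"x"`, `"y"` or `"z"`.
#' @param v a [state_vector()].
#' @return a [state_vector()].
#' @export
apply_dipole <- function(ints, component, v) {
  component <- match.arg(component, c("x", "y", "z"))
  op <- dipole_operator(ints, v$space, component)
  state_vector(v$space, op_apply(op, v$amp))
}

#' Apply a Cartesian triplet (spin-tensor) excitation operator
#'
#' Applies one of
#' `T^x_ij = (a+_{ia} a_{jb} + a+_{ib} a_{ja}) / 2`,
#' `T^y_ij = -i (a+_{ia} a_{jb} - a+_{ib} a_{ja}) / 2`,
#' `T^z_ij = (a+_{ia} a_{ja} - a+_{ib} a_{jb}) / 2`
#' (`a`/`b` = alpha/beta spin), the spin-tensor excitation operators that
#' the Cartesian spin-orbit matrices are contracted with.
#'
#' @param component `"x"`, `"y"` or `"z"`.
#' @param i,j spatial orbital indices (1-based).
#' @param v a [state_vector()].
#' @return a [state_vector()].
#' @export
apply_triplet <- function(component, i, j, v) {
  component <- match.arg(component, c("x", "y", "z"))
  n <- v$space$n_orb
  if (i < 1 || i > n || j < 1 || j > n) stop("orbital index out of range")
  O <- matrix(0 + 0i, 2 * n, 2 * n)
  ia <- i; ib <- i + n; ja <- j; jb <- j + n
  if (component == "x") {
    O[ia, jb] <- 0.5; O[ib, ja] <- 0.5
  } else if (component == "y") {
    O[ia, jb] <- -0.5i; O[ib, ja] <- 0.5i
  } else {
    O[ia, ja] <- 0.5; O[ib, jb] <- -0.5
  }
  op <- onebody_operator(v$space, O)
  state_vector(v$space, op_apply(op, v$amp))
}

# S_z diagonal and S+ sparse operator, cached per space
spin_parts <- function(space) {
  space_cache_get(space, "spin_parts", function() {
    n <- space$n_orb
    bits <- cpp_det_bits(space$dets, space$n_spin)
    sz <- as.vector(bits[, seq_len(n), drop = FALSE] %*% rep(0.5, n) -
                    bits[, n + seq_len(n), drop = FALSE] %*% rep(0.5, n))
    O <- matrix(0 + 0i, 2 * n, 2 * n)
    for (i in seq_len(n)) O[i, i + n] <- 1  # a+_{i,alpha} a_{i,beta}
    list(sz = sz, splus = onebody_operator(space, O))
  })
}

#' Apply the total-spin operator S^2
#'
#' Uses `S^2 = S_- S_+ + S_z (S_z + 1)`; the sparse `S_+` operator and the
#' `S_z` diagonal are cached on the space.
#'
#' @param v a [state_vector()].
#' @return `S^2 v` as a [state_vector()].
#' @export
apply_s2 <- function(v) {
  state_vector(v$space, s2_apply_raw(v$space, v$amp))
}

s2_apply_raw <- function(space, x) {
  sp <- spin_parts(space)
  vec <- is.null(dim(x))
  up <- op_apply(sp$splus, x)
  # S_- = (S_+)^H ; the operator is real so transpose suffices
  tm <- Matrix::t(sp$splus$re)
  down <- as.matrix(tm %*% Re(up)) + 1i * as.matrix(tm %*% Im(up))
  y <- down + sp$sz * (sp$sz + 1) * x
  if (vec) as.vector(y) else y
}
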