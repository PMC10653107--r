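# Independent brute-force second-quantization oracle.
#
# Determinants are occupation vectors over 2n spin orbitals (alpha block
# then beta block, matching the package convention |D> = a+_{p1}...a+_{pN}
# |vac> with ascending indices).  Operators are applied literally as strings
# of elementary creation/annihilation operators; the Hamiltonian is
# composed from spin-summed excitation operators E_ij, so this path shares
# no code (and no Slater-Condon shortcuts) with the implementation.

bf_full_basis <- function(n_spin, n_elec) {
  if (n_elec == 0) return(matrix(integer(0), 1, 0))
  t(utils::combn(n_spin, n_elec))
}

bf_code <- function(occ_idx) sum(2^(occ_idx - 1))

# sign of a_p on the determinant with (sorted) occupied indices occ
bf_annihilate <- function(occ, p) {
  if (!(p %in% occ)) return(NULL)
  s <- (-1)^sum(occ < p)
  list(occ = setdiff(occ, p), sign = s)
}

bf_create <- function(occ, p) {
  if (p %in% occ) return(NULL)
  s <- (-1)^sum(occ < p)
  list(occ = sort(c(occ, p)), sign = s)
}

# dense matrix of sum_{rp} O[r,p] a+_r a_p over a basis (rows of occ
# indices); codes index the basis columns
bf_onebody <- function(basis, O) {
  nd <- nrow(basis)
  codes <- apply(basis, 1, bf_code)
  H <- matrix(0 + 0i, nd, nd)
  n_spin <- ncol(O)
  for (J in seq_len(nd)) {
    occ <- basis[J, ]
    for (p in occ) for (r in seq_len(n_spin)) {
      if (O[r, p] == 0) next
      a <- bf_annihilate(occ, p)
      b <- bf_create(a$occ, r)
      if (is.null(b)) next
      I <- match(bf_code(b$occ), codes)
      if (is.na(I)) next
      H[I, J] <- H[I, J] + a$sign * b$sign * O[r, p]
    }
  }
  H
}

# spin-summed excitation operator E_ij (spatial indices) as a dense matrix
bf_E <- function(basis, n_orb, i, j) {
  O <- matrix(0 + 0i, 2 * n_orb, 2 * n_orb)
  O[i, j] <- 1
  O[i + n_orb, j + n_orb] <- 1
  bf_onebody(basis, O)
}

# full Hamiltonian: h1 via E_ij, two-body via (1/2) sum (ij|kl)
# (E_ij E_kl - delta_jk E_il), SOC via the spin-orbital matrix
bf_hamiltonian <- function(basis, ints) {
  n <- ints$space$n_orb
  nd <- nrow(basis)
  H <- diag(ints$e_core + 0i, nd)
  Es <- vector("list", n * n)
  for (i in seq_len(n)) for (j in seq_len(n))
    Es[[(i - 1) * n + j]] <- bf_E(basis, n, i, j)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (ints$h1[i, j] != 0)
      H <- H + ints$h1[i, j] * Es[[(i - 1) * n + j]]
    for (k in seq_len(n)) for (l in seq_len(n)) {
      v <- ints$eri[i, j, k, l]
      if (v == 0) next
      term <- Es[[(i - 1) * n + j]] %*% Es[[(k - 1) * n + l]]
      if (j == k) term <- term - Es[[(i - 1) * n + l]]
      H <- H + 0.5 * v * term
    }
  }
  # SOC: sum_c sum_ij h^c_ij T^c_ij built from elementary spin couplings
  sx <- matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE)
  sy <- matrix(c(0, -0.5i, 0.5i, 0), 2, 2, byrow = TRUE)
  sz <- matrix(c(0.5, 0, 0, -0.5), 2, 2, byrow = TRUE)
  spin_mats <- list(x = sx, y = sy, z = sz)
  O <- matrix(0 + 0i, 2 * n, 2 * n)
  for (cc in c("x", "y", "z")) {
    hs <- ints$h_soc[[cc]]
    if (all(hs == 0)) next
    s <- spin_mats[[cc]]
    for (si in 1:2) for (sj in 1:2) {
      if (s[si, sj] == 0) next
      O[(si - 1) * n + seq_len(n), (sj - 1) * n + seq_len(n)] <-
        O[(si - 1) * n + seq_len(n), (sj - 1) * n + seq_len(n)] +
        hs * s[si, sj]
    }
  }
  if (any(O != 0)) H <- H + bf_onebody(basis, O)
  H
}

# basis rows matching the canonical order of a package determinant_space
bf_basis_for_space <- function(space) {
  bits <- rascv:::cpp_det_bits(space$dets, space$n_spin)
  t(apply(bits, 1, function(b) which(b == 1)))
}

# projected RAS Hamiltonian: build over the full fixed-electron-number
# basis (operator products must run over all intermediate determinants)
# and take the submatrix on the space -- <D'|H|D> is basis-local
bf_hamiltonian_for_space <- function(space, ints) {
  basis <- bf_full_basis(space$n_spin, space$n_elec)
  codes <- apply(basis, 1, bf_code)
  H <- bf_hamiltonian(basis, ints)
  idx <- match(space$dets, codes)
  H[idx, idx, drop = FALSE]
}

# brute-force RAS filter over all bitstrings (exhaustive oracle)
bf_ras_codes <- function(spec) {
  n_orb <- spec$n_orb
  n_spin <- 2L * n_orb
  basis <- bf_full_basis(n_spin, spec$n_elec)
  keep <- apply(basis, 1, function(occ) {
    for (p in spec$partitions) {
      so <- c(p$orbitals, p$orbitals + n_orb)
      holes <- 2 * length(p$orbitals) - sum(occ %in% so)
      if (holes > p$max_holes) return(FALSE)
    }
    TRUE
  })
  sort(apply(basis[keep, , drop = FALSE], 1, bf_code))
}

# random integral set obeying all symmetries (seeded)
random_ints <- function(n, seed, soc = TRUE, dip = TRUE, two_body = TRUE) {
  set.seed(seed)
  h1 <- matrix(rnorm(n * n), n, n)
  h1 <- (h1 + t(h1)) / 2
  eri <- array(0, c(n, n, n, n))
  if (two_body) {
    eri <- array(rnorm(n^4), c(n, n, n, n))
    eri <- eri + aperm(eri, c(2, 1, 3, 4))
    eri <- eri + aperm(eri, c(1, 2, 4, 3))
    eri <- eri + aperm(eri, c(3, 4, 1, 2))
    eri <- eri / 8
  }
  mk_soc <- function() {
    a <- matrix(rnorm(n * n), n, n)
    (a - t(a)) / 2 * 1i
  }
  mk_dip <- function() {
    a <- matrix(rnorm(n * n), n, n)
    (a + t(a)) / 2
  }
  z <- function() matrix(0 + 0i, n, n)
  zr <- function() matrix(0, n, n)
  space <- orbital_space(paste0("orb", 1:n), rep("RAS2", n),
                         rep("valence", n))
  integral_set(space, e_core = rnorm(1),
               h1 = h1, eri = eri,
               h_soc = if (soc) list(x = mk_soc(), y = mk_soc(),
                                     z = mk_soc())
                       else list(x = z(), y = z(), z = z()),
               dip = if (dip) list(x = mk_dip(), y = mk_dip(),
                                   z = mk_dip())
                     else list(x = zr(), y = zr(), z = zr()))
}

# seeded random complex state over a space
random_state <- function(space, seed) {
  set.seed(seed)
  n <- length(space$dets)
  v <- complex(real = rnorm(n), imaginary = rnorm(n))
  state_vector(space, v / sqrt(sum(Mod(v)^2)))
}

full_space <- function(n_orb, n_elec, ...) {
  enumerate_space(ras_spec(list(list(orbitals = seq_len(n_orb),
                                     max_holes = Inf)), n_elec), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
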