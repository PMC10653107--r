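test_that("closed-shell single-orbital energy follows the pair formula", {
  space <- orbital_space("a", "RAS2", "valence")
  eri <- array(0.5, c(1, 1, 1, 1))
  ints <- integral_set(space, e_core = 0.3, h1 = matrix(-1, 1, 1),
                       eri = eri)
  sp <- full_space(1, 2)
  v <- state_vector(sp, 1)
  hv <- apply_h(ints, v)
  expect_equal(hv$amp, (0.3 - 2 + 0.5) * v$amp, tolerance = 1e-12)
})

test_that("Hamiltonian action matches the brute-force operator algebra", {
  # random integrals (two-body + SOC) over full and RAS-restricted spaces
  cases <- list(
    list(ints = random_ints(2, seed = 31), space = full_space(2, 2)),
    list(ints = random_ints(3, seed = 32), space = full_space(3, 3)),
    list(ints = random_ints(3, seed = 33),
         space = enumerate_space(ras_spec(list(
           list(orbitals = 1, max_holes = 1),
           list(orbitals = 2:3, max_holes = Inf)), 3))))
  for (cs in cases) {
    H_bf <- bf_hamiltonian_for_space(cs$space, cs$ints)
    H_pkg <- rascv:::op_dense(
      rascv:::hamiltonian_operator(cs$ints, cs$space))
    expect_lt(max(abs(H_pkg - H_bf)), 1e-10)
  }
})

test_that("the Hamiltonian is Hermitian including the spin-orbit term", {
  fx <- get_fixture("d2_toy")
  x <- random_state(fx$space, 41)
  y <- random_state(fx$space, 42)
  lhs <- sum(Conj(x$amp) * apply_h(fx$ints, y)$amp)
  rhs <- Conj(sum(Conj(y$amp) * apply_h(fx$ints, x)$amp))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("spin-free Hamiltonians commute with S^2 and S_z", {
  fx <- get_fixture("d2_toy", zeta = 0)
  v <- random_state(fx$space, 43)
  hs <- apply_s2(apply_h(fx$ints, v))
  sh <- apply_h(fx$ints, apply_s2(v))
  expect_lt(max(Mod(hs$amp - sh$amp)), 1e-10)
  sz <- rascv:::spin_parts(fx$space)$sz
  hz <- sz * apply_h(fx$ints, v)$amp
  zh <- apply_h(fx$ints, state_vector(fx$space, sz * v$amp))$amp
  expect_lt(max(Mod(hz - zh)), 1e-10)
})

test_that("Cartesian triplet operators match the brute-force algebra", {
  space <- full_space(2, 2)
  basis <- bf_basis_for_space(space)
  n <- 2
  smat <- list(x = matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE),
               y = matrix(c(0, -0.5i, 0.5i, 0), 2, 2, byrow = TRUE),
               z = matrix(c(0.5, 0, 0, -0.5), 2, 2, byrow = TRUE))
  for (comp in c("x", "y", "z")) for (i in 1:2) for (j in 1:2) {
    O <- matrix(0 + 0i, 4, 4)
    for (si in 1:2) for (sj in 1:2)
      O[(si - 1) * n + i, (sj - 1) * n + j] <- smat[[comp]][si, sj]
    ref <- bf_onebody(basis, O)
    for (col in seq_len(nrow(basis))) {
      v <- state_vector(space, replace(rep(0 + 0i, nrow(basis)), col, 1))
      got <- apply_triplet(comp, i, j, v)$amp
      expect_lt(max(Mod(got - ref[, col])), 1e-12)
    }
  }
})

test_that("T^z counts the spin of the number operator combination", {
  space <- full_space(2, 1)
  # determinant with an alpha electron in orbital 1 (beta empty)
  idx <- det_index(space, 1)
  v <- state_vector(space, replace(rep(0 + 0i, 4), idx, 1))
  tz <- apply_triplet("z", 1, 1, v)
  expect_equal(tz$amp, 0.5 * v$amp, tolerance = 1e-12)
  # acting where both spin orbitals are empty annihilates the state
  tx <- apply_triplet("x", 2, 2, v)
  expect_equal(max(Mod(tx$amp)), 0, tolerance = 1e-14)
})

test_that("S^2 has the exact eigenstructure", {
  # single alpha electron: S(S+1) = 3/4
  sp1 <- full_space(1, 1)
  v <- state_vector(sp1, c(1, 0))
  expect_equal(apply_s2(v)$amp, 0.75 * v$amp, tolerance = 1e-12)
  # maximal-spin determinant, five alpha electrons: S = 5/2
  sp5 <- full_space(5, 5, twice_ms = 5)
  vmax <- state_vector(sp5, 1)
  expect_equal(apply_s2(vmax)$amp, 8.75 * vmax$amp, tolerance = 1e-12)
  # dense S^2 on the 2-orbital, 2-electron space: eigenvalue set {0, 2}
  sp2 <- full_space(2, 2)
  D <- length(sp2$dets)
  S2 <- vapply(seq_len(D), function(k)
    apply_s2(state_vector(sp2, replace(rep(0 + 0i, D), k, 1)))$amp,
    complex(D))
  ev <- eigen(S2, symmetric = TRUE)$values
  expect_equal(sort(unique(round(ev, 9))), c(0, 2))
})

test_that("dipole application is the dense spin-free one-body action", {
  ints <- random_ints(3, seed = 51)
  space <- full_space(3, 2)
  basis <- bf_basis_for_space(space)
  for (comp in c("x", "z")) {
    ref <- bf_onebody(basis, rascv:::spinorb_spinfree(ints$dip[[comp]]))
    v <- random_state(space, 52)
    got <- apply_dipole(ints, comp, v)$amp
    expect_lt(max(Mod(got - ref %*% v$amp)), 1e-10)
    # Hermiticity
    w <- random_state(space, 53)
    lhs <- sum(Conj(w$amp) * apply_dipole(ints, comp, v)$amp)
    rhs <- Conj(sum(Conj(v$amp) * apply_dipole(ints, comp, w)$amp))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  zero <- integral_set(ints$space, h1 = ints$h1)
  v <- random_state(space, 54)
  expect_equal(max(Mod(apply_dipole(zero, "y", v)$amp)), 0)
})

test_that("ground_state handles trivial and analytic cases", {
  # single-determinant space
  space <- orbital_space("a", "RAS2", "valence")
  ints <- integral_set(space, e_core = 0.1, h1 = matrix(-0.7, 1, 1))
  sp <- full_space(1, 2)
  gs <- ground_state(ints, sp)
  expect_equal(gs$energy, 0.1 - 1.4, tolerance = 1e-10)
  expect_equal(Mod(gs$states[[1]]$amp), 1)

  # single p hole: 4-fold j=3/2 manifold at -zeta/2, gap 3 zeta / 2
  fx <- get_fixture("p_hole")
  gsp <- get_ground_state(fx)
  expect_identical(length(gsp$states), 4L)
  e6 <- lowest_eigenvalues(fx$ints, fx$space, n = 6)
  expect_equal(hartree_to_ev(e6[5] - e6[1]), 1.5 * 8.2,
               tolerance = 1e-8)
  expect_equal(hartree_to_ev(e6[1]), -8.2 / 2, tolerance = 1e-8)
})

test_that("the d6 Hund model has a high-spin S = 2 ground state", {
  fx <- get_fixture("ferrous", zeta = 0)
  gs <- get_ground_state(fx)
  for (st in gs$states) {
    s2 <- Re(sum(Conj(st$amp) * apply_s2(st)$amp))
    expect_equal(s2, 6, tolerance = 1e-8)
  }
  # iterative energy matches dense diagonalization
  eig <- dense_eigen(fx$ints, fx$space)
  expect_equal(gs$energy, eig$values[1], tolerance = 1e-8)
  # manifold states are orthonormal
  M <- vapply(gs$states, `[[`, complex(length(fx$space$dets)), "amp")
  G <- Conj(t(M)) %*% M
  expect_lt(max(Mod(G - diag(ncol(M)))), 1e-8)
})

test_that("iterative eigenvalues match dense diagonalization", {
  fx <- get_fixture("d2_toy")
  e10 <- lowest_eigenvalues(fx$ints, fx$space, n = 10)
  eig <- dense_eigen(fx$ints, fx$space)
  expect_lt(max(abs(e10 - eig$values[1:10])), 1e-8)
})

test_that("spin-free ground energies are independent of S_z restriction", {
  fx_full <- get_fixture("ferrous", zeta = 0)
  fx_ms <- get_fixture("ferrous", zeta = 0, twice_ms = 0)
  g1 <- get_ground_state(fx_full)
  g2 <- get_ground_state(fx_ms)
  expect_equal(g1$energy, g2$energy, tolerance = 1e-10)
})

test_that("odd-electron spin-orbit spectra are Kramers degenerate", {
  for (nm in c("p_hole", "ferric")) {
    fx <- get_fixture(nm)
    e10 <- lowest_eigenvalues(fx$ints, fx$space, n = min(10,
      length(fx$space$dets)))
    pairs <- matrix(e10[seq_len(2 * (length(e10) %/% 2))], nrow = 2)
    expect_lt(max(abs(pairs[2, ] - pairs[1, ])), 1e-8)
  }
})
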