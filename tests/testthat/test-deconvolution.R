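test_that("Loewdin projectors obey the projector algebra", {
  for (nm in c("p_hole", "d2_toy", "ferrous")) {
    fx <- get_fixture(nm)
    spins <- attainable_spins(fx$space)
    v <- random_state(fx$space, 71)
    parts <- lapply(spins, function(S) spin_project(S, v)$amp)
    # resolution of identity
    expect_lt(max(Mod(Reduce(`+`, parts) - v$amp)), 1e-8)
    for (k in seq_along(spins)) {
      # idempotence
      pk <- spin_project(spins[k], state_vector(fx$space, parts[[k]]))$amp
      expect_lt(max(Mod(pk - parts[[k]])), 1e-8)
      # mutual orthogonality (operator product annihilates)
      if (k < length(spins)) {
        pq <- spin_project(spins[k + 1],
                           state_vector(fx$space, parts[[k]]))$amp
        expect_lt(max(Mod(pq)), 1e-8)
      }
    }
  }
  expect_error(spin_project(7.5, random_state(get_fixture("p_hole")$space,
                                              72)),
               "not attainable")
})

test_that("projectors keep and annihilate pure spin eigenvectors", {
  fx <- get_fixture("d2_toy", zeta = 0)
  gs <- get_ground_state(fx)
  v <- gs$states[[1]]  # pure singlet (checked via <S^2>)
  expect_lt(Re(sum(Conj(v$amp) * apply_s2(v)$amp)), 1e-8)
  keep <- spin_project(0, v)
  expect_lt(max(Mod(keep$amp - v$amp)), 1e-10)
  kill <- spin_project(1, v)
  expect_lt(max(Mod(kill$amp)), 1e-10)
})

test_that("single coupled pair carries all particle-hole weight", {
  # dipole couples exactly one core-valence pair
  space <- orbital_space(c("c", "v"), c("RAS1", "RAS2"),
                         c("core", "valence"))
  h1 <- diag(ev_to_hartree(c(-700, 0)))
  dx <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  ints <- integral_set(space, h1 = h1,
                       dip = list(x = dx, y = matrix(0, 2, 2),
                                  z = matrix(0, 2, 2)))
  sp <- enumerate_space(ras_spec(list(list(orbitals = 1, max_holes = 1),
                                      list(orbitals = 2,
                                           max_holes = Inf)), 2),
                        space = space)
  gs <- ground_state(ints, sp)
  grid <- frequency_grid_seq(695, 705, 0.1, eta = 0.3)
  ph <- ph_decompose_xas(ints, gs, grid, basis = "input")
  key <- "ph:c->v"
  expect_true(key %in% names(ph$components))
  others <- setdiff(names(ph$components), key)
  for (k in others)
    expect_lt(max(abs(ph$components[[k]])), 1e-10 * max(ph$total))
  expect_lt(max(abs(ph$components[[key]] - ph$total)) / max(ph$total),
            1e-10)
})

test_that("particle-hole XAS components sum to the total pointwise", {
  for (nm in c("d2_toy", "ferrous")) {
    fx <- get_fixture(nm)
    gs <- get_ground_state(fx)
    grid <- frequency_grid_seq(699, 745, 0.5, eta = 0.3)
    ph <- ph_decompose_xas(fx$ints, gs, grid)
    expect_lt(sumrule_check(ph)$max_rel_dev, 1e-8)
    # and the total is the plain correction-vector spectrum
    cv <- xas_spectrum(fx$ints, gs, grid, tol = 1e-11)
    expect_lt(max(abs(ph$total - cv$total)) / max(cv$total), 1e-7)
    # valence sums are sums of the matching components
    vs <- ph$meta$valence_sums
    expect_gt(length(vs), 0)
    expect_lt(max(abs(Reduce(`+`, vs) +
                        (ph$components$elastic %||% 0) -
                        ph$total)) / max(ph$total), 1e-7)
  }
})

test_that("valence-summed components resolve the crystal-field splitting", {
  # one-electron limit: empty d shell split by 10Dq, no two-electron terms
  tendq <- 1.2
  p <- ligand_field_params(core_orbitals = 3, valence_orbitals = 5,
                           crystal_field = c(0, 0, tendq, tendq, tendq),
                           core_energy = -710, zeta_core = 0,
                           u_direct = 0, j_exchange = 0,
                           core_valence_attraction = 0)
  ints <- build_model(p)
  space <- enumerate_space(ras_spec_from_space(ints$space, 6),
                           space = ints$space)
  gs <- ground_state(ints, space)
  grid <- frequency_grid_seq(705, 715, 0.02, eta = 0.3)
  ph <- ph_decompose_xas(ints, gs, grid, basis = "input")
  vs <- ph$meta$valence_sums
  peak_of <- function(y) grid$values[which.max(y)]
  lo <- peak_of(vs[["phsum:3d_z2"]])
  hi <- peak_of(vs[["phsum:3d_xy"]])
  expect_equal(hi - lo, tendq, tolerance = 0.03)
})

test_that("RIXS particle-hole components sum to the total", {
  fx <- get_fixture("d2_toy")
  gs <- get_ground_state(fx)
  xg <- frequency_grid_seq(698, 736, 0.5, eta = 0.3)
  wex <- select_omega_ex(xas_spectrum(fx$ints, gs, xg, tol = 1e-10),
                         c(698, 734))
  lg <- frequency_grid_seq(-0.4, 4, 0.05, eta = 0.3, eta_prime = 0.1)
  ph <- ph_decompose_rixs(fx$ints, gs, wex, lg)
  expect_lt(sumrule_check(ph)$max_rel_dev, 1e-8)
  rx <- rixs_spectrum(fx$ints, gs, wex, lg, tol = 1e-11)
  expect_lt(max(abs(ph$total - rx$total)) / max(rx$total), 1e-7)
  expect_gt(ph$meta$vv_fraction, 0.99)
  # every valence-to-valence ordered pair is reported
  val <- fx$ints$space$labels[fx$ints$space$shell == "valence"]
  for (i in val) for (a in setdiff(val, i))
    expect_true(paste0("ph:", i, "->", a) %in% names(ph$components))
})

test_that("an empty valence shell leaves only the elastic channel", {
  fx <- get_fixture("p_to_d")
  gs <- get_ground_state(fx)
  lg <- frequency_grid_seq(-0.4, 3, 0.05, eta = 0.3, eta_prime = 0.1)
  ph <- ph_decompose_rixs(fx$ints, gs, 705.9, lg)
  vv <- grep("^ph:3d", names(ph$components), value = TRUE)
  for (k in vv)
    expect_lt(max(abs(ph$components[[k]])), 1e-8 * max(ph$total))
  expect_gt(max(ph$components$elastic), 0)
})

test_that("designed three-level loss peak lands in its pair component", {
  ints <- three_level_ints(e2 = 700, e3 = 2, m1 = 0.9, m2 = 0.6)
  space <- full_space(3, 1)
  gs <- ground_state(ints, space)
  lg <- frequency_grid_seq(1, 3, 0.02, eta = 0.3, eta_prime = 0.1)
  ph <- ph_decompose_rixs(ints, gs, 700, lg, basis = "input")
  key <- "ph:g->f"
  expect_true(key %in% names(ph$components))
  # the loss peak belongs to the designed pair; everything else in the
  # window is the tail of the elastic line
  resid <- ph$total - ph$components[[key]] - ph$components$elastic
  expect_lt(max(abs(resid)) / max(ph$total), 1e-8)
  # and the pair component dominates at the loss peak
  at_peak <- which.min(abs(lg$values - 2))
  expect_gt(ph$components[[key]][at_peak] / ph$total[at_peak], 0.95)
})

test_that("average particle-hole contributions follow the set formula", {
  fx <- get_fixture("d2_toy")
  gs <- get_ground_state(fx)
  xg <- frequency_grid_seq(698, 736, 0.5, eta = 0.3)
  wex <- select_omega_ex(xas_spectrum(fx$ints, gs, xg, tol = 1e-10),
                         c(698, 734))
  lg <- frequency_grid_seq(-0.4, 4, 0.05, eta = 0.3, eta_prime = 0.1)
  ph <- ph_decompose_rixs(fx$ints, gs, wex, lg)
  labs <- ph$meta$basis_labels
  val <- labs[fx$ints$space$shell == "valence"]
  one <- average_ph(ph, H = val[1], P = val[2])
  expect_equal(one, ph$components[[paste0("ph:", val[1], "->", val[2])]],
               tolerance = 1e-12)
  trio <- average_ph(ph, H = val[1], P = val[2:3])
  manual <- (ph$components[[paste0("ph:", val[1], "->", val[2])]] +
             ph$components[[paste0("ph:", val[1], "->", val[3])]]) / 2
  expect_equal(trio, manual, tolerance = 1e-12)
  expect_error(average_ph(ph, H = "nope", P = val[2]), "missing")
  # uniform components average to themselves
  fake <- ph
  fake$components <- list("ph:a->b" = rep(2, 5), "ph:a->c" = rep(2, 5))
  expect_equal(average_ph(fake, "a", c("b", "c")), rep(2, 5))
})

test_that("spin channels obey the spin-free selection rule and sum rule", {
  fx0 <- get_fixture("ferrous", zeta = 0)
  gs0 <- get_ground_state(fx0)
  grid <- frequency_grid_seq(712, 746, 0.25, eta = 0.3)
  sd0 <- spin_decompose(fx0$ints, gs0, grid)
  expect_lt(sumrule_check(sd0)$max_rel_dev, 1e-8)
  tot <- rascv:::trapz(grid$values, sd0$total)
  for (key in names(sd0$components)) {
    w <- rascv:::trapz(grid$values, sd0$components[[key]]) / tot
    if (key == "spin:S=2") expect_gt(w, 1 - 1e-10)
    else expect_lt(abs(w), 1e-10)
  }
})

test_that("spin-orbit coupling moves weight into the spin-flip channel", {
  grid <- frequency_grid_seq(712, 746, 0.25, eta = 0.3)
  w1 <- vapply(c(0, 0.05, 0.1), function(zeta) {
    fx <- get_fixture("ferrous", zeta = zeta)
    gs <- get_ground_state(fx)
    sd <- spin_decompose(fx$ints, gs, grid)
    expect_lt(sumrule_check(sd)$max_rel_dev, 1e-8)
    rascv:::trapz(grid$values, sd$components[["spin:S=1"]]) /
      rascv:::trapz(grid$values, sd$total)
  }, numeric(1))
  expect_lt(abs(w1[1]), 1e-10)
  expect_gt(w1[2], 0)
  expect_gt(w1[3], w1[2])
})

test_that("RIXS spin channels sum to the total", {
  fx <- get_fixture("d2_toy")
  gs <- get_ground_state(fx)
  lg <- frequency_grid_seq(-0.4, 4, 0.05, eta = 0.3, eta_prime = 0.1)
  sd <- spin_decompose(fx$ints, gs, lg, omega_ex = 706)
  expect_lt(sumrule_check(sd)$max_rel_dev, 1e-8)
  expect_true(all(vapply(sd$components, min, numeric(1)) >= -1e-12))
})

test_that("sum-rule reports quantify missing components", {
  grid <- frequency_grid(1:5, eta = 0.3)
  total <- c(1, 2, 4, 2, 1)
  comps <- list(a = total * 0.75, b = total * 0.25)
  spec <- rascv:::new_spectrum(grid, total, components = comps)
  expect_equal(sumrule_check(spec)$max_rel_dev, 0)
  expect_true(sumrule_check(spec)$ok)
  dropped <- spec
  dropped$components$b <- NULL
  chk <- sumrule_check(dropped)
  expect_false(chk$ok)
  expect_equal(chk$max_rel_dev, 0.25, tolerance = 1e-12)
  bad <- spec
  bad$components$a <- bad$components$a[1:3]
  expect_error(sumrule_check(bad), "match")
})

test_that("totals are invariant under the deconvolution basis", {
  fx <- get_fixture("d2_toy")
  gs <- get_ground_state(fx)
  grid <- frequency_grid_seq(699, 720, 0.5, eta = 0.3)
  nat <- ph_decompose_xas(fx$ints, gs, grid, basis = "natural")
  inp <- ph_decompose_xas(fx$ints, gs, grid, basis = "input")
  expect_lt(max(abs(nat$total - inp$total)) / max(inp$total), 1e-7)
  # rotating the valence block by an arbitrary unitary leaves the total
  # unchanged as well
  n <- fx$ints$space$n_orb
  set.seed(9)
  val <- which(fx$ints$space$shell == "valence")
  U <- diag(1, n)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  U[val, val] <- Q
  rot <- ph_decompose_xas(fx$ints, gs, grid, basis = U)
  expect_lt(max(abs(rot$total - inp$total)) / max(inp$total), 1e-7)
  expect_error(ph_decompose_xas(fx$ints, gs, grid, basis = U * 1.01),
               "unitary")
})

test_that("natural orbitals diagonalize the shell density blocks", {
  fx <- get_fixture("ferrous")
  gs <- get_ground_state(fx)
  nb <- natural_orbital_basis(gs)
  n <- fx$ints$space$n_orb
  expect_lt(max(Mod(Conj(t(nb$C)) %*% nb$C - diag(n))), 1e-10)
  # occupations: core full, six valence electrons
  expect_equal(sum(nb$occupations), 12, tolerance = 1e-8)
  expect_true(all(nb$occupations[1:3] > 1.99))
  val_occ <- nb$occupations[4:8]
  expect_true(all(diff(val_occ) < 1e-12))  # sorted descending
})
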