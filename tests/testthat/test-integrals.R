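test_that("unit conversion round-trips", {
  x <- c(1e-6, 0.3, 8.2, 710)
  expect_equal(hartree_to_ev(ev_to_hartree(x)), x, tolerance = 1e-12)
  expect_equal(ev_to_hartree(27.211386245988), 1, tolerance = 1e-12)
})

test_that("model integral sets satisfy all symmetry invariants", {
  for (nm in c("p_hole", "p_to_d", "d2_toy", "ferrous", "ferric",
               "ferrous_sigma"))
    expect_silent(validate_integrals(get_fixture(nm)$ints))
  expect_silent(validate_integrals(random_ints(3, seed = 11)))
})

test_that("degenerate spin-free model reduces to a scaled identity", {
  p <- ligand_field_params(core_orbitals = 3, valence_orbitals = 5,
                           crystal_field = rep(1.5, 5), zeta_core = 0,
                           u_direct = 0, j_exchange = 0,
                           core_valence_attraction = 0)
  ints <- build_model(p)
  expect_true(all(vapply(ints$h_soc, function(m) max(abs(m)), numeric(1))
                  == 0))
  vb <- ints$h1[4:8, 4:8]
  expect_equal(vb, diag(ev_to_hartree(1.5), 5), tolerance = 1e-14)
})

test_that("one-particle p shell splits into j=3/2 and j=1/2 by 3 zeta / 2", {
  zeta <- 8.2
  p <- ligand_field_params(core_orbitals = 3, valence_orbitals = 0,
                           crystal_field = numeric(0), core_energy = 0,
                           zeta_core = zeta, u_direct = 0, j_exchange = 0,
                           core_valence_attraction = 0)
  ints <- build_model(p)
  e <- sort(hartree_to_ev(eigen(rascv:::spinorb_onebody(ints),
                                symmetric = TRUE)$values))
  # one electron: j=1/2 doublet at -zeta, j=3/2 quadruplet at +zeta/2
  expect_equal(e, c(-zeta, -zeta, rep(zeta / 2, 4)), tolerance = 1e-10)
  expect_equal(e[3] - e[1], 1.5 * zeta, tolerance = 1e-10)
})

test_that("tetrahedral-like crystal field gives two one-electron levels", {
  p <- ligand_field_params(core_orbitals = 0, valence_orbitals = 5,
                           crystal_field = c(0, 0, 0.65, 0.65, 0.65),
                           zeta_core = 0, u_direct = 0, j_exchange = 0,
                           core_valence_attraction = 0)
  ints <- build_model(p)
  e <- round(hartree_to_ev(eigen(ints$h1, symmetric = TRUE)$values), 9)
  expect_equal(as.vector(table(e)), c(2, 3))
  expect_equal(max(e) - min(e), 0.65, tolerance = 1e-10)
})

test_that("extended FCIDUMP round trip is exact", {
  for (ints in list(get_fixture("ferrous_sigma")$ints,
                    random_ints(3, seed = 5))) {
    path <- withr::local_tempfile(fileext = ".fcidump")
    write_integrals(ints, path, n_elec = 12)
    back <- read_integrals(path)
    expect_equal(back$h1, ints$h1, tolerance = 0)
    expect_equal(back$eri, ints$eri, tolerance = 0)
    for (cc in c("x", "y", "z")) {
      expect_equal(back$h_soc[[cc]], ints$h_soc[[cc]], tolerance = 0)
      expect_equal(back$dip[[cc]], ints$dip[[cc]], tolerance = 0)
    }
    expect_equal(back$e_core, ints$e_core, tolerance = 0)
    expect_identical(back$space$labels, ints$space$labels)
    expect_identical(back$space$partition, ints$space$partition)
    # writing again reproduces the file byte for byte
    path2 <- withr::local_tempfile(fileext = ".fcidump")
    write_integrals(back, path2, n_elec = 12)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("minimal FCIDUMP file parses; SOC antisymmetry is completed", {
  path <- withr::local_tempfile()
  writeLines(c("&FCI NORB=2,NELEC=1,MS2=1,", " ORBSYM=1,1,", " ISYM=1,",
               "&END",
               "-1.0000000000000000e+00 1 1 0 0",
               "0.0000000000000000e+00 0 0 0 0",
               "&SOC z",
               "2.5000000000000000e-01 1 2"), path)
  ints <- read_integrals(path)
  expect_equal(ints$space$n_orb, 2)
  expect_equal(ints$h1, matrix(c(-1, 0, 0, 0), 2, 2))
  expect_true(all(ints$eri == 0))
  expect_equal(ints$h_soc$z[1, 2], 0.25i)
  expect_equal(ints$h_soc$z[2, 1], -0.25i)  # antisymmetric completion
  expect_equal(ints$e_core, 0)
})

test_that("malformed FCIDUMP input raises parse errors naming the line", {
  bad <- function(lines) {
    path <- tempfile()
    writeLines(lines, path)
    path
  }
  hdr <- c("&FCI NORB=2,NELEC=2,MS2=0,", "&END")
  expect_error(read_integrals(bad(c(hdr, "1.0 1 5 0 0"))), "out of range")
  expect_error(read_integrals(bad(c(hdr, "1.0 1"))), "line 3")
  expect_error(read_integrals(bad(c("no header", "1.0 1 1 0 0"))),
               "header")
  expect_error(read_integrals(bad(c(hdr, "1.0 1 2 0 0",
                                    "2.0 2 1 0 0"))),
               "conflicting duplicate")
  expect_error(read_integrals(bad(c(hdr, "0.5 1 2 1 1",
                                    "0.7 2 1 1 1"))),
               "conflicting duplicate")
  expect_error(read_integrals("/nonexistent/file"), "no such file")
})

test_that("stored eri entry count equals the brute-force orbit count", {
  ints <- random_ints(3, seed = 7)
  n <- 3
  # brute force: count orbits of the 8-fold symmetry group over nonzero
  # entries
  seen <- array(FALSE, c(n, n, n, n))
  orbits <- 0L
  for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n) {
    if (seen[i, j, k, l] || ints$eri[i, j, k, l] == 0) next
    orbits <- orbits + 1L
    for (o in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                   c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                   c(k, l, j, i), c(l, k, j, i)))
      seen[o[1], o[2], o[3], o[4]] <- TRUE
  }
  expect_identical(eri_unique_count(ints), orbits)
  path <- withr::local_tempfile()
  write_integrals(ints, path)
  body <- grep("^-?[0-9.]+e[+-][0-9]+ [0-9]+ [0-9]+ [0-9]+ [0-9]+$",
               readLines(path), value = TRUE)
  idx <- do.call(rbind, lapply(strsplit(body, " "),
                               function(t) as.integer(t[-1])))
  n_eri_lines <- sum(idx[, 3] > 0 & idx[, 4] > 0)
  expect_identical(n_eri_lines, as.integer(orbits))
})

test_that("integral rotation preserves spectra-relevant invariants", {
  ints <- random_ints(3, seed = 13)
  set.seed(1)
  A <- matrix(rnorm(9), 3, 3)
  U <- qr.Q(qr(A))
  rot <- rotate_integrals(ints, U)
  expect_silent(validate_integrals(rot))
  expect_equal(sort(eigen(rot$h1, symmetric = TRUE)$values),
               sort(eigen(ints$h1, symmetric = TRUE)$values),
               tolerance = 1e-10)
  # rotating back restores the original tensors
  back <- rotate_integrals(rot, t(U))
  expect_equal(back$eri, ints$eri, tolerance = 1e-10)
  expect_equal(back$h1, ints$h1, tolerance = 1e-10)
  expect_error(rotate_integrals(ints, U * 1.01), "unitary")
})

test_that("adapter selects by occupation window and localizes unitarily", {
  occ <- c(2.0, 2.0, 1.1, 0.9, 0.0)
  full <- random_ints(5, seed = 21)
  # identity coefficients: selection must pick orbitals 3 and 4 and leave
  # the integrals untouched
  act <- from_adapter(diag(5), occ, full, n_select = 2,
                      window = c(0.02, 1.98))
  expect_equal(act$h1, full$h1[3:4, 3:4], tolerance = 1e-12)
  expect_equal(act$eri, full$eri[3:4, 3:4, 3:4, 3:4], tolerance = 1e-12)
  expect_error(from_adapter(diag(5), occ, full, n_select = 3,
                            window = c(0.02, 1.98)),
               "candidates")
  # localized selection: h1 eigenvalues equal those of the projected
  # subspace (unitary invariance)
  set.seed(3)
  Cf <- qr.Q(qr(matrix(rnorm(25), 5)))
  act2 <- from_adapter(Cf, occ, full, n_select = 2,
                       window = c(0.02, 1.98), localization = "pipek",
                       atom_of_basis = c(1, 1, 2, 2, 3))
  Csel <- Cf[, 3:4]
  ref <- sort(eigen(t(Csel) %*% full$h1 %*% Csel,
                    symmetric = TRUE)$values)
  expect_equal(sort(eigen(act2$h1, symmetric = TRUE)$values), ref,
               tolerance = 1e-8)
  expect_silent(validate_integrals(act2))
})
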