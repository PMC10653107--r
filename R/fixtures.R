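#' Standard model fixtures
#'
#' Named ligand-field models used throughout the tests, examples and the
#' acceptance workflow.  Each fixture fixes the model parameters and the
#' electron count; the determinant space applies the conventional hole
#' limits (at most one core hole, at most one ligand hole, valence
#' unrestricted).
#'
#' * `p_hole`: bare p shell with a single hole (5 electrons in 3 orbitals,
#'   6 determinants) -- the analytic spin-orbit test case (j = 3/2 manifold
#'   lowest, gap `3 zeta / 2`).
#' * `p_to_d`: closed-shell 2p6 ground state with an empty d shell and no
#'   two-electron terms -- one-particle L-edge physics (two bands split by
#'   `3 zeta / 2`).
#' * `d2_toy`: reduced valence shell (3 orbitals, 2p6 3d2) -- small space
#'   for RIXS oracle comparisons and deconvolution checks.
#' * `ferrous`: 2p6 3d6 high-spin model (S = 2 ground state).
#' * `ferric`: 2p6 3d5 high-spin model (S = 5/2 ground state, Kramers
#'   degenerate).
#' * `ferrous_sigma`: `ferrous` extended by two filled sigma-type ligand
#'   orbitals with valence hopping (RAS1' partition, one hole allowed).
#'
#' @param name fixture name.
#' @param zeta core spin-orbit constant (eV); `NULL` takes the fixture
#'   default (8.2 eV, or as noted).
#' @param twice_ms optional `2 M_s` restriction for spin-free runs.
#' @return list with `params`, `ints` ([integral_set()]), `spec`
#'   ([ras_spec()]) and `space` ([determinant_space()]).
#' @export
model_fixture <- function(name = c("p_hole", "p_to_d", "d2_toy", "ferrous",
                                   "ferric", "ferrous_sigma"),
                          zeta = NULL, twice_ms = NULL) {
  name <- match.arg(name)
  z <- function(default) if (is.null(zeta)) default else zeta
  cf_tet <- c(0, 0, 0.65, 0.65, 0.65)  # e below t2 by 10Dq = 0.65 eV
  cfg <- switch(name,
    p_hole = list(params = ligand_field_params(
      core_orbitals = 3, valence_orbitals = 0, crystal_field = numeric(0),
      core_energy = 0, zeta_core = z(8.2), u_direct = 0, j_exchange = 0,
      core_valence_attraction = 0), n_elec = 5),
    p_to_d = list(params = ligand_field_params(
      core_orbitals = 3, valence_orbitals = 5,
      crystal_field = rep(0, 5), core_energy = -710, zeta_core = z(8.2),
      u_direct = 0, j_exchange = 0, core_valence_attraction = 0),
      n_elec = 6),
    d2_toy = list(params = ligand_field_params(
      core_orbitals = 3, valence_orbitals = 3,
      crystal_field = c(0, 0.4, 0.8), core_energy = -710,
      zeta_core = z(8.2)), n_elec = 8),
    ferrous = list(params = ligand_field_params(
      core_orbitals = 3, valence_orbitals = 5, crystal_field = cf_tet,
      core_energy = -710, zeta_core = z(8.2)), n_elec = 12),
    ferric = list(params = ligand_field_params(
      core_orbitals = 3, valence_orbitals = 5, crystal_field = cf_tet,
      core_energy = -712, zeta_core = z(8.2)), n_elec = 11),
    ferrous_sigma = list(params = ligand_field_params(
      core_orbitals = 3, valence_orbitals = 5, crystal_field = cf_tet,
      core_energy = -710, zeta_core = z(8.2), ligand_orbitals = 2,
      ligand_energy = -3, ligand_hopping = 1), n_elec = 16))
  ints <- build_model(cfg$params)
  spec <- ras_spec_from_space(ints$space, cfg$n_elec)
  space <- enumerate_space(spec, space = ints$space, twice_ms = twice_ms)
  list(name = name, params = cfg$params, ints = ints, spec = spec,
       space = space)
}

#' Write the fixture integral files
#'
#' Emits every [model_fixture()] as an extended FCIDUMP file (plus metadata
#' sidecar) into a directory.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
make_fixture_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names <- c("p_hole", "p_to_d", "d2_toy", "ferrous", "ferric",
             "ferrous_sigma")
  paths <- character(0)
  for (nm in names) {
    fx <- model_fixture(nm)
    p <- file.path(dir, paste0(nm, ".fcidump"))
    write_integrals(fx$ints, p, n_elec = fx$spec$n_elec)
    paths[nm] <- p
  }
  invisible(paths)
}
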