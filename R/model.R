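#' Ligand-field model parameters
#'
#' Parameters for the built-in model generator that emulates the 2p-3d
#' multiplet physics of a first-row transition-metal L edge: a filled core p
#' shell with spin-orbit constant `zeta_core`, a crystal-field-split valence
#' d shell with Hund exchange, core-hole/valence interaction, and
#' dipole-allowed core-valence transitions.  Optional filled ligand
#' (sigma-type) orbitals with one-electron hopping onto the valence shell
#' extend the model for charge-transfer correlation.  All energies in eV,
#' dipole factors in atomic units.
#'
#' @param core_orbitals number of core orbitals (3 = a p shell; 0 allowed).
#' @param valence_orbitals number of valence orbitals (5 = a d shell; fewer
#'   for reduced models, taken as the first elements of the d basis
#'   z2, x2-y2, xy, yz, xz).
#' @param crystal_field per-valence-orbital diagonal energies (eV).
#' @param core_energy common diagonal energy of the core orbitals (eV),
#'   typically a large negative number setting the edge position.
#' @param zeta_core spin-orbit constant of the core shell (eV).
#' @param valence_soc spin-orbit constant of the valence shell (eV).
#' @param u_direct intra-valence direct Coulomb parameter U (eV).
#' @param j_exchange intra-valence exchange (Hund) parameter J (eV).
#' @param core_valence_attraction core-valence direct Coulomb parameter
#'   (eV); a positive value makes core-hole states feel the valence
#'   occupation (the effective core-hole--electron attraction of L-edge
#'   multiplet models).
#' @param dipole_strengths scalar or `core x valence` matrix of radial
#'   dipole factors (a.u.) multiplying the tabulated p-to-d angular factors.
#' @param ligand_orbitals number of filled sigma-type ligand orbitals.
#' @param ligand_energy diagonal energy of the ligand orbitals (eV).
#' @param ligand_hopping one-electron hopping between each ligand orbital
#'   and the valence orbitals (eV); scalar or `ligand x valence` matrix.
#' @return an object of class `model_params`.
#' @export
ligand_field_params <- function(core_orbitals = 3, valence_orbitals = 5,
                                crystal_field = NULL, core_energy = -710,
                                zeta_core = 8.2, valence_soc = 0,
                                u_direct = 4, j_exchange = 0.9,
                                core_valence_attraction = 1.5,
                                dipole_strengths = 1,
                                ligand_orbitals = 0, ligand_energy = -3,
                                ligand_hopping = 1) {
  if (core_orbitals < 0 || valence_orbitals < 0 || ligand_orbitals < 0)
    stop("orbital counts must be nonnegative")
  if (core_orbitals > 3) stop("the core shell is a p shell (at most 3)")
  if (valence_orbitals > 5) stop("the valence shell is a d shell (at most 5)")
  if (is.null(crystal_field)) crystal_field <- rep(0, valence_orbitals)
  if (length(crystal_field) != valence_orbitals)
    stop("crystal_field needs one energy per valence orbital")
  p <- list(core_orbitals = core_orbitals,
            valence_orbitals = valence_orbitals,
            crystal_field = as.numeric(crystal_field),
            core_energy = core_energy, zeta_core = zeta_core,
            valence_soc = valence_soc, u_direct = u_direct,
            j_exchange = j_exchange,
            core_valence_attraction = core_valence_attraction,
            dipole_strengths = dipole_strengths,
            ligand_orbitals = ligand_orbitals,
            ligand_energy = ligand_energy,
            ligand_hopping = ligand_hopping)
  num <- unlist(p[c("crystal_field", "core_energy", "zeta_core",
                    "valence_soc", "u_direct", "j_exchange",
                    "core_valence_attraction", "ligand_energy")])
  if (any(!is.finite(num))) stop("all energy parameters must be finite")
  structure(p, class = "model_params")
}

# angular momentum matrices in the real orbital bases (imaginary,
# antisymmetric); p basis (x, y, z), d basis (z2, x2-y2, xy, yz, xz)
.L_p <- local({
  e <- function(...) matrix(complex(real = 0, imaginary = c(...)), 3, 3,
                            byrow = TRUE)
  list(x = e(0, 0, 0,   0, 0, -1,  0, 1, 0),
       y = e(0, 0, 1,   0, 0, 0,  -1, 0, 0),
       z = e(0, -1, 0,  1, 0, 0,   0, 0, 0))
})

.L_d <- local({
  s3 <- sqrt(3)
  e <- function(...) matrix(complex(real = 0, imaginary = c(...)), 5, 5,
                            byrow = TRUE)
  list(x = e(0, 0, 0, s3, 0,
             0, 0, 0, 1, 0,
             0, 0, 0, 0, -1,
             -s3, -1, 0, 0, 0,
             0, 0, 1, 0, 0),
       y = e(0, 0, 0, 0, -s3,
             0, 0, 0, 0, 1,
             0, 0, 0, 1, 0,
             0, 0, -1, 0, 0,
             s3, -1, 0, 0, 0),
       z = e(0, 0, 0, 0, 0,
             0, 0, -2, 0, 0,
             0, 2, 0, 0, 0,
             0, 0, 0, 0, 1,
             0, 0, 0, -1, 0))
})

# angular factors <p_a | r_c | d_b>, rows p (x,y,z), cols d
# (z2, x2-y2, xy, yz, xz); common radial factor omitted
.dip_pd <- local({
  s5 <- 1 / sqrt(5)
  s15 <- 1 / sqrt(15)
  m <- function(...) matrix(c(...), 3, 5, byrow = TRUE)
  list(x = m(-s15, s5, 0, 0, 0,
             0, 0, s5, 0, 0,
             0, 0, 0, 0, s5),
       y = m(0, 0, s5, 0, 0,
             -s15, -s5, 0, 0, 0,
             0, 0, 0, s5, 0),
       z = m(0, 0, 0, 0, s5,
             0, 0, 0, s5, 0,
             2 * s15, 0, 0, 0, 0))
})

.p_labels <- c("2p_x", "2p_y", "2p_z")
.d_labels <- c("3d_z2", "3d_x2y2", "3d_xy", "3d_yz", "3d_xz")

#' Build an integral set from ligand-field model parameters
#'
#' Synthesizes an [integral_set()] carrying the model Hamiltonian: diagonal
#' core/crystal-field/ligand energies and ligand-valence hopping on `h1`,
#' shell spin-orbit coupling `zeta * L_c` on `h_soc`, a direct/exchange
#' two-electron structure (`U`, Hund `J`, core-valence direct term) on
#' `eri`, and core-valence dipole matrices with the exact real-orbital
#' p-to-d angular factors.  Parameters are given in eV and converted to
#' Hartree.
#'
#' @param params a [ligand_field_params()] object.
#' @return an [integral_set()] whose orbital order is core, valence, ligand;
#'   core orbitals are tagged `RAS1`, ligand `RAS1P`, valence `RAS2`.
#' @export
build_model <- function(params) {
  stopifnot(inherits(params, "model_params"))
  nc <- params$core_orbitals
  nv <- params$valence_orbitals
  nl <- params$ligand_orbitals
  n <- nc + nv + nl
  if (n < 1L) stop("model has no orbitals")
  labels <- c(.p_labels[seq_len(nc)], .d_labels[seq_len(nv)],
              if (nl > 0) paste0("sigma_", seq_len(nl)))
  space <- orbital_space(labels,
                         partition = c(rep("RAS1", nc), rep("RAS2", nv),
                                       rep("RAS1P", nl)),
                         shell = c(rep("core", nc), rep("valence", nv),
                                   rep("ligand", nl)))
  ic <- seq_len(nc)
  iv <- nc + seq_len(nv)
  il <- nc + nv + seq_len(nl)
  ha <- ev_to_hartree

  h1 <- matrix(0, n, n)
  if (nc > 0) diag(h1)[ic] <- ha(params$core_energy)
  if (nv > 0) diag(h1)[iv] <- ha(params$crystal_field)
  if (nl > 0) {
    diag(h1)[il] <- ha(params$ligand_energy)
    hop <- params$ligand_hopping
    if (length(hop) == 1L) hop <- matrix(hop, nl, nv)
    h1[il, iv] <- ha(hop)
    h1[iv, il] <- t(ha(hop))
  }

  h_soc <- list(x = matrix(0 + 0i, n, n), y = matrix(0 + 0i, n, n),
                z = matrix(0 + 0i, n, n))
  for (cc in c("x", "y", "z")) {
    if (nc > 0 && params$zeta_core != 0)
      h_soc[[cc]][ic, ic] <- ha(params$zeta_core) *
        .L_p[[cc]][seq_len(nc), seq_len(nc)]
    if (nv > 0 && params$valence_soc != 0)
      h_soc[[cc]][iv, iv] <- ha(params$valence_soc) *
        .L_d[[cc]][seq_len(nv), seq_len(nv)]
  }

  eri <- array(0, c(n, n, n, n))
  u <- ha(params$u_direct)
  j <- ha(params$j_exchange)
  g <- ha(params$core_valence_attraction)
  for (a in iv) for (b in iv) {
    if (a == b) {
      eri[a, a, a, a] <- u
    } else {
      eri[a, a, b, b] <- u           # direct (aa|bb)
      eri[a, b, b, a] <- j           # exchange; full 8-fold orbit of K_ab
      eri[a, b, a, b] <- j
    }
  }
  if (g != 0) for (i in ic) for (a in iv) {
    eri[i, i, a, a] <- g
    eri[a, a, i, i] <- g
  }

  dip <- list(x = matrix(0, n, n), y = matrix(0, n, n),
              z = matrix(0, n, n))
  if (nc > 0 && nv > 0) {
    str <- params$dipole_strengths
    if (length(str) == 1L) str <- matrix(str, nc, nv)
    for (cc in c("x", "y", "z")) {
      blk <- .dip_pd[[cc]][seq_len(nc), seq_len(nv), drop = FALSE] * str
      dip[[cc]][ic, iv] <- blk
      dip[[cc]][iv, ic] <- t(blk)
    }
  }

  integral_set(space, e_core = 0, h1 = h1, eri = eri, h_soc = h_soc,
               dip = dip)
}
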