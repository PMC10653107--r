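# Adapter from external mean-field output: select active orbitals by
# natural-occupation window, optionally localize them within the active
# space (Pipek-style population localization), and transform the full-space
# integrals into the active basis.

read_numeric_matrix <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    as.matrix(read.table(x))
  else as.matrix(x)
}

# Pipek-style Jacobi sweeps maximizing sum_A (sum_{mu in A} C_mu^2)^2
pipek_localize <- function(C, atom_of_basis, max_sweeps = 50, tol = 1e-10) {
  n_act <- ncol(C)
  atoms <- unique(atom_of_basis)
  pop <- function(v, A) sum(v[atom_of_basis == A]^2)
  for (sweep in seq_len(max_sweeps)) {
    gain <- 0
    for (s in seq_len(n_act - 1)) for (t in (s + 1):n_act) {
      Ast <- 0
      Bst <- 0
      for (A in atoms) {
        ps <- pop(C[, s], A)
        pt <- pop(C[, t], A)
        pst <- sum(C[atom_of_basis == A, s] * C[atom_of_basis == A, t])
        Ast <- Ast + pst^2 - (ps - pt)^2 / 4
        Bst <- Bst + pst * (ps - pt)
      }
      if (Ast^2 + Bst^2 < tol^2) next
      g <- atan2(Bst, -Ast) / 4
      cs <- cos(g)
      sn <- sin(g)
      u <- C[, s] * cs + C[, t] * sn
      v <- -C[, s] * sn + C[, t] * cs
      C[, s] <- u
      C[, t] <- v
      gain <- gain + abs(g)
    }
    if (gain < tol) break
  }
  C
}

#' Build an active-space integral set from external natural orbitals
#'
#' Selects the orbitals whose natural occupations fall inside `window`,
#' checks the count against the requested RAS model size, optionally
#' localizes them within the active space (any unitary rotation confined to
#' the active space is spectrum-preserving; a Pipek-style population
#' localization is provided for interpretable particle-hole labels), and
#' transforms the full-space integrals into the active basis.  Partition
#' tags are assigned from the shell labels (`core -> RAS1`,
#' `ligand -> RAS1P`, `valence -> RAS2`).
#'
#' @param mo_coeffs full-basis orbital coefficient matrix (basis x MO), or
#'   a whitespace-delimited text file holding it.
#' @param occupations natural occupation numbers per MO, or a text file.
#' @param full_ints an [integral_set()] over the full basis.
#' @param n_select number of active orbitals the RAS model requires.
#' @param window occupation window `c(lo, hi)`; orbitals with
#'   `lo < occ < hi` are candidates.
#' @param shell shell tag per selected orbital (in selection order).
#' @param labels optional labels per selected orbital.
#' @param localization `"pipek"` or `"none"`.
#' @param atom_of_basis integer atom index per basis function (required for
#'   `"pipek"`).
#' @return an [integral_set()] over the selected (and possibly localized)
#'   active orbitals.
#' @export
from_adapter <- function(mo_coeffs, occupations, full_ints, n_select,
                         window = c(0.02, 1.98), shell = "valence",
                         labels = NULL, localization = c("none", "pipek"),
                         atom_of_basis = NULL) {
  localization <- match.arg(localization)
  C_full <- read_numeric_matrix(mo_coeffs)
  occ <- as.numeric(read_numeric_matrix(occupations))
  if (length(occ) != ncol(C_full))
    stop("one occupation number per orbital is required")
  cand <- which(occ > window[1] & occ < window[2])
  if (length(cand) != n_select)
    stop("occupation window selected ", length(cand),
         " orbitals but the RAS model requests ", n_select,
         "; candidates (index: occupation): ",
         paste(sprintf("%d: %.4f", cand, occ[cand]), collapse = ", "))
  C <- C_full[, cand, drop = FALSE]
  if (localization == "pipek") {
    if (is.null(atom_of_basis))
      stop("pipek localization needs atom_of_basis")
    C <- pipek_localize(C, atom_of_basis)
  }
  n <- n_select
  shell <- rep_len(shell, n)
  if (is.null(labels))
    labels <- paste0(shell, "_", stats::ave(seq_len(n), shell,
                                            FUN = seq_along))
  partition <- c(core = "RAS1", ligand = "RAS1P",
                 valence = "RAS2")[shell]
  space <- orbital_space(labels, partition, shell)
  tr1 <- function(m) Conj(t(C)) %*% m %*% C
  eri <- full_ints$eri
  eri <- apply_mode(eri, C, 1, conjugate = TRUE)
  eri <- apply_mode(eri, C, 2, conjugate = FALSE)
  eri <- apply_mode(eri, C, 3, conjugate = TRUE)
  eri <- apply_mode(eri, C, 4, conjugate = FALSE)
  integral_set(space, e_core = full_ints$e_core, h1 = Re_if_real(tr1(full_ints$h1)),
               eri = Re_if_real(eri),
               h_soc = lapply(full_ints$h_soc, tr1),
               dip = lapply(full_ints$dip, function(m) Re_if_real(tr1(m))))
}
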