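#' Active orbital space
#'
#' Describes the spatial active orbitals: a unique text label per orbital, a
#' RAS partition tag (`"RAS1"`, `"RAS1P"`, `"RAS2"`) controlling the hole
#' restrictions, and a shell tag (`"core"`, `"valence"`, `"ligand"`) used by
#' the model generator, the dipole operator, and the deconvolution labels.
#'
#' @param labels character vector of unique orbital labels, e.g. `"2p_x"`,
#'   `"3d_z2"`, `"sigma_1"`.
#' @param partition character vector, one of `RAS1`, `RAS1P`, `RAS2` per
#'   orbital.
#' @param shell character vector, one of `core`, `valence`, `ligand` per
#'   orbital.
#' @return an object of class `orbital_space`.
#' @export
orbital_space <- function(labels, partition, shell) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 1L) stop("orbital_space needs at least one orbital")
  if (anyDuplicated(labels)) stop("orbital labels must be unique")
  partition <- match.arg(as.character(partition), c("RAS1", "RAS1P", "RAS2"),
                         several.ok = TRUE)
  shell <- match.arg(as.character(shell), c("core", "valence", "ligand"),
                     several.ok = TRUE)
  partition <- rep_len(partition, n)
  shell <- rep_len(shell, n)
  if (length(partition) != n || length(shell) != n)
    stop("partition and shell must have one entry per orbital")
  structure(list(n_orb = n, labels = labels, partition = partition,
                 shell = shell),
            class = "orbital_space")
}

#' @export
print.orbital_space <- function(x, ...) {
  cat("<orbital_space> ", x$n_orb, " spatial orbitals\n", sep = "")
  print(data.frame(label = x$labels, partition = x$partition,
                   shell = x$shell))
  invisible(x)
}

orbitals_in_shell <- function(space, shell) which(space$shell == shell)
orbitals_in_partition <- function(space, partition) {
  which(space$partition == partition)
}
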