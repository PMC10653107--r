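#' Restricted-active-space specification
#'
#' Defines the determinant basis: an ordered list of partitions (disjoint
#' sets of spatial orbitals, each with a maximum hole count over its spin
#' orbitals, `Inf` for unrestricted) and the total electron count.  The
#' classic L-edge setup is a core partition with at most one hole, an
#' optional sigma-bonding partition with at most one hole, and an
#' unrestricted valence partition.
#'
#' @param partitions list of `list(orbitals = <spatial indices>,
#'   max_holes = <count or Inf>)`.
#' @param n_elec total number of active electrons.
#' @param n_orb total number of spatial orbitals; defaults to the union of
#'   the partitions, which must cover `1:n_orb` disjointly.
#' @return an object of class `ras_spec`.
#' @export
ras_spec <- function(partitions, n_elec, n_orb = NULL) {
  orbs <- unlist(lapply(partitions, `[[`, "orbitals"))
  if (anyDuplicated(orbs)) stop("partitions must be disjoint")
  if (is.null(n_orb)) n_orb <- max(orbs)
  if (!setequal(orbs, seq_len(n_orb)))
    stop("partitions must cover every orbital 1..n_orb")
  partitions <- lapply(partitions, function(p) {
    mh <- if (is.null(p$max_holes)) Inf else p$max_holes
    if (mh < 0) stop("max_holes must be nonnegative")
    list(orbitals = as.integer(sort(p$orbitals)),
         max_holes = min(mh, 2 * length(p$orbitals)))
  })
  if (n_elec < 0 || n_elec > 2 * n_orb)
    stop("n_elec must lie in [0, 2*n_orb]")
  structure(list(partitions = partitions, n_elec = as.integer(n_elec),
                 n_orb = as.integer(n_orb)),
            class = "ras_spec")
}

#' RAS specification from orbital-space partition tags
#'
#' Builds a [ras_spec()] using the `RAS1`/`RAS1P`/`RAS2` tags of an
#' [orbital_space()], with the conventional hole limits (one hole in each
#' restricted partition, valence unrestricted).
#'
#' @param space an [orbital_space()].
#' @param n_elec total active electrons.
#' @param max_holes named vector of hole limits per partition tag.
#' @return a [ras_spec()].
#' @export
ras_spec_from_space <- function(space, n_elec,
                                max_holes = c(RAS1 = 1, RAS1P = 1,
                                              RAS2 = Inf)) {
  parts <- list()
  for (tag in c("RAS1", "RAS1P", "RAS2")) {
    idx <- orbitals_in_partition(space, tag)
    if (length(idx))
      parts[[length(parts) + 1L]] <- list(orbitals = idx,
                                          max_holes = max_holes[[tag]])
  }
  ras_spec(parts, n_elec, n_orb = space$n_orb)
}

# spin orbitals (1-based) of a spatial orbital set, alpha block then beta
spin_orbitals <- function(orbitals, n_orb) c(orbitals, orbitals + n_orb)

#' Enumerate the restricted determinant space
#'
#' Produces every determinant (spin-orbital occupation bitstring) with the
#' requested electron count that satisfies all per-partition hole limits, in
#' a canonical, reproducible order (lexicographic on the bitstring with the
#' alpha block most significant, alpha of orbital 1 first).  Because the
#' spin-orbit operator mixes S_z sectors, no S_z restriction is applied
#' unless `twice_ms` is given (useful for spin-free runs).
#'
#' @param spec a [ras_spec()].
#' @param space optional [orbital_space()] carried along for labels.
#' @param twice_ms optional integer `2*M_s` filter.
#' @return an object of class `determinant_space` with elements `spec`,
#'   `dets` (numeric occupation words), `n_orb`, `n_spin`, `n_elec`.
#' @export
enumerate_space <- function(spec, space = NULL, twice_ms = NULL) {
  stopifnot(inherits(spec, "ras_spec"))
  n_orb <- spec$n_orb
  n_spin <- 2L * n_orb
  if (n_spin > 52L) stop("at most 26 spatial orbitals are supported")
  parts <- spec$partitions
  caps <- vapply(parts, function(p) 2L * length(p$orbitals), integer(1))
  # minimum electrons per partition implied by its hole limit
  lo <- mapply(function(p, cap) {
    mh <- p$max_holes
    if (is.finite(mh)) max(0L, cap - as.integer(mh)) else 0L
  }, parts, caps)
  compositions <- list(integer(0))
  totals <- 0L
  for (k in seq_along(parts)) {
    new <- list()
    newtot <- integer(0)
    for (ci in seq_along(compositions)) {
      rem <- spec$n_elec - totals[ci]
      e_min <- max(lo[k], rem - sum(caps[-seq_len(k)]))
      e_max <- min(caps[k], rem)
      if (e_max < e_min) next
      for (e in e_min:e_max) {
        new[[length(new) + 1L]] <- c(compositions[[ci]], e)
        newtot <- c(newtot, totals[ci] + e)
      }
    }
    compositions <- new
    totals <- newtot
  }
  keep <- totals == spec$n_elec
  compositions <- compositions[keep]
  if (!length(compositions))
    stop("infeasible RAS specification: no determinant satisfies the ",
         "electron count and hole limits")

  part_spin <- lapply(parts, function(p) spin_orbitals(p$orbitals, n_orb))
  codes <- numeric(0)
  for (comp in compositions) {
    block_codes <- lapply(seq_along(parts), function(k) {
      so <- part_spin[[k]]
      e <- comp[k]
      if (e == 0L) return(0)
      if (e == length(so)) return(sum(2^(so - 1)))
      ch <- utils::combn(so, e)
      colSums(matrix(2^(ch - 1), nrow = e))
    })
    acc <- 0
    for (bc in block_codes) acc <- as.vector(outer(acc, bc, `+`))
    codes <- c(codes, acc)
  }
  if (!is.null(twice_ms)) {
    bits <- cpp_det_bits(codes, n_spin)
    na <- rowSums(bits[, seq_len(n_orb), drop = FALSE])
    nb <- rowSums(bits[, n_orb + seq_len(n_orb), drop = FALSE])
    codes <- codes[na - nb == twice_ms]
    if (!length(codes))
      stop("infeasible RAS specification: empty S_z sector")
  }
  # canonical order: alpha block most significant, orbital 1 first
  bits <- cpp_det_bits(codes, n_spin)
  key <- as.vector(bits %*% 2^(n_spin - seq_len(n_spin)))
  ord <- order(key)
  codes <- codes[ord]
  structure(list(spec = spec, space = space, dets = codes,
                 n_orb = n_orb, n_spin = n_spin, n_elec = spec$n_elec,
                 twice_ms = twice_ms, cache = new.env(parent = emptyenv())),
            class = "determinant_space")
}

#' @export
print.determinant_space <- function(x, ...) {
  cat("<determinant_space> ", length(x$dets), " determinants, ",
      x$n_elec, " electrons in ", x$n_orb, " orbitals\n", sep = "")
  invisible(x)
}

#' @export
length.determinant_space <- function(x) length(x$dets)

#' Position of determinants in the canonical order
#'
#' @param space a [determinant_space()].
#' @param dets numeric occupation words.
#' @return integer indices (NA when not in the space).
#' @export
det_index <- function(space, dets) match(dets, space$dets)

#' Occupation bitstring of a determinant
#'
#' @param det numeric occupation word(s).
#' @param n_spin number of spin orbitals.
#' @return character bitstrings, alpha block first (orbital 1 leftmost).
#' @export
det_to_string <- function(det, n_spin) {
  bits <- cpp_det_bits(det, n_spin)
  apply(bits, 1, paste0, collapse = "")
}

#' Apply an elementary excitation to a determinant
#'
#' Applies `a^+_create a_annihilate` (1-based spin-orbital indices, alpha
#' block then beta block) with the fermionic phase of the package ordering
#' convention.
#'
#' @param det numeric occupation word.
#' @param create,annihilate spin-orbital indices.
#' @param n_spin number of spin orbitals (for range checking).
#' @return `list(det = <word>, sign = +-1)` or `NULL` when the operator
#'   annihilates the determinant.
#' @export
excitation_apply <- function(det, create, annihilate, n_spin = 52L) {
  if (create < 1 || create > n_spin || annihilate < 1 ||
      annihilate > n_spin)
    stop("spin-orbital index out of range")
  r <- cpp_excite(det, as.integer(create), as.integer(annihilate))
  if (r[2] == 0) return(NULL)
  list(det = r[1], sign = as.integer(r[2]))
}

#' Single and double excitations connecting a determinant to a space
#'
#' Enumerates every single and double excitation of `det` that lands inside
#' the restricted space, with the fermionic sign and the spin-orbital
#' indices of the excitation.
#'
#' @param det numeric occupation word (must be a member of `space`).
#' @param space a [determinant_space()].
#' @return a data.frame with columns `index`, `sign`, `annihilate1`,
#'   `create1`, `annihilate2`, `create2` (`NA` for singles).
#' @export
connections <- function(det, space) {
  if (is.na(det_index(space, det)))
    stop("determinant is not a member of the space")
  as.data.frame(cpp_connections(det, space$dets, space$n_spin))
}

#' Write a determinant space as a text dump
#'
#' One bitstring per line in canonical order, preceded by header comments
#' recording the RAS specification.
#'
#' @param space a [determinant_space()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_determinant_space <- function(space, path) {
  hdr <- c(sprintf("# n_orb %d n_elec %d", space$n_orb, space$n_elec),
           vapply(space$spec$partitions, function(p)
             sprintf("# partition orbitals %s max_holes %s",
                     paste(p$orbitals, collapse = ","),
                     format(p$max_holes)), character(1)))
  writeLines(c(hdr, det_to_string(space$dets, space$n_spin)), path)
  invisible(path)
}
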