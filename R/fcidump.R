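# Extended FCIDUMP dialect.
#
# Standard FCIDUMP header (&FCI NORB=..., NELEC=..., MS2=..., ORBSYM=...,
# ISYM=... &END) and body records "value i j k l":
#   * k,l > 0           : two-electron integral (ij|kl), chemist notation,
#                         one entry per 8-fold symmetry orbit
#   * k = l = 0, i,j > 0: one-electron integral h1[i,j] (i >= j stored)
#   * i = j = k = l = 0 : core energy
# Extension sections are introduced by sentinels "&SOC x|y|z" (records
# "im_value i j": the imaginary part of the antisymmetric spin-orbit
# matrix, i < j stored) and "&DIP x|y|z" (records "value i j", symmetric,
# i >= j stored).  Orbital labels, partition and shell tags live in a YAML
# sidecar "<path>.meta.yaml".

fcid_fmt <- function(x) formatC(x, format = "e", digits = 16)

#' Write an integral set in the extended FCIDUMP format
#'
#' Deterministic output: fixed entry ordering (row-major over the unique
#' index tuples) and fixed float format; [read_integrals()] inverts it
#' exactly.  The orbital metadata is written to `<path>.meta.yaml`.
#'
#' @param ints an [integral_set()].
#' @param path output file path.
#' @param n_elec electron count recorded in the header (metadata only).
#' @param ms2 `2*M_s` recorded in the header (metadata only).
#' @return `path`, invisibly.
#' @export
write_integrals <- function(ints, path, n_elec = 0, ms2 = 0) {
  n <- ints$space$n_orb
  lines <- c(sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n, n_elec, ms2),
             sprintf(" ORBSYM=%s", paste(rep("1,", n), collapse = "")),
             " ISYM=1,", "&END")
  rec <- character(0)
  # two-electron: one entry per symmetry-unique orbit, i>=j, k>=l, ij>=kl
  for (i in seq_len(n)) for (j in seq_len(i))
    for (k in seq_len(i)) for (l in seq_len(k)) {
      if ((i * (i - 1)) / 2 + j < (k * (k - 1)) / 2 + l) next
      v <- ints$eri[i, j, k, l]
      if (v != 0)
        rec <- c(rec, sprintf("%s %d %d %d %d", fcid_fmt(v), i, j, k, l))
    }
  for (i in seq_len(n)) for (j in seq_len(i)) {
    v <- ints$h1[i, j]
    if (v != 0)
      rec <- c(rec, sprintf("%s %d %d 0 0", fcid_fmt(v), i, j))
  }
  rec <- c(rec, sprintf("%s 0 0 0 0", fcid_fmt(ints$e_core)))
  for (comp in c("x", "y", "z")) {
    m <- ints$h_soc[[comp]]
    ent <- character(0)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      v <- Im(m[i, j])
      if (v != 0) ent <- c(ent, sprintf("%s %d %d", fcid_fmt(v), i, j))
    }
    if (length(ent)) rec <- c(rec, paste("&SOC", comp), ent)
  }
  for (comp in c("x", "y", "z")) {
    m <- ints$dip[[comp]]
    ent <- character(0)
    for (i in seq_len(n)) for (j in seq_len(i)) {
      v <- m[i, j]
      if (v != 0) ent <- c(ent, sprintf("%s %d %d", fcid_fmt(v), i, j))
    }
    if (length(ent)) rec <- c(rec, paste("&DIP", comp), ent)
  }
  writeLines(c(lines, rec), path)
  meta <- list(orbitals = lapply(seq_len(n), function(k)
    list(index = k, label = ints$space$labels[k],
         partition = ints$space$partition[k],
         shell = ints$space$shell[k])))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read an extended FCIDUMP integral file
#'
#' Parses the dialect written by [write_integrals()], reconstructing all
#' symmetry-redundant entries (8-fold for the two-electron integrals,
#' symmetric completion for `h1`/dipoles, antisymmetric completion for the
#' spin-orbit matrices).  Conflicting duplicate entries and out-of-range
#' indices raise parse errors naming the offending line.
#'
#' @param path input file path.
#' @param meta_path optional sidecar metadata path (defaults to
#'   `<path>.meta.yaml`; when absent, generic labels are used).
#' @return an [integral_set()].
#' @export
read_integrals <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  perr <- function(ln, msg) stop("parse error at line ", ln, ": ", msg)
  # ---- header ----
  hstart <- grep("^\\s*&FCI", lines)
  if (!length(hstart)) perr(1, "missing &FCI header")
  hend <- grep("&END|/\\s*$", lines)
  hend <- hend[hend >= hstart[1]][1]
  if (is.na(hend)) perr(hstart[1], "unterminated &FCI header")
  header <- paste(lines[hstart[1]:hend], collapse = " ")
  get_int <- function(key) {
    m <- regmatches(header, regexpr(paste0(key, "\\s*=\\s*-?[0-9]+"), header))
    if (!length(m)) perr(hstart[1], paste0("missing ", key, " in header"))
    as.integer(sub(paste0(key, "\\s*=\\s*"), "", m))
  }
  n <- get_int("NORB")
  if (n < 1) perr(hstart[1], "NORB must be >= 1")
  h1 <- matrix(0, n, n)
  eri <- array(0, c(n, n, n, n))
  h_soc <- list(x = matrix(0 + 0i, n, n), y = matrix(0 + 0i, n, n),
                z = matrix(0 + 0i, n, n))
  dip <- list(x = matrix(0, n, n), y = matrix(0, n, n),
              z = matrix(0, n, n))
  e_core <- 0
  seen_ecore <- FALSE
  section <- "main"
  comp <- NULL
  set_checked <- function(cur, v, ln) {
    if (cur != 0 && abs(cur - v) > 1e-12 * max(1, abs(v)))
      perr(ln, "conflicting duplicate entry")
    v
  }
  for (ln in seq_along(lines)) {
    if (ln <= hend) next
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    sent <- regmatches(line, regexec("^&(SOC|DIP)\\s+([xyz])$", line))[[1]]
    if (length(sent)) {
      section <- sent[2]
      comp <- sent[3]
      next
    }
    toks <- strsplit(line, "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(toks[1]))
    idx <- suppressWarnings(as.integer(toks[-1]))
    if (is.na(val) || anyNA(idx)) perr(ln, "malformed record")
    if (section == "main") {
      if (length(idx) != 4) perr(ln, "expected 'value i j k l'")
      i <- idx[1]; j <- idx[2]; k <- idx[3]; l <- idx[4]
      if (any(idx < 0) || any(idx > n)) perr(ln, "orbital index out of range")
      if (all(idx == 0)) {
        if (seen_ecore && abs(e_core - val) > 1e-12 * max(1, abs(val)))
          perr(ln, "conflicting duplicate core-energy entry")
        e_core <- val
        seen_ecore <- TRUE
      } else if (k == 0 && l == 0) {
        if (i == 0 || j == 0) perr(ln, "bad one-electron indices")
        h1[i, j] <- set_checked(h1[i, j], val, ln)
        h1[j, i] <- set_checked(if (i == j) 0 else h1[j, i], val, ln)
      } else {
        if (any(idx == 0)) perr(ln, "bad two-electron indices")
        orbit <- unique(list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                             c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                             c(k, l, j, i), c(l, k, j, i)))
        for (o in orbit) {
          cur <- eri[o[1], o[2], o[3], o[4]]
          if (cur != 0 && abs(cur - val) > 1e-12 * max(1, abs(val)))
            perr(ln, "conflicting duplicate two-electron entry")
          eri[o[1], o[2], o[3], o[4]] <- val
        }
      }
    } else if (section == "SOC") {
      if (length(idx) != 2) perr(ln, "expected 'im_value i j'")
      i <- idx[1]; j <- idx[2]
      if (any(idx < 1) || any(idx > n)) perr(ln, "orbital index out of range")
      if (i == j && val != 0) perr(ln, "nonzero diagonal SOC entry")
      m <- h_soc[[comp]]
      if (Im(m[i, j]) != 0 && abs(Im(m[i, j]) - val) > 1e-12)
        perr(ln, "conflicting duplicate SOC entry")
      m[i, j] <- complex(real = 0, imaginary = val)
      m[j, i] <- complex(real = 0, imaginary = -val)
      h_soc[[comp]] <- m
    } else {  # DIP
      if (length(idx) != 2) perr(ln, "expected 'value i j'")
      i <- idx[1]; j <- idx[2]
      if (any(idx < 1) || any(idx > n)) perr(ln, "orbital index out of range")
      m <- dip[[comp]]
      m[i, j] <- set_checked(m[i, j], val, ln)
      m[j, i] <- set_checked(if (i == j) 0 else m[j, i], val, ln)
      dip[[comp]] <- m
    }
  }
  if (is.null(meta_path)) meta_path <- paste0(path, ".meta.yaml")
  space <- if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    ord <- order(vapply(meta$orbitals, `[[`, numeric(1), "index"))
    orbs <- meta$orbitals[ord]
    orbital_space(vapply(orbs, `[[`, character(1), "label"),
                  vapply(orbs, `[[`, character(1), "partition"),
                  vapply(orbs, `[[`, character(1), "shell"))
  } else {
    orbital_space(paste0("orb", seq_len(n)), rep("RAS2", n),
                  rep("valence", n))
  }
  integral_set(space, e_core = e_core, h1 = h1, eri = eri, h_soc = h_soc,
               dip = dip)
}

#' Count of symmetry-unique nonzero two-electron integrals
#'
#' The number of `(ij|kl)` entries [write_integrals()] emits.
#'
#' @param ints an [integral_set()].
#' @return integer count.
#' @export
eri_unique_count <- function(ints) {
  n <- ints$space$n_orb
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(i))
    for (k in seq_len(i)) for (l in seq_len(k)) {
      if ((i * (i - 1)) / 2 + j < (k * (k - 1)) / 2 + l) next
      if (ints$eri[i, j, k, l] != 0) cnt <- cnt + 1L
    }
  cnt
}
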