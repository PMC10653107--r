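#' Write a state vector as tab-separated text
#'
#' Columns `det` (occupation bitstring), `re`, `im`; header comments record
#' the space dimensions and optional metadata (e.g. an energy).  Used to
#' pass ground states and correction vectors between CLI stages.
#'
#' @param v a [state_vector()].
#' @param path output file.
#' @param meta optional named list of scalar metadata.
#' @return `path`, invisibly.
#' @export
write_state <- function(v, path, meta = list()) {
  space <- v$space
  hdr <- c(sprintf("# n_orb\t%d", space$n_orb),
           sprintf("# n_elec\t%d", space$n_elec))
  for (key in names(meta))
    hdr <- c(hdr, sprintf("# %s\t%s", key, format(meta[[key]],
                                                  digits = 17)))
  df <- data.frame(det = det_to_string(space$dets, space$n_spin),
                   re = Re(v$amp), im = Im(v$amp))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(df, digits = 17), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a state vector written by [write_state()]
#'
#' The determinant bitstrings are checked against the canonical order of
#' `space`.
#'
#' @param path input file.
#' @param space the [determinant_space()] the amplitudes refer to.
#' @return a [state_vector()].
#' @export
read_state <- function(path, space) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric", "numeric"))
  expected <- det_to_string(space$dets, space$n_spin)
  if (!identical(df$det, expected))
    stop("state file does not match the canonical determinant order ",
         "of the space")
  state_vector(space, complex(real = df$re, imaginary = df$im))
}
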