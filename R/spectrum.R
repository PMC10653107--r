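#' Frequency grid for spectra
#'
#' Ordered energies (eV) with the Lorentzian broadenings: `eta` for the
#' absorption (core-excited) resolvent and `eta_prime` for the RIXS
#' energy-loss resolvent.  Defaults follow the usual L-edge practice
#' (`eta = 0.3` eV, `eta_prime = 0.1` eV).
#'
#' @param values strictly increasing energies (eV).
#' @param eta Lorentzian broadening of the absorption resolvent (eV, > 0).
#' @param eta_prime broadening of the loss resolvent (eV, > 0); only used
#'   for RIXS.
#' @return an object of class `frequency_grid`.
#' @export
frequency_grid <- function(values, eta = 0.3, eta_prime = 0.1) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(diff(values) <= 0))
    stop("grid energies must be strictly increasing")
  if (eta <= 0 || eta_prime <= 0) stop("broadenings must be positive")
  structure(list(values = values, eta = eta, eta_prime = eta_prime),
            class = "frequency_grid")
}

#' @rdname frequency_grid
#' @param from,to,by grid limits and step (eV).
#' @export
frequency_grid_seq <- function(from, to, by, eta = 0.3, eta_prime = 0.1) {
  frequency_grid(seq(from, to, by = by), eta = eta, eta_prime = eta_prime)
}

new_spectrum <- function(grid, total, components = NULL, meta = list()) {
  structure(list(grid = grid, total = total, components = components,
                 meta = meta),
            class = "xray_spectrum")
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat("<xray_spectrum> ", length(x$grid$values), " points [",
      min(x$grid$values), ", ", max(x$grid$values), "] eV, max total ",
      format(max(x$total)), "\n", sep = "")
  if (!is.null(x$components))
    cat("  components: ", paste(names(x$components), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Incident energy at the absorption maximum of a window
#'
#' Picks the grid energy with maximum total intensity inside
#' `window = c(lo, hi)` (the L3 band, say); ties break toward lower energy.
#'
#' @param spec an XAS `xray_spectrum`.
#' @param window length-2 numeric energy interval (eV).
#' @return the selected energy (eV).
#' @export
select_omega_ex <- function(spec, window) {
  v <- spec$grid$values
  keep <- which(v >= window[1] & v <= window[2])
  if (!length(keep)) stop("window does not intersect the grid")
  i <- keep[which.max(spec$total[keep])]  # which.max takes the first: low-E tie rule
  v[i]
}

#' Normalize a spectrum to a window maximum
#'
#' Scales all intensities (total and every component) so that the maximum
#' of the total inside `window` equals `value` -- the convention used to
#' compare L-edge spectra (XAS maximum to 1, RIXS maxima to fixed
#' fractions).  The scale factor is recorded in `meta$scale`.
#'
#' @param spec an `xray_spectrum`.
#' @param value target maximum.
#' @param window energy window (eV); defaults to the full grid.
#' @return the scaled `xray_spectrum`.
#' @export
normalize_spectrum <- function(spec, value = 1, window = NULL) {
  v <- spec$grid$values
  keep <- if (is.null(window)) seq_along(v)
          else which(v >= window[1] & v <= window[2])
  m <- max(spec$total[keep])
  if (m <= 0) stop("spectrum is zero in the normalization window")
  s <- value / m
  spec$total <- spec$total * s
  if (!is.null(spec$components))
    spec$components <- lapply(spec$components, `*`, s)
  spec$meta$scale <- c(spec$meta$scale, s)
  spec
}

#' Check a deconvolution sum rule
#'
#' The sum of the deconvolved components must reproduce the total spectrum
#' pointwise.  Returns the maximum pointwise deviation relative to the
#' spectrum maximum.
#'
#' @param spec an `xray_spectrum` carrying components (or a total plus an
#'   explicit `components` list).
#' @param components optional list of component intensity vectors; defaults
#'   to `spec$components`.
#' @param threshold pass threshold for `ok`.
#' @return list with `max_rel_dev` and logical `ok`.
#' @export
sumrule_check <- function(spec, components = NULL, threshold = 1e-8) {
  if (is.null(components)) components <- spec$components
  if (is.null(components)) stop("no components to check")
  lens <- vapply(components, length, integer(1))
  if (any(lens != length(spec$total)))
    stop("component grids do not match the total")
  s <- Reduce(`+`, components)
  dev <- max(abs(s - spec$total)) / max(spec$total, 1e-300)
  list(max_rel_dev = dev, ok = dev <= threshold)
}

#' Write a spectrum as tab-separated text
#'
#' Columns: `energy_eV`, `total`, then one column per component.  Header
#' comment lines record the broadenings and metadata (`omega_ex`,
#' normalization, ground-manifold size).
#'
#' @param spec an `xray_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  meta <- spec$meta
  hdr <- c(sprintf("# eta_eV\t%.10g", spec$grid$eta),
           sprintf("# eta_prime_eV\t%.10g", spec$grid$eta_prime))
  for (key in names(meta)) {
    val <- meta[[key]]
    if (is.numeric(val))
      hdr <- c(hdr, sprintf("# %s\t%s", key,
                            paste(format(val, digits = 12), collapse = "\t")))
    else hdr <- c(hdr, sprintf("# %s\t%s", key,
                               paste(as.character(val), collapse = "\t")))
  }
  df <- data.frame(energy_eV = spec$grid$values, total = spec$total,
                   check.names = FALSE)
  for (key in names(spec$components)) df[[key]] <- spec$components[[key]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path input file.
#' @return an `xray_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   check.names = FALSE)
  meta <- list()
  eta <- 0.3
  etap <- 0.1
  for (h in hdr) {
    parts <- strsplit(sub("^#\\s*", "", h), "\t")[[1]]
    key <- parts[1]
    val <- parts[-1]
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    if (key == "eta_eV") eta <- val
    else if (key == "eta_prime_eV") etap <- val
    else meta[[key]] <- val
  }
  comp_names <- setdiff(names(df), c("energy_eV", "total"))
  comps <- if (length(comp_names)) as.list(df[comp_names]) else NULL
  new_spectrum(frequency_grid(df$energy_eV, eta = eta, eta_prime = etap),
               df$total, components = comps, meta = meta)
}

# trapezoidal integral of a channel over the grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Integrated channel percentages
#'
#' Trapezoidal integral of each component over the grid divided by the
#' integrated total, in percent.
#'
#' @param spec an `xray_spectrum` with components.
#' @return named numeric vector of percentages.
#' @export
channel_percentages <- function(spec) {
  if (is.null(spec$components)) stop("spectrum has no components")
  tot <- trapz(spec$grid$values, spec$total)
  vapply(spec$components, function(y)
    100 * trapz(spec$grid$values, y) / tot, numeric(1))
}
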