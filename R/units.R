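#' Energy unit conversion
#'
#' All internal energies are in Hartree; user-facing energies (grids, model
#' parameters, spectra) are in eV.  The conversion constant is the 2018
#' CODATA value 27.211386245988 eV/Hartree.
#'
#' @param x numeric energies.
#' @return converted energies.
#' @export
ev_to_hartree <- function(x) x / 27.211386245988

#' @rdname ev_to_hartree
#' @export
hartree_to_ev <- function(x) x * 27.211386245988
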