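# Physical constants pinned to CODATA 2018 so unit conversions are bit-stable.

#' Physical constants used throughout thinmem
#'
#' MD units are used everywhere: lengths in nm, time in ps, energies in
#' kJ/mol, temperature in K, forces in kJ mol^-1 nm^-1.
#'
#' @format A list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant as molar gas constant, kJ mol^-1 K^-1.}
#'   \item{NA_avogadro}{Avogadro constant, mol^-1.}
#' }
#' @export
thinmem_constants <- list(
  kB = 8.31446261815324e-3,     # kJ mol^-1 K^-1
  NA_avogadro = 6.02214076e23   # mol^-1
)
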