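#' Physical constants and unit conversions
#'
#' All energies inside the package are kcal/mol, distances Angstrom,
#' times ps, temperatures K. Kilojoule inputs are converted once at the
#' boundary.
#'
#' @name units
NULL

#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCAL <- 0.0019872041

#' Convert kJ/mol to kcal/mol
#' @param x energy in kJ/mol
#' @return energy in kcal/mol
#' @export
kj_to_kcal <- function(x) x / 4.184

#' Convert kcal/mol to kJ/mol
#' @param x energy in kcal/mol
#' @return energy in kJ/mol
#' @export
kcal_to_kj <- function(x) x * 4.184
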