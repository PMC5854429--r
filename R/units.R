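#' Boltzmann constant in kcal/mol/K
#'
#' Internal unit system: energies in kcal/mol, lengths in Angstrom, times in
#' ps.  Masses are carried in the derived unit kcal/mol * ps^2 / A^2 so that
#' no conversion factor appears in the equations of motion; the default mass
#' of 1 gives a thermal velocity sqrt(kB*T) ~ 0.77 A/ps at 300 K.
#'
#' @format A length-one numeric, 0.0019872 kcal/mol/K.
#' @export
kB_kcal <- 0.0019872

#' Thermal energy kB*T
#'
#' @param temperature Temperature in Kelvin.
#' @return kB*T in kcal/mol (about 0.596 kcal/mol at 300 K).
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  kB_kcal * temperature
}
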