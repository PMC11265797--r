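#' Physical constants and unit conventions
#'
#' Internal units throughout the package are nm for distances, ps for times and
#' kcal/mol for energies. Bias force constants supplied in kJ/mol/unit^2 (the
#' convention of most MD engines) are converted on input with 1 kcal = 4.184 kJ
#' exactly. The default temperature is 310 K.
#'
#' @name units
NULL

#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCAL <- 1.987204259e-3

#' Default simulation temperature (K)
#' @export
DEFAULT_TEMPERATURE <- 310

#' Standard-state volume per molecule at 1 M, in nm^3
#' @export
STANDARD_VOLUME_NM3 <- 1.660539

#' Thermal energy kT in kcal/mol
#'
#' @param temperature temperature in K
#' @return kT in kcal/mol
#' @export
kT_kcal <- function(temperature = DEFAULT_TEMPERATURE) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KCAL * temperature
}

#' Convert kJ/mol to kcal/mol (exact thermochemical calorie)
#' @param x energies or force constants in kJ/mol units
#' @export
kj_to_kcal <- function(x) x / 4.184

#' Convert kcal/mol to kJ/mol
#' @param x energies in kcal/mol units
#' @export
kcal_to_kj <- function(x) x * 4.184

#' RT ln(10) in kcal/mol, the free energy of one pKa unit
#'
#' @param temperature temperature in K
#' @return RT ln 10 in kcal/mol (1.4186 at 310 K)
#' @export
rt_ln10 <- function(temperature = DEFAULT_TEMPERATURE) {
  kT_kcal(temperature) * log(10)
}
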