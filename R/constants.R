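#' Thermal energy in piconewton-nanometres
#'
#' Boltzmann's constant is 1.380649e-23 J/K, i.e. 1.380649e-2 pN nm / K.
#' At the assay temperature of 298.15 K (25 degrees C) this gives
#' kT = 4.116 pN nm, the single value used throughout the package for trap
#' calibration, detachment hazards and Bell-bond fits.
#'
#' @param temperature_K temperature in kelvin.
#' @return thermal energy kT in pN nm.
#' @examples
#' kt_pN_nm(298.15) # 4.116
#' @export
kt_pN_nm <- function(temperature_K = 298.15) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  1.380649e-2 * temperature_K
}
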