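#' Physical constants for permeation calculations
#'
#' Bundle of constants used throughout the package: Faraday constant,
#' gas constant, absolute temperature, molar volume of water and the ion
#' valence. Recordings emulated by this package were made at room
#' temperature, so the default temperature is 295 K (about 22 C).
#'
#' @param temperature absolute temperature in kelvin. Default 295 K.
#' @param v_w molar volume of water in m^3/mol. Default 1.807e-5.
#' @param z_ion valence of the permeant ion (+1 for K+).
#' @param water_density density of water in kg/L, used to convert an
#'   osmolality (osmol/kg) into an osmolarity (osmol/L) when computing the
#'   osmotic pressure. Default 1.
#' @return a named list with elements `F` (C/mol), `R` (J/mol/K), `T` (K),
#'   `v_w` (m^3/mol), `z_ion`, `water_density` (kg/L).
#' @examples
#' consts <- physConstants()
#' consts$F / (consts$R * consts$T) # 1/volt scale of voltage dependence
#' @export
physConstants <- function(temperature = 295, v_w = 1.807e-5, z_ion = 1,
                          water_density = 1) {
  stopifnot(temperature > 0, v_w > 0, water_density > 0)
  list(F = 96485.33212, R = 8.314462618, T = temperature,
       v_w = v_w, z_ion = z_ion, water_density = water_density)
}

## elementary charge in coulomb
.e_charge <- 1.602176634e-19
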