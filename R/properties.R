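## Temperature-dependent material properties of water, air and water vapor.
## Closed forms are standard engineering correlations, valid over 0-100 degC,
## which covers the isothermal operating points (45 and 68 degC).

#' Dynamic viscosity of liquid water
#'
#' Vogel-type correlation, accurate to ~1% between 0 and 100 degC.
#'
#' @param temperature Temperature in degC.
#' @return Viscosity in Pa s.
#' @export
#' @examples
#' water_viscosity(45) # ~5.9e-4 Pa s
water_viscosity <- function(temperature) {
  TK <- temperature + 273.15
  2.414e-5 * 10^(247.8 / (TK - 140))
}

#' Density of liquid water
#'
#' Quadratic fit around the density maximum; adequate (<0.1%) for 0-100 degC.
#'
#' @inheritParams water_viscosity
#' @return Density in kg/m^3.
#' @export
water_density <- function(temperature) {
  1000 * (1 - (temperature + 288.9414) / (508929.2 * (temperature + 68.12963)) *
            (temperature - 3.9863)^2)
}

#' Dynamic viscosity of air
#'
#' Sutherland's law.
#'
#' @inheritParams water_viscosity
#' @return Viscosity in Pa s.
#' @export
air_viscosity <- function(temperature) {
  TK <- temperature + 273.15
  1.716e-5 * (TK / 273.15)^1.5 * (273.15 + 110.4) / (TK + 110.4)
}

#' Binary diffusivity of water vapor in air
#'
#' Power-law temperature scaling (Bolz-Tuve type) referenced to 0 degC.
#'
#' @inheritParams water_viscosity
#' @return Diffusivity in um^2/s.
#' @export
vapor_diffusivity_air <- function(temperature) {
  TK <- temperature + 273.15
  2.178e-5 * (TK / 273.15)^1.81 * 1e12   # m^2/s -> um^2/s
}

#' Saturation vapor mass density over liquid water
#'
#' Magnus form for the saturation pressure combined with the ideal gas law.
#'
#' @inheritParams water_viscosity
#' @return Saturated vapor density in kg/m^3.
#' @export
#' @examples
#' saturation_vapor_density(45) # ~0.065 kg/m^3
saturation_vapor_density <- function(temperature) {
  TK <- temperature + 273.15
  e_sat <- 611.2 * exp(17.62 * temperature / (243.12 + temperature)) # Pa
  e_sat * 0.018015 / (8.3145 * TK)
}

## alias used where an argument name shadows the function
.sat_vapor_density <- saturation_vapor_density

#' Stokes-Einstein diffusion coefficient of a sphere in water
#'
#' @param radius Particle radius in um.
#' @inheritParams water_viscosity
#' @return Diffusion coefficient in um^2/s.
#' @export
#' @examples
#' stokes_einstein_D(0.25, 45) # ~1.6 um^2/s for a 0.5 um bead
stokes_einstein_D <- function(radius, temperature) {
  TK <- temperature + 273.15
  mu <- water_viscosity(temperature)
  .KB * TK / (6 * pi * mu * radius * 1e-6) * 1e12   # m^2/s -> um^2/s
}
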