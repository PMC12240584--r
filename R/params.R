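#' Physical parameter set for a chamber run
#'
#' Collects the material constants entering the gas, vapor and liquid solves.
#' All defaults are derived from the run temperature via standard property
#' correlations; any field can be overridden explicitly.
#'
#' @param temperature Chamber temperature in degC (isothermal premise).
#' @param liquid_viscosity Liquid water viscosity, Pa s.
#' @param liquid_density Liquid water density, kg/m^3.
#' @param gas_viscosity Gas (air) viscosity, Pa s.
#' @param vapor_diffusivity Water vapor diffusivity in air, um^2/s.
#' @param saturation_vapor_density Saturated vapor density at `temperature`,
#'   kg/m^3.
#' @param ambient_humidity Relative humidity of the incoming gas, fraction in
#'   `[0, 1)`. Default 0.15: room air (~23 degC, 50% RH) heated to the 45 degC
#'   chamber temperature.
#' @param evap_kappa Dimensionless calibration prefactor of the evaporation
#'   law; rescaled automatically when the evaporation profile is calibrated
#'   against the water inflow.
#' @return An object of class `physical_params`.
#' @export
#' @examples
#' p <- physical_params(45)
#' p$liquid_viscosity
physical_params <- function(temperature = 45,
                            liquid_viscosity = NULL,
                            liquid_density = NULL,
                            gas_viscosity = NULL,
                            vapor_diffusivity = NULL,
                            saturation_vapor_density = NULL,
                            ambient_humidity = 0.15,
                            evap_kappa = 1) {
  if (is.null(liquid_viscosity)) liquid_viscosity <- water_viscosity(temperature)
  if (is.null(liquid_density)) liquid_density <- water_density(temperature)
  if (is.null(gas_viscosity)) gas_viscosity <- air_viscosity(temperature)
  if (is.null(vapor_diffusivity)) {
    vapor_diffusivity <- vapor_diffusivity_air(temperature)
  }
  if (is.null(saturation_vapor_density)) {
    saturation_vapor_density <- .sat_vapor_density(temperature)
  }
  p <- list(
    temperature = temperature,
    liquid_viscosity = liquid_viscosity,
    liquid_density = liquid_density,
    gas_viscosity = gas_viscosity,
    vapor_diffusivity = vapor_diffusivity,
    saturation_vapor_density = saturation_vapor_density,
    ambient_humidity = ambient_humidity,
    evap_kappa = evap_kappa
  )
  class(p) <- "physical_params"
  validate_physical_params(p)
  p
}

#' @rdname physical_params
#' @param x Object to validate.
#' @export
validate_physical_params <- function(x) {
  stopifnot(inherits(x, "physical_params"))
  pos <- c("liquid_viscosity", "liquid_density", "gas_viscosity",
           "vapor_diffusivity", "saturation_vapor_density", "evap_kappa")
  for (f in pos) {
    if (!is.numeric(x[[f]]) || length(x[[f]]) != 1L || !is.finite(x[[f]]) ||
        x[[f]] <= 0) {
      stop("physical_params: '", f, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (x$temperature < 0 || x$temperature > 100) {
    stop("physical_params: temperature must lie in [0, 100] degC",
         call. = FALSE)
  }
  if (x$ambient_humidity < 0 || x$ambient_humidity >= 1) {
    stop("physical_params: ambient_humidity must lie in [0, 1)", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.physical_params <- function(x, ...) {
  cat("<physical_params>  T =", x$temperature, "degC\n")
  cat(sprintf("  liquid: mu = %.3g Pa s, rho = %.4g kg/m^3\n",
              x$liquid_viscosity, x$liquid_density))
  cat(sprintf("  gas:    mu = %.3g Pa s, D_vap = %.3g um^2/s\n",
              x$gas_viscosity, x$vapor_diffusivity))
  cat(sprintf("  vapor:  rho_sat = %.4g kg/m^3, ambient RH = %.2f, kappa = %.3g\n",
              x$saturation_vapor_density, x$ambient_humidity, x$evap_kappa))
  invisible(x)
}
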