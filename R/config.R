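#' Chamber configuration
#'
#' Geometry, flow settings and discretization of the 2D chamber projection.
#' Coordinates: `x` in `[0, width]` runs horizontally along the gas-flow
#' direction, `y` in `[0, height]` vertically; the gas-water interface sits at
#' `y = height` and pure water flows in upward across `y = 0`. The out-of-plane
#' `depth` enters only the conversion between volumetric flow rate and mean
#' velocity.
#'
#' @param width Interface width (x extent), um.
#' @param height Channel height (y extent), um.
#' @param depth Out-of-plane channel thickness, um.
#' @param gas_gap Height of the gas channel above the interface, um. Default
#'   derived from `gas_duct_area / (width in mm)`.
#' @param inflow_rate Pure-water inflow, nl/s.
#' @param gas_flow Gas flow through the duct, ml/min.
#' @param gas_duct_area Gas duct cross-section, mm^2. The default 0.417 mm^2
#'   maps 250 ml/min to a 10 m/s mean gas velocity.
#' @param interface_shape Either `"flat"` (default) or `"meniscus"`.
#' @param meniscus_sagitta Sagitta of the fixed meniscus in um (only used for
#'   `interface_shape = "meniscus"`; affects interface length weighting).
#' @param interface_peak_speed Peak tangential liquid speed at the interface
#'   (um/s) used by the calibrated gas-shear coupling of
#'   [solve_liquid_flow()]. Default 900 um/s, the bead-velocimetry scale.
#' @param nx,ny Number of grid cells in x and y.
#' @param refine Grading ratio of the y grid: coarsest (bottom) over finest
#'   (interface-adjacent) cell height.
#' @param nz_gas Number of gas-gap grid cells normal to the interface.
#' @param refine_gas Grading ratio of the gas grid toward the interface.
#' @return An object of class `chamber_config`.
#' @seealso [fig2_config()], [fig3_config()] for the two reference
#'   configurations of the study.
#' @export
chamber_config <- function(width = 1500, height = 4000, depth = 250,
                           gas_gap = NULL,
                           inflow_rate = 4, gas_flow = 250,
                           gas_duct_area = 0.417,
                           interface_shape = c("flat", "meniscus"),
                           meniscus_sagitta = 0,
                           interface_peak_speed = 900,
                           nx = 96, ny = 120, refine = 60,
                           nz_gas = 72, refine_gas = 40) {
  interface_shape <- match.arg(interface_shape)
  if (is.null(gas_gap)) gas_gap <- gas_duct_area / (width * 1e-3) * 1e3
  cfg <- list(
    width = width, height = height, depth = depth, gas_gap = gas_gap,
    inflow_rate = inflow_rate, gas_flow = gas_flow,
    gas_duct_area = gas_duct_area,
    interface_shape = interface_shape, meniscus_sagitta = meniscus_sagitta,
    interface_peak_speed = interface_peak_speed,
    nx = nx, ny = ny, refine = refine,
    nz_gas = nz_gas, refine_gas = refine_gas
  )
  class(cfg) <- "chamber_config"
  validate_chamber_config(cfg)
  cfg
}

#' @rdname chamber_config
#' @param x Object to validate.
#' @export
validate_chamber_config <- function(x) {
  stopifnot(inherits(x, "chamber_config"))
  pos <- c("width", "height", "depth", "gas_gap", "gas_duct_area")
  for (f in pos) {
    if (!is.numeric(x[[f]]) || length(x[[f]]) != 1L || x[[f]] <= 0) {
      stop("chamber_config: '", f, "' must be positive", call. = FALSE)
    }
  }
  if (x$inflow_rate < 0 || x$gas_flow < 0) {
    stop("chamber_config: flow rates must be non-negative", call. = FALSE)
  }
  if (x$nx < 16 || x$ny < 16) {
    stop("chamber_config: nx and ny must both be >= 16", call. = FALSE)
  }
  if (x$refine < 1 || x$refine_gas < 1) {
    stop("chamber_config: grading ratios must be >= 1", call. = FALSE)
  }
  invisible(x)
}

#' Reference configuration of the accumulation experiment
#'
#' 4 nl/s pure-water inflow, 250 ml/min gas flow, 45 degC: the conditions of
#' the bead-velocimetry and 63mer accumulation runs.
#'
#' @param ... Overrides passed to [chamber_config()].
#' @return A `chamber_config`.
#' @export
fig2_config <- function(...) {
  chamber_config(inflow_rate = 4, gas_flow = 250, ...)
}

#' Reference configuration of the salt-cycling experiment
#'
#' 3 nl/s inflow, 230 ml/min gas flow, 45 degC: the conditions of the FRET /
#' Mg2+ accumulation and random-walk analyses.
#'
#' @param ... Overrides passed to [chamber_config()].
#' @return A `chamber_config`.
#' @export
fig3_config <- function(...) {
  chamber_config(inflow_rate = 3, gas_flow = 230, ...)
}

#' @export
print.chamber_config <- function(x, ...) {
  cat(sprintf("<chamber_config> %g x %g x %g um, gas gap %g um\n",
              x$width, x$height, x$depth, x$gas_gap))
  cat(sprintf("  inflow %g nl/s (mean %.2f um/s), gas %g ml/min (mean %.2f m/s)\n",
              x$inflow_rate,
              mean_inflow_velocity(x$inflow_rate, x$width, x$depth),
              x$gas_flow, gas_mean_velocity(x$gas_flow, x$gas_duct_area)))
  cat(sprintf("  grid %d x %d (refine %g), gas grid %d (refine %g)\n",
              x$nx, x$ny, x$refine, x$nz_gas, x$refine_gas))
  invisible(x)
}

#' Mean inflow velocity from a volumetric rate
#'
#' Converts a volumetric water inflow through the chamber cross-section into a
#' mean velocity: `rate * 1e6 / (width * depth)` (1 nl = 1e6 um^3).
#'
#' @param rate Inflow in nl/s.
#' @param width,depth Cross-section dimensions in um.
#' @return Mean velocity in um/s.
#' @export
#' @examples
#' mean_inflow_velocity(4, 1500, 250) # ~10.7 um/s
mean_inflow_velocity <- function(rate, width, depth) {
  if (width <= 0 || depth <= 0) {
    stop("mean_inflow_velocity: cross-section dimensions must be positive",
         call. = FALSE)
  }
  if (any(rate < 0)) stop("mean_inflow_velocity: rate must be >= 0",
                          call. = FALSE)
  rate * 1e6 / (width * depth)
}

#' Mean gas velocity from a duct flow rate
#'
#' `flow` in ml/min through `duct_area` in mm^2, returned in m/s.
#'
#' @param flow Gas flow in ml/min.
#' @param duct_area Duct cross-section in mm^2.
#' @return Mean gas velocity in m/s.
#' @export
#' @examples
#' gas_mean_velocity(250, 0.42) # ~9.9 m/s
gas_mean_velocity <- function(flow, duct_area) {
  if (duct_area <= 0) {
    stop("gas_mean_velocity: duct_area must be positive", call. = FALSE)
  }
  if (any(flow < 0)) stop("gas_mean_velocity: flow must be >= 0", call. = FALSE)
  (flow / 60) * 1e3 / duct_area * 1e-3   # mm^3/s / mm^2 = mm/s -> m/s
}

#' Read or write a chamber configuration as YAML
#'
#' @param file Path to a YAML file.
#' @return `read_chamber_config()` returns a validated `chamber_config`.
#' @export
read_chamber_config <- function(file) {
  vals <- yaml::read_yaml(file)
  cfg <- do.call(chamber_config, vals)
  cfg
}

#' @rdname read_chamber_config
#' @param config A `chamber_config`.
#' @export
write_chamber_config <- function(config, file) {
  stopifnot(inherits(config, "chamber_config"))
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}
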