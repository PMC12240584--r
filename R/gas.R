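#' Solve the laminar gas flow in the gas gap
#'
#' The gas channel above the interface is a plane channel of height `gas_gap`;
#' the fully developed laminar solution is the analytic plane-Poiseuille
#' profile with no-slip at both the outer wall and the interface (liquid
#' interface speeds are four orders of magnitude below gas speeds, so the
#' interface is stationary for the gas). Coordinates: `x` along the interface,
#' `z` normal to it with `z = 0` at the interface.
#'
#' @param config A [chamber_config()].
#' @param params A [physical_params()].
#' @return A `gas_flow_field` with the velocity matrix `u` (um/s, nx x nz),
#'   grid vectors and the mean velocity.
#' @export
solve_gas_flow <- function(config, params) {
  validate_chamber_config(config)
  U <- gas_mean_velocity(config$gas_flow, config$gas_duct_area) * 1e6 # um/s
  h <- config$gas_gap
  nx <- config$nx
  dz <- rev(graded_spacings(h, config$nz_gas, config$refine_gas)) # fine at z=0
  zf <- c(0, cumsum(dz)); zf[length(zf)] <- h
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  dx <- rep(config$width / nx, nx)
  xc <- (seq_len(nx) - 0.5) * dx[1]
  uz <- 6 * U * (zc / h) * (1 - zc / h)
  # Reynolds number on the gap (air density from the ideal gas law)
  rho_gas <- 101325 * 0.028965 / (8.3145 * (params$temperature + 273.15))
  Re <- rho_gas * (U * 1e-6) * (h * 1e-6) / params$gas_viscosity
  if (Re > 2000) {
    warning(sprintf("gas flow Reynolds number %.0f exceeds the laminar range",
                    Re))
  }
  out <- list(
    u = matrix(rep(uz, each = nx), nx, length(zc)),
    xc = xc, dx = dx, zc = zc, zf = zf, dz = dz,
    mean_velocity = U, gap = h, reynolds = Re
  )
  class(out) <- "gas_flow_field"
  out
}

#' Tangential stress exerted by the gas on the interface
#'
#' Two profiles are available. `"developing"` (default): the gas momentum
#' boundary layer grows from the upstream edge of the interface, like the
#' vapor boundary layer of [solve_vapor_field()], giving the laminar
#' flat-plate (Blasius) wall shear `tau(x) = 0.332 mu U sqrt(U / (nu x))`,
#' strongly peaked at the leading edge. `"developed"`: the fully developed
#' plane-channel value `tau = 6 mu U / gap`, uniform along the interface.
#'
#' @param gasflow A `gas_flow_field` from [solve_gas_flow()].
#' @param params A [physical_params()].
#' @param profile `"developing"` (flat-plate boundary layer from the leading
#'   edge) or `"developed"` (plane-Poiseuille wall shear).
#' @return A `shear_profile`: interface coordinates `x` (um) and stress `tau`
#'   (Pa).
#' @export
#' @examples
#' cfg <- chamber_config()
#' p <- physical_params(45)
#' sh <- interface_shear(solve_gas_flow(cfg, p), p, profile = "developed")
#' mean(sh$tau) # ~4 Pa
interface_shear <- function(gasflow, params,
                            profile = c("developing", "developed")) {
  stopifnot(inherits(gasflow, "gas_flow_field"))
  profile <- match.arg(profile)
  if (profile == "developed") {
    # shear rate in 1/s: velocities are um/s, gap in um
    rate <- 6 * gasflow$mean_velocity / gasflow$gap
    tau <- rep(params$gas_viscosity * rate, length(gasflow$xc))
  } else {
    rho_gas <- 101325 * 0.028965 / (8.3145 * (params$temperature + 273.15))
    nu <- params$gas_viscosity / rho_gas            # m^2/s
    U <- gasflow$mean_velocity * 1e-6               # m/s
    x_m <- gasflow$xc * 1e-6
    tau <- 0.332 * params$gas_viscosity * U * sqrt(U / (nu * x_m))
  }
  out <- list(x = gasflow$xc, tau = tau)
  class(out) <- "shear_profile"
  out
}

#' Solve steady vapor transport in the gas gap
#'
#' Finite-volume advection-diffusion solve for the vapor mass density
#' `c_v(x, z)`: saturated at the interface (`z = 0`), ambient at the gas inlet
#' (`x = 0`), no-flux at the outer wall, convective outflow at the outlet.
#' Advection is upwinded (cell Peclet ~5 in x); diffusion is central on the
#' graded grid.
#'
#' @inheritParams interface_shear
#' @param config The [chamber_config()] used for the gas solve.
#' @return A `vapor_field`: density matrix `c` (kg/m^3, nx x nz) plus grid
#'   vectors and the saturation/ambient bounds.
#' @export
solve_vapor_field <- function(gasflow, params, config) {
  stopifnot(inherits(gasflow, "gas_flow_field"))
  nx <- length(gasflow$xc); nz <- length(gasflow$zc)
  dx <- gasflow$dx; dz <- gasflow$dz
  zc <- gasflow$zc
  D <- params$vapor_diffusivity           # um^2/s
  c_sat <- params$saturation_vapor_density
  c_amb <- params$ambient_humidity * c_sat
  uz <- gasflow$u[1, ]                    # profile, constant in x

  n <- nx * nz
  ii <- rep(seq_len(nx), nz)              # x index of each cell
  kk <- rep(seq_len(nz), each = nx)       # z index of each cell
  r <- seq_len(n)
  diag_v <- numeric(n); rhs <- numeric(n)
  a_flux <- uz[kk] * dz[kk]               # advective face flux, um^2/s

  # x-direction: advection (upwind, u > 0) + diffusion between columns
  d_x <- D * dz[kk] / dx[1]
  west <- ii > 1L; east <- ii < nx
  off_i <- r[west]; off_j <- r[west] - 1L
  off_v <- -(a_flux[west] + d_x[west])
  diag_v[west] <- diag_v[west] + d_x[west]
  # inlet column: advective influx at ambient (rhs only) + diffusive tie
  d_in <- D * dz[kk] / (dx[1] / 2)
  diag_v[!west] <- diag_v[!west] + d_in[!west]
  rhs[!west] <- rhs[!west] + (a_flux[!west] + d_in[!west]) * c_amb
  diag_v[east] <- diag_v[east] + a_flux[east] + d_x[east]
  off_i <- c(off_i, r[east]); off_j <- c(off_j, r[east] + 1L)
  off_v <- c(off_v, -d_x[east])
  diag_v[!east] <- diag_v[!east] + a_flux[!east]  # pure advective outflow

  # z-direction: diffusion only (no normal gas velocity in the developed gap)
  low <- kk > 1L; up <- kk < nz
  d_dn <- D * dx[ii] / c(2 * zc[1], diff(zc))[kk]   # distance to row below
  d_up <- D * dx[ii] / c(diff(zc), Inf)[kk]         # distance to row above
  # interface Dirichlet at z = 0 (half-cell distance zc[1])
  d0 <- D * dx[ii] / zc[1]
  diag_v[!low] <- diag_v[!low] + d0[!low]
  rhs[!low] <- rhs[!low] + d0[!low] * c_sat
  off_i <- c(off_i, r[low]); off_j <- c(off_j, r[low] - nx)
  off_v <- c(off_v, -d_dn[low])
  diag_v[low] <- diag_v[low] + d_dn[low]
  diag_v[up] <- diag_v[up] + d_up[up]
  off_i <- c(off_i, r[up]); off_j <- c(off_j, r[up] + nx)
  off_v <- c(off_v, -d_up[up])                      # outer wall: no flux

  A <- Matrix::sparseMatrix(
    i = c(r, off_i), j = c(r, off_j), x = c(diag_v, off_v), dims = c(n, n))
  sol <- Matrix::solve(A, rhs)
  cmat <- matrix(as.numeric(sol), nx, nz)
  if (max(cmat) > c_sat * (1 + 1e-8) || min(cmat) < c_amb * (1 - 1e-8)) {
    warning("vapor field violates the maximum principle beyond round-off")
  }
  out <- list(c = cmat, xc = gasflow$xc, dx = dx, zc = zc, dz = dz,
              c_sat = c_sat, c_amb = c_amb)
  class(out) <- "vapor_field"
  out
}

#' Evaporation-velocity profile along the interface
#'
#' The local evaporation velocity is proportional to the interfacial vapor
#' gradient: `v_e(x) = kappa * (D_vap / rho_liquid) * dc_v/dn`. In calibrated
#' mode (default) `kappa` is rescaled so the total evaporated volume balances
#' the configured water inflow, the condition for a stationary interface.
#'
#' @param vapor A `vapor_field` from [solve_vapor_field()].
#' @param params A [physical_params()].
#' @param config A [chamber_config()].
#' @param calibrate If `TRUE`, rescale `kappa` to balance evaporation against
#'   the inflow.
#' @return An `evaporation_profile`: interface coordinates `x`, local `v_e`
#'   (um/s), the interface-length-weighted mean `v_bar`, and the `kappa` used.
#' @export
evaporation_profile <- function(vapor, params, config, calibrate = TRUE) {
  stopifnot(inherits(vapor, "vapor_field"))
  grad <- (vapor$c_sat - vapor$c[, 1]) / vapor$zc[1]  # kg/m^3 per um
  v_e <- params$evap_kappa * params$vapor_diffusivity * grad /
    params$liquid_density
  if (any(v_e < 0)) {
    warning("condensing interface segments clipped to zero evaporation")
    v_e <- pmax(v_e, 0)
  }
  kappa <- params$evap_kappa
  if (calibrate) {
    target <- config$inflow_rate * 1e6            # um^3/s
    total <- sum(v_e * vapor$dx) * config$depth   # um^3/s
    if (total <= 0) stop("evaporation_profile: cannot calibrate a zero profile",
                         call. = FALSE)
    scale <- target / total
    v_e <- v_e * scale
    kappa <- kappa * scale
  }
  out <- list(x = vapor$xc, dx = vapor$dx, v_e = v_e,
              v_bar = sum(v_e * vapor$dx) / sum(vapor$dx),
              kappa = kappa, calibrated = calibrate)
  class(out) <- "evaporation_profile"
  out
}

#' @export
print.evaporation_profile <- function(x, ...) {
  cat(sprintf(
    "<evaporation_profile> v_bar = %.3g um/s, range [%.3g, %.3g], kappa = %.3g%s\n",
    x$v_bar, min(x$v_e), max(x$v_e), x$kappa,
    if (x$calibrated) " (calibrated)" else ""))
  invisible(x)
}
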