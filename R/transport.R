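#' Describe a dissolved, non-volatile solute
#'
#' @param name Label, e.g. `"dna63"` or `"mg"`.
#' @param D Diffusion coefficient in um^2/s (63mer DNA: 95; Mg2+: 705).
#' @param c0 Initial relative concentration (1 = loaded sample).
#' @param support Initial spatial support: `"full"` (whole chamber, the
#'   continuous-dilution scenario in which the loaded sample fills the pore
#'   ahead of the pure-water influx) or `"plug"`.
#' @param plug_height Height (um) of the initial plug below the interface,
#'   for `support = "plug"`.
#' @param inflow_concentration Relative solute concentration carried by the
#'   bottom inflow: 0 (default) for the diluting pure-water influx, 1 for a
#'   feed that keeps supplying sample at the loaded concentration (the
#'   scenario of a pore drawing from a biomolecule-laden reservoir).
#' @return A `solute_spec`.
#' @export
#' @examples
#' solute_spec("dna63", 95)
#' solute_spec("mg", 705)
solute_spec <- function(name, D, c0 = 1,
                        support = c("full", "plug"), plug_height = NULL,
                        inflow_concentration = 0) {
  support <- match.arg(support)
  if (D <= 0 || c0 <= 0) {
    stop("solute_spec: D and c0 must be positive", call. = FALSE)
  }
  if (support == "plug" && (is.null(plug_height) || plug_height <= 0)) {
    stop("solute_spec: plug support needs a positive plug_height",
         call. = FALSE)
  }
  if (inflow_concentration < 0) {
    stop("solute_spec: inflow_concentration must be >= 0", call. = FALSE)
  }
  structure(list(name = name, D = D, c0 = c0, support = support,
                 plug_height = plug_height,
                 inflow_concentration = inflow_concentration),
            class = "solute_spec")
}

## Water volume fluxes through cell faces (per unit depth, um^2/s), exact
## streamfunction differences -> discretely divergence-free. Boundary faces
## are zeroed: no solute crosses walls, interface or the pure-water inlet.
solute_face_fluxes <- function(flow) {
  g <- flow$grid; psi <- flow$psi
  nx <- g$nx; ny <- g$ny
  # x-face (i = 1..nx+1) between columns, rows j = 1..ny
  Fx <- psi[, 2:(ny + 1), drop = FALSE] - psi[, 1:ny, drop = FALSE]
  Fx[1, ] <- 0; Fx[nx + 1, ] <- 0
  # y-face (j = 1..ny+1) spanning columns i = 1..nx
  Fy <- -(psi[2:(nx + 1), , drop = FALSE] - psi[1:nx, , drop = FALSE])
  Fy_bottom <- Fy[, 1]                 # water influx faces (for a laden feed)
  Fy[, 1] <- 0; Fy[, ny + 1] <- 0
  list(Fx = Fx, Fy = Fy, Fy_bottom = Fy_bottom)
}

## Largest stable advective time step (CFL = 1) for the solute fluxes.
advective_dt_limit <- function(flow) {
  g <- flow$grid
  fl <- solute_face_fluxes(flow)
  vol <- g$areas
  outflow <- pmax(fl$Fx[-1, , drop = FALSE], 0) +
    pmax(-fl$Fx[-(g$nx + 1), , drop = FALSE], 0) +
    pmax(fl$Fy[, -1, drop = FALSE], 0) +
    pmax(-fl$Fy[, -(g$ny + 1), drop = FALSE], 0)
  m <- max(outflow / vol)
  if (m <= 0) Inf else 1 / m
}

initial_field <- function(solute, grid) {
  c0 <- matrix(solute$c0, grid$nx, grid$ny)
  if (solute$support == "plug") {
    below <- grid$yc < grid$height - solute$plug_height
    c0[, below] <- 0
  }
  c0
}

#' Simulate solute transport in a solved flow
#'
#' Integrates the advection-diffusion equation
#' `dc/dt = div(D grad c) - div(u c)` with zero total solute flux through
#' every boundary (the interface evaporates water but passes no solute; the
#' bottom inflow is pure water; walls are impermeable). Advection uses a
#' positivity-preserving limited upwind scheme in flux form; diffusion is
#' implicit. Total solute mass is conserved to round-off.
#'
#' @param flow A `flow_field` from [solve_liquid_flow()].
#' @param solute A [solute_spec()].
#' @param duration Simulated time, s.
#' @param dt Time step, s. Default: 0.45 of the advective CFL limit. A larger
#'   value than the CFL limit is refused with the admissible step reported.
#' @param snapshot_times Times (s) at which to store the field. Default: ten
#'   evenly spaced snapshots plus the final time.
#' @return A `concentration_field`: array `c` of dim `(nx, ny, n_snapshots)`
#'   holding `c/c0`, snapshot `times`, the `grid`, solute and mass ledger.
#' @export
simulate_transport <- function(flow, solute, duration, dt = NULL,
                               snapshot_times = NULL) {
  stopifnot(inherits(flow, "flow_field"), inherits(solute, "solute_spec"))
  g <- flow$grid
  dt_lim <- advective_dt_limit(flow)
  if (is.null(dt)) {
    dt <- if (is.finite(dt_lim)) 0.45 * dt_lim else duration / 100
  } else if (dt > dt_lim) {
    stop(sprintf(paste0("simulate_transport: dt = %.4g s violates the ",
                        "advective stability limit; use dt <= %.4g s"),
                 dt, dt_lim), call. = FALSE)
  }
  # resolve the accumulation boundary layer delta = D / v_e (mean profile
  # scale; the integrable leading-edge peak of v_e does not set the layer)
  if (!is.null(flow$evap) && flow$evap$v_bar > 0) {
    delta <- solute$D / flow$evap$v_bar
    if (g$dy[g$ny] > delta) {
      stop(sprintf(paste0("simulate_transport: interfacial cell (%.3g um) ",
                          "cannot resolve the boundary layer D/v_e = %.3g um; ",
                          "rebuild the grid with min_diffusivity = %g"),
           g$dy[g$ny], delta, solute$D), call. = FALSE)
    }
  }
  nsteps <- max(1L, as.integer(ceiling(duration / dt)))
  dt <- duration / nsteps
  if (is.null(snapshot_times)) {
    snapshot_times <- unique(c(seq(0, duration, length.out = 11L), duration))
  }
  snap_steps <- sort(unique(pmin(nsteps, pmax(0L, as.integer(
    round(snapshot_times / dt))))))
  fl <- solute_face_fluxes(flow)
  c0 <- initial_field(solute, g)
  c_in <- solute$inflow_concentration * solute$c0
  res <- transport_run_cpp(as.numeric(c0), g$nx, g$ny, g$dx, g$dy,
                           g$xc, g$yc, as.numeric(fl$Fx), as.numeric(fl$Fy),
                           solute$D, dt, nsteps, snap_steps, c_in,
                           fl$Fy_bottom)
  mass0 <- sum(c0 * g$areas) + c_in * sum(fl$Fy_bottom) * nsteps * dt
  if (res$min_c < -1e-8 * max(res$c)) {
    stop(sprintf("simulate_transport: advection scheme produced negative
concentrations (min %.3g); reduce dt", res$min_c), call. = FALSE)
  }
  out <- list(
    c = array(res$snapshots, dim = c(g$nx, g$ny, length(snap_steps))) /
      solute$c0,
    times = snap_steps * dt,
    grid = g, solute = solute, dt = dt,
    mass_initial = mass0, mass_final = res$mass,
    mass_error = abs(res$mass - mass0) / mass0
  )
  class(out) <- "concentration_field"
  out
}

#' Time series of the maximum relative concentration
#'
#' Per-snapshot maximum of `c/c0`, taken over cells at least one cell away
#' from the boundary (the outermost ring is excluded to keep the measure
#' independent of boundary-extrapolation conventions).
#'
#' @param field A `concentration_field`.
#' @return A data.frame with columns `time` (s) and `max_c` (fold).
#' @export
max_accumulation_series <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  if (length(field$times) == 0L) {
    stop("max_accumulation_series: no snapshots", call. = FALSE)
  }
  nx <- field$grid$nx; ny <- field$grid$ny
  inner <- field$c[2:(nx - 1), 2:(ny - 1), , drop = FALSE]
  data.frame(time = field$times,
             max_c = apply(inner, 3, max))
}

#' Integrate a solute to its steady concentration field
#'
#' Runs the transport simulation in intervals until the relative field change
#' per 100 s drops below `tol`. The steady state is the mass-conserving
#' redistribution of the initial load (boundary-layer pile-up balanced by
#' vortex stirring and diffusion).
#'
#' @inheritParams simulate_transport
#' @param tol Relative max-norm change per 100 s interval accepted as steady.
#' @param max_time Give up (with an error) beyond this simulated time, s.
#' @return A `concentration_field` with a single snapshot (the steady field)
#'   and an attribute `settling_time`.
#' @export
steady_state_field <- function(flow, solute, tol = 1e-3, dt = NULL,
                               max_time = 20000) {
  stopifnot(inherits(flow, "flow_field"))
  t_done <- 0
  interval <- 100
  fld <- simulate_transport(flow, solute, interval, dt = dt,
                            snapshot_times = interval)
  hist <- numeric(0)
  repeat {
    t_done <- t_done + interval
    prev <- fld$c[, , dim(fld$c)[3]]
    # continue from the previous state
    sol2 <- solute
    fld2 <- continue_transport(flow, sol2, prev, interval, dt = dt)
    cur <- fld2$c[, , dim(fld2$c)[3]]
    change <- max(abs(cur - prev)) / max(abs(cur))
    hist <- c(hist, change)
    fld <- fld2
    if (change < tol) break
    if (t_done > max_time) {
      stop(sprintf(paste0("steady_state_field: not steady after %.0f s; ",
                          "residual history: %s"), t_done,
           paste(signif(tail(hist, 5), 3), collapse = ", ")), call. = FALSE)
    }
  }
  out <- list(c = array(cur, dim = c(dim(cur), 1L)),
              times = t_done + interval,
              grid = fld$grid, solute = solute, dt = fld$dt,
              mass_initial = fld$mass_initial, mass_final = fld$mass_final,
              mass_error = fld$mass_error)
  class(out) <- "concentration_field"
  attr(out, "settling_time") <- t_done + interval
  out
}

## advance an existing concentration matrix by `duration`
continue_transport <- function(flow, solute, cmat, duration, dt = NULL) {
  g <- flow$grid
  dt_lim <- advective_dt_limit(flow)
  if (is.null(dt)) dt <- if (is.finite(dt_lim)) 0.45 * dt_lim else duration / 100
  nsteps <- max(1L, as.integer(ceiling(duration / dt)))
  dt <- duration / nsteps
  fl <- solute_face_fluxes(flow)
  c_in <- solute$inflow_concentration * solute$c0
  res <- transport_run_cpp(as.numeric(cmat * solute$c0), g$nx, g$ny,
                           g$dx, g$dy, g$xc, g$yc,
                           as.numeric(fl$Fx), as.numeric(fl$Fy),
                           solute$D, dt, nsteps, nsteps, c_in, fl$Fy_bottom)
  mass0 <- sum(cmat * solute$c0 * g$areas) +
    c_in * sum(fl$Fy_bottom) * nsteps * dt
  out <- list(
    c = array(res$snapshots, dim = c(g$nx, g$ny, 1L)) / solute$c0,
    times = duration, grid = g, solute = solute, dt = dt,
    mass_initial = mass0, mass_final = res$mass,
    mass_error = abs(res$mass - mass0) / mass0
  )
  class(out) <- "concentration_field"
  out
}

#' @export
print.concentration_field <- function(x, ...) {
  ns <- dim(x$c)[3]
  cat(sprintf("<concentration_field> %s (D = %g um^2/s), %d snapshot(s) to t = %g s\n",
              x$solute$name, x$solute$D, ns, max(x$times)))
  cat(sprintf("  max c/c0 = %.3g; mass error %.2g\n",
              max(x$c[, , ns]), x$mass_error))
  invisible(x)
}
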