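## Steady incompressible 2D Stokes flow in the chamber, streamfunction-
## vorticity formulation on the graded tensor grid.
##
## Convention: u = dpsi/dy, v = -dpsi/dx, omega = dv/dx - du/dy = -lap(psi).
## The coupled linear system solves lap(psi) + omega = 0 and lap(omega) = 0
## with psi Dirichlet everywhere (through-flow streamfunction) and the
## tangential condition injected through boundary-vorticity (Thom-type) rows.

## Second-derivative weights on three nonuniformly spaced points.
d2_weights <- function(hm, hp) {
  cbind(2 / (hm * (hm + hp)), -2 / (hm * hp), 2 / (hp * (hm + hp)))
}

## First-derivative (central) weights on three nonuniformly spaced points.
d1_weights <- function(hm, hp) {
  cbind(-hp / (hm * (hm + hp)), (hp - hm) / (hm * hp), hm / (hp * (hm + hp)))
}

#' Solve the steady liquid flow in the chamber
#'
#' Stokes flow driven by (i) uniform upward inflow across the bottom,
#' (ii) the evaporation velocity profile as normal outflow across the
#' interface, and (iii) the gas drag along the interface. Side walls are
#' no-slip. The gas drag enters in one of three coupling modes:
#'
#' * `"calibrated"` (default): the stress-driven problem is solved once to
#'   obtain the shape of the interfacial tangential velocity, which is then
#'   rescaled so its peak equals `config$interface_peak_speed` and imposed as
#'   a velocity boundary condition. The magnitude of the 2D-projected
#'   gas-liquid momentum coupling is not recoverable from the plane-channel
#'   shear alone (the physical interface is recessed and three-dimensional),
#'   so the peak speed is an explicit, velocimetry-scale parameter.
#' * `"stress"`: tangential stress continuity `mu_l du/dn = tau(x)` with the
#'   gas-side shear; no rescaling.
#' * `"prescribed"`: impose the tangential velocity profile `u_t` directly.
#'
#' @param config A [chamber_config()].
#' @param params A [physical_params()].
#' @param evap An [evaporation_profile()] (calibrated against the inflow
#'   within 1%, otherwise no steady solution exists and the solver refuses).
#' @param shear A `shear_profile` from [interface_shear()] (needed for the
#'   stress-based modes).
#' @param coupling Gas-drag coupling mode, see Details.
#' @param u_t Tangential interface velocity (um/s) at the `nx + 1` grid nodes
#'   for `coupling = "prescribed"`.
#' @param grid Optional pre-built [build_grid()] grid.
#' @return A `flow_field`: node matrices `psi` (um^2/s), `omega` (1/s), `u`,
#'   `v` (um/s), the `grid`, and `diagnostics` (max speed, max interfacial
#'   tangential speed, vortex center, mass imbalance).
#' @export
solve_liquid_flow <- function(config, params, evap, shear = NULL,
                              coupling = c("calibrated", "stress",
                                           "prescribed"),
                              u_t = NULL, grid = NULL, hele_shaw = FALSE) {
  coupling <- match.arg(coupling)
  kappa_hs <- if (hele_shaw) 12 / config$depth^2 else 0
  if (is.null(grid)) grid <- build_grid(config)
  v_in <- mean_inflow_velocity(config$inflow_rate, config$width, config$depth)
  # interface normal-velocity profile on cell centers -> node streamfunction
  stopifnot(inherits(evap, "evaporation_profile"))
  if (length(evap$v_e) != grid$nx) {
    stop("solve_liquid_flow: evaporation profile and grid have different nx",
         call. = FALSE)
  }
  Q2 <- v_in * grid$width                       # through-flow per depth, um^2/s
  evap_total <- sum(evap$v_e * grid$dx)
  if (Q2 > 0 && abs(evap_total - Q2) / Q2 > 0.01) {
    stop(sprintf(paste0(
      "solve_liquid_flow: evaporation (%.4g um^2/s) and inflow (%.4g um^2/s) ",
      "differ by more than 1%%; no steady solution exists. Calibrate the ",
      "evaporation profile first."), evap_total, Q2), call. = FALSE)
  }

  if (coupling == "calibrated") {
    if (is.null(shear)) {
      stop("solve_liquid_flow: 'calibrated' coupling needs a shear profile",
           call. = FALSE)
    }
    base <- stokes_solve(grid, v_in, evap, mode = "stress",
                         tau_over_mu = shear$tau / params$liquid_viscosity,
                         kappa_hs = kappa_hs)
    shape <- base$u[, grid$ny + 1L]
    pk <- max(abs(shape))
    if (pk <= 0) stop("solve_liquid_flow: stress solve produced no interfacial
motion to calibrate", call. = FALSE)
    u_t <- shape / pk * config$interface_peak_speed
    sol <- stokes_solve(grid, v_in, evap, mode = "velocity", u_t = u_t,
                        kappa_hs = kappa_hs)
  } else if (coupling == "stress") {
    if (is.null(shear)) {
      stop("solve_liquid_flow: 'stress' coupling needs a shear profile",
           call. = FALSE)
    }
    sol <- stokes_solve(grid, v_in, evap, mode = "stress",
                        tau_over_mu = shear$tau / params$liquid_viscosity,
                        kappa_hs = kappa_hs)
  } else {
    if (is.null(u_t)) {
      stop("solve_liquid_flow: 'prescribed' coupling needs u_t", call. = FALSE)
    }
    if (length(u_t) != grid$nx + 1L) {
      stop("solve_liquid_flow: u_t must have nx + 1 node values",
           call. = FALSE)
    }
    sol <- stokes_solve(grid, v_in, evap, mode = "velocity", u_t = u_t,
                        kappa_hs = kappa_hs)
  }
  sol$config <- config
  sol$evap <- evap
  sol$diagnostics <- flow_diagnostics(sol, Q2)
  sol
}

## Core linear solve. mode = "stress" (tau_over_mu at interface, 1/s) or
## "velocity" (u_t at the nx+1 interface nodes, um/s). kappa_hs is the
## Hele-Shaw drag coefficient 12/depth^2 (1/um^2; 0 = plain 2D).
stokes_solve <- function(grid, v_in, evap, mode, tau_over_mu = NULL,
                         u_t = NULL, kappa_hs = 0) {
  nxn <- grid$nx + 1L; nyn <- grid$ny + 1L
  x <- grid$xf; y <- grid$yf
  n <- nxn * nyn
  pid <- function(i, j) (j - 1L) * nxn + i     # psi index; omega = n + pid

  # Dirichlet streamfunction on the boundary
  psi_bottom <- -v_in * x
  psi_top <- -c(0, cumsum(evap$v_e * grid$dx))
  psi_top <- psi_top * if (psi_top[nxn] != 0) {
    (-v_in * grid$width) / psi_top[nxn]        # absorb <=1% residual exactly
  } else 1
  psi_left <- rep(0, nyn)
  psi_right <- rep(-v_in * grid$width, nyn)

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  rhs <- numeric(2L * n)
  newt <- function(i, j, v) { ti <<- c(ti, i); tj <<- c(tj, j); tv <<- c(tv, v) }

  ii <- rep(seq_len(nxn), nyn)
  jj <- rep(seq_len(nyn), each = nxn)
  interior <- ii > 1L & ii < nxn & jj > 1L & jj < nyn
  bnd <- !interior

  # --- psi Dirichlet rows on the boundary
  pb <- numeric(n)
  pb[jj == 1L] <- psi_bottom[ii[jj == 1L]]
  pb[jj == nyn] <- psi_top[ii[jj == nyn]]
  pb[ii == 1L] <- psi_left[jj[ii == 1L]]
  pb[ii == nxn] <- psi_right[jj[ii == nxn]]
  # corners belong to the walls; consistent values either way
  rb <- which(bnd)
  newt(rb, rb, rep(1, length(rb)))
  rhs[rb] <- pb[rb]

  # --- interior rows: lap(psi) + omega = 0 and lap(omega) = 0
  it <- which(interior)
  hxm <- x[ii[it]] - x[ii[it] - 1L]; hxp <- x[ii[it] + 1L] - x[ii[it]]
  hym <- y[jj[it]] - y[jj[it] - 1L]; hyp <- y[jj[it] + 1L] - y[jj[it]]
  wx <- d2_weights(hxm, hxp); wy <- d2_weights(hym, hyp)
  for (off in c(0L, n)) {                       # same Laplacian for psi, omega
    newt(off + it, off + it - 1L, wx[, 1])
    newt(off + it, off + it,      wx[, 2] + wy[, 2])
    newt(off + it, off + it + 1L, wx[, 3])
    newt(off + it, off + it - nxn, wy[, 1])
    newt(off + it, off + it + nxn, wy[, 3])
  }
  newt(it, n + it, rep(1, length(it)))          # + omega in the psi equation
  if (kappa_hs > 0) {                           # out-of-plane (Hele-Shaw) drag
    newt(n + it, n + it, rep(-kappa_hs, length(it)))
  }

  # --- boundary vorticity rows
  # bottom (j = 1), interior i: no-slip u_t = 0
  ib <- which(jj == 1L & ii > 1L & ii < nxn)
  h1 <- y[2] - y[1]
  wxb <- d2_weights(x[ii[ib]] - x[ii[ib] - 1L], x[ii[ib] + 1L] - x[ii[ib]])
  newt(n + ib, n + ib, rep(1, length(ib)))
  newt(n + ib, ib - 1L, wxb[, 1]); newt(n + ib, ib, wxb[, 2])
  newt(n + ib, ib + 1L, wxb[, 3])
  newt(n + ib, ib + nxn, rep(2 / h1^2, length(ib)))
  newt(n + ib, ib, rep(-2 / h1^2, length(ib)))
  rhs[n + ib] <- 0                              # tangential velocity zero

  # left / right walls (interior j): no-slip v = 0
  for (side in c(1L, 2L)) {
    iw <- if (side == 1L) which(ii == 1L & jj > 1L & jj < nyn)
          else which(ii == nxn & jj > 1L & jj < nyn)
    hx <- if (side == 1L) x[2] - x[1] else x[nxn] - x[nxn - 1L]
    inn <- if (side == 1L) iw + 1L else iw - 1L
    wyw <- d2_weights(y[jj[iw]] - y[jj[iw] - 1L], y[jj[iw] + 1L] - y[jj[iw]])
    newt(n + iw, n + iw, rep(1, length(iw)))
    newt(n + iw, iw - nxn, wyw[, 1]); newt(n + iw, iw, wyw[, 2])
    newt(n + iw, iw + nxn, wyw[, 3])
    newt(n + iw, inn, rep(2 / hx^2, length(iw)))
    newt(n + iw, iw, rep(-2 / hx^2, length(iw)))
    rhs[n + iw] <- 0
  }

  # interface (j = nyn), interior i
  itp <- which(jj == nyn & ii > 1L & ii < nxn)
  hN <- y[nyn] - y[nyn - 1L]
  wxt <- d2_weights(x[ii[itp]] - x[ii[itp] - 1L], x[ii[itp] + 1L] - x[ii[itp]])
  if (mode == "velocity") {
    # Thom row with prescribed tangential velocity u_t
    ut_i <- u_t[ii[itp]]
    newt(n + itp, n + itp, rep(1, length(itp)))
    newt(n + itp, itp - 1L, wxt[, 1]); newt(n + itp, itp, wxt[, 2])
    newt(n + itp, itp + 1L, wxt[, 3])
    newt(n + itp, itp - nxn, rep(2 / hN^2, length(itp)))
    newt(n + itp, itp, rep(-2 / hN^2, length(itp)))
    rhs[n + itp] <- -2 * ut_i / hN
  } else {
    # stress continuity: omega = 2 v_x - tau/mu, v_x = -psi_xx
    tau_i <- tau_over_mu[pmin(ii[itp], length(tau_over_mu))]
    newt(n + itp, n + itp, rep(1, length(itp)))
    newt(n + itp, itp - 1L, 2 * wxt[, 1]); newt(n + itp, itp, 2 * wxt[, 2])
    newt(n + itp, itp + 1L, 2 * wxt[, 3])
    rhs[n + itp] <- -tau_i
  }

  # corners: vorticity as the mean of the two adjacent boundary values
  corners <- cbind(
    c(pid(1L, 1L), pid(2L, 1L), pid(1L, 2L)),
    c(pid(nxn, 1L), pid(nxn - 1L, 1L), pid(nxn, 2L)),
    c(pid(1L, nyn), pid(2L, nyn), pid(1L, nyn - 1L)),
    c(pid(nxn, nyn), pid(nxn - 1L, nyn), pid(nxn, nyn - 1L)))
  for (cc in seq_len(4L)) {
    rc <- n + corners[1, cc]
    newt(rc, rc, 1)
    newt(rc, n + corners[2, cc], -0.5)
    newt(rc, n + corners[3, cc], -0.5)
  }

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(2L * n, 2L * n))
  sol <- as.numeric(Matrix::solve(A, rhs))
  psi <- matrix(sol[seq_len(n)], nxn, nyn)
  omega <- matrix(sol[n + seq_len(n)], nxn, nyn)

  u <- apply_d1(psi, y, along = 2L)             # u = dpsi/dy
  v <- -apply_d1(psi, x, along = 1L)            # v = -dpsi/dx
  out <- list(psi = psi, omega = omega, u = u, v = v, grid = grid,
              v_in = v_in)
  class(out) <- "flow_field"
  out
}

## First derivative of a node matrix along x (along = 1) or y (along = 2),
## second order on the nonuniform grid, one-sided at the ends.
apply_d1 <- function(m, coord, along) {
  if (along == 1L) return(t(apply_d1(t(m), coord, 2L)))
  nc <- length(coord)
  out <- m
  hm <- coord[2:(nc - 1)] - coord[1:(nc - 2)]
  hp <- coord[3:nc] - coord[2:(nc - 1)]
  w <- d1_weights(hm, hp)
  out[, 2:(nc - 1)] <-
    m[, 1:(nc - 2), drop = FALSE] * rep(w[, 1], each = nrow(m)) +
    m[, 2:(nc - 1), drop = FALSE] * rep(w[, 2], each = nrow(m)) +
    m[, 3:nc, drop = FALSE] * rep(w[, 3], each = nrow(m))
  # one-sided second-order ends
  h1 <- coord[2] - coord[1]; h2 <- coord[3] - coord[2]
  out[, 1] <- (-(2 * h1 + h2) / (h1 * (h1 + h2))) * m[, 1] +
    ((h1 + h2) / (h1 * h2)) * m[, 2] - (h1 / (h2 * (h1 + h2))) * m[, 3]
  hA <- coord[nc] - coord[nc - 1]; hB <- coord[nc - 1] - coord[nc - 2]
  out[, nc] <- ((2 * hA + hB) / (hA * (hA + hB))) * m[, nc] -
    ((hA + hB) / (hA * hB)) * m[, nc - 1] + (hA / (hB * (hA + hB))) * m[, nc - 2]
  out
}

## Summary numbers of a solved flow.
flow_diagnostics <- function(flow, Q2) {
  g <- flow$grid
  speed <- sqrt(flow$u^2 + flow$v^2)
  psi <- flow$psi
  b_range <- range(psi[c(1, nrow(psi)), ], psi[, c(1, ncol(psi))])
  over <- max(psi) - b_range[2]
  under <- b_range[1] - min(psi)
  if (max(over, under) > 1e-9 * max(abs(b_range), 1e-12)) {
    k <- if (over >= under) which.max(psi) else which.min(psi)
    ij <- arrayInd(k, dim(psi))
    center <- c(x = g$xf[ij[1]], y = g$yf[ij[2]])
  } else {
    center <- c(x = NA_real_, y = NA_real_)
  }
  list(
    max_speed = max(speed),
    max_interface_speed = max(abs(flow$u[, ncol(flow$u)])),
    vortex_center = center,
    mass_imbalance = abs(sum(flow$evap$v_e * g$dx) - Q2) / max(Q2, 1e-300)
  )
}

#' Relative inflow/outflow mass imbalance of a solved flow
#'
#' @param flow A `flow_field` from [solve_liquid_flow()].
#' @param config The corresponding [chamber_config()].
#' @return `|inflow - evaporative outflow| / inflow` (fraction). With zero
#'   inflow the absolute outflow (um^2/s per unit depth) is returned with a
#'   `"zero_inflow"` attribute.
#' @export
check_mass_balance <- function(flow, config) {
  stopifnot(inherits(flow, "flow_field"))
  v_in <- mean_inflow_velocity(config$inflow_rate, config$width, config$depth)
  Q2 <- v_in * flow$grid$width
  out_flux <- sum(flow$evap$v_e * flow$grid$dx)
  if (Q2 == 0) {
    return(structure(out_flux, zero_inflow = TRUE))
  }
  abs(Q2 - out_flux) / Q2
}

#' Area-weighted distribution of flow speeds
#'
#' Histogram of the speed magnitude over the chamber, each node weighted by
#' the area it represents, normalized to unit mass — the simulation-side
#' counterpart of a bead-velocity histogram.
#'
#' @param flow A `flow_field`.
#' @param breaks Bin edges in um/s, or a bin count passed to [cut()]-style
#'   equal spacing over the speed range.
#' @param log10 If `TRUE` (default), bin `log10(speed)` instead of speed
#'   (speeds span two decades between bulk and interface).
#' @return A data.frame with bin `mid`, `density` (sums to 1) and edges.
#' @export
velocity_histogram <- function(flow, breaks = 40, log10 = TRUE) {
  stopifnot(inherits(flow, "flow_field"))
  g <- flow$grid
  speed <- sqrt(flow$u^2 + flow$v^2)
  if (all(speed == 0)) stop("velocity_histogram: flow field is empty",
                            call. = FALSE)
  # node weights: product of half-cell extents
  wx <- c(g$dx[1] / 2, (g$dx[-g$nx] + g$dx[-1]) / 2, g$dx[g$nx] / 2)
  wy <- c(g$dy[1] / 2, (g$dy[-g$ny] + g$dy[-1]) / 2, g$dy[g$ny] / 2)
  w <- as.numeric(outer(wx, wy))
  s <- as.numeric(speed)
  if (log10) {
    s_pos <- pmax(s, max(s) * 1e-12)
    val <- base::log10(s_pos)
  } else val <- s
  if (length(breaks) == 1L) {
    breaks <- seq(min(val), max(val), length.out = breaks + 1L)
    breaks[1] <- breaks[1] - 1e-9; breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  }
  bin <- findInterval(val, breaks, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= length(breaks) - 1L
  dens <- vapply(seq_len(length(breaks) - 1L),
                 function(b) sum(w[keep][bin[keep] == b]), numeric(1))
  dens <- dens / sum(dens)
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             density = dens)
}

#' @export
print.flow_field <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<flow_field> %d x %d nodes\n", nrow(x$psi), ncol(x$psi)))
  if (!is.null(d)) {
    cat(sprintf("  max speed %.3g um/s; interface tangential max %.3g um/s\n",
                d$max_speed, d$max_interface_speed))
    cat(sprintf("  vortex center (%.0f, %.0f) um; mass imbalance %.2g\n",
                d$vortex_center[1], d$vortex_center[2], d$mass_imbalance))
  }
  invisible(x)
}

#' Build a flow field directly from a streamfunction
#'
#' Utility for analytic/synthetic flows (uniform streams, zero flow, test
#' vortices): differentiates a node streamfunction matrix into velocities on
#' the given grid.
#'
#' @param grid A [build_grid()] grid.
#' @param psi Node matrix `(nx+1) x (ny+1)` of streamfunction values, um^2/s.
#' @return A `flow_field` (without solver diagnostics).
#' @export
flow_from_psi <- function(grid, psi) {
  stopifnot(inherits(grid, "grid2d"),
            all(dim(psi) == c(grid$nx + 1L, grid$ny + 1L)))
  out <- list(psi = psi, omega = NULL,
              u = apply_d1(psi, grid$yf, along = 2L),
              v = -apply_d1(psi, grid$xf, along = 1L),
              grid = grid, v_in = NA_real_)
  class(out) <- "flow_field"
  out
}
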