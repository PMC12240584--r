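#' Brownian-dynamics trajectory of a single molecule in the flow
#'
#' Euler-Maruyama integration `x -> x + u(x) dt + sqrt(2 D dt) xi` with the
#' velocity interpolated bilinearly from the solved node field and specular
#' reflection at every boundary (walls and interface pass no solute, the
#' particle picture of the zero-flux condition).
#'
#' @param flow A `flow_field`.
#' @param D Molecular diffusion coefficient, um^2/s (61/63mer DNA: 95).
#' @param start Start position `c(x, y)` in um. Default: bulk centerline at
#'   mid-height.
#' @param duration Trajectory length, s.
#' @param dt Integration step, s; must satisfy
#'   `dt <= min(h_min^2 / (4 D), h_min / max speed)` with `h_min` the finest
#'   cell size. Default: half that bound.
#' @param seed Integer seed (set via [set.seed()]) making the trajectory
#'   bit-reproducible.
#' @param save_dt Time spacing of stored positions, s (integration runs at
#'   `dt`; positions are recorded every `save_dt`).
#' @return A `trajectory`: data.frame `path` with `time`, `x`, `y`; plus
#'   `dt`, `seed`, `D`.
#' @export
simulate_trajectory <- function(flow, D, start = NULL, duration = 600,
                                dt = NULL, seed = NULL, save_dt = 0.05) {
  stopifnot(inherits(flow, "flow_field"))
  g <- flow$grid
  if (is.null(start)) start <- c(g$width / 2, g$height / 2)
  if (start[1] < 0 || start[1] > g$width || start[2] < 0 ||
      start[2] > g$height) {
    stop("simulate_trajectory: start position outside the chamber",
         call. = FALSE)
  }
  h_min <- min(g$dx, g$dy)
  vmax <- max(sqrt(flow$u^2 + flow$v^2))
  dt_bound <- min(if (D > 0) h_min^2 / (4 * D) else Inf,
                  if (vmax > 0) h_min / vmax else Inf)
  if (is.null(dt)) {
    dt <- 0.5 * dt_bound
  } else if (dt > dt_bound) {
    stop(sprintf(paste0("simulate_trajectory: dt = %.4g s exceeds the ",
                        "stability bound %.4g s"), dt, dt_bound),
         call. = FALSE)
  }
  save_every <- max(1L, as.integer(round(save_dt / dt)))
  nsteps <- as.integer(ceiling(duration / dt / save_every)) * save_every
  if (!is.null(seed)) set.seed(seed)
  pos <- walk_cpp(start[1], start[2], D, dt, nsteps, save_every,
                  g$xf, g$yf, flow$u, flow$v)
  out <- list(
    path = data.frame(time = seq(0, by = dt * save_every,
                                 length.out = nrow(pos)),
                      x = pos[, 1], y = pos[, 2]),
    dt = dt, save_dt = dt * save_every, seed = seed, D = D
  )
  class(out) <- "trajectory"
  out
}

#' Sample a concentration field along a trajectory
#'
#' Bilinear interpolation of the (last-snapshot) relative concentration at
#' each stored trajectory point. Outside the outermost cell centers the field
#' is clamped to the nearest cell value.
#'
#' @param traj A `trajectory`.
#' @param field A `concentration_field` on the same chamber domain.
#' @param snapshot Snapshot index to sample (default: last).
#' @return Numeric vector of `c/c0` values, one per trajectory point.
#' @export
sample_along <- function(traj, field, snapshot = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(field, "concentration_field"))
  g <- field$grid
  if (max(traj$path$x) > g$width + 1e-9 || max(traj$path$y) > g$height + 1e-9) {
    stop("sample_along: trajectory and field domains differ", call. = FALSE)
  }
  if (is.null(snapshot)) snapshot <- dim(field$c)[3]
  interp_bilinear(g$xc, g$yc, field$c[, , snapshot],
                  traj$path$x, traj$path$y)
}

## bilinear interpolation on cell centers, clamped at the edges
interp_bilinear <- function(xc, yc, z, xp, yp) {
  nx <- length(xc); ny <- length(yc)
  ix <- pmin(pmax(findInterval(xp, xc), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(yp, yc), 1L), ny - 1L)
  tx <- pmin(pmax((xp - xc[ix]) / (xc[ix + 1L] - xc[ix]), 0), 1)
  ty <- pmin(pmax((yp - yc[iy]) / (yc[iy + 1L] - yc[iy]), 0), 1)
  z00 <- z[cbind(ix, iy)]; z10 <- z[cbind(ix + 1L, iy)]
  z01 <- z[cbind(ix, iy + 1L)]; z11 <- z[cbind(ix + 1L, iy + 1L)]
  (1 - tx) * ((1 - ty) * z00 + ty * z01) + tx * ((1 - ty) * z10 + ty * z11)
}

#' Oscillation metrics of a sampled concentration signal
#'
#' Summarizes the concentration excursions a molecule experiences along its
#' path: extreme ratios and the number of large-amplitude cycles. A cycle is
#' a passage below `low_frac * max(signal)` followed by a return above
#' `high_frac * max(signal)` (hysteresis suppresses chatter around a single
#' threshold).
#'
#' @param values Sampled signal (e.g. `c/c0` from [sample_along()]).
#' @param low_frac,high_frac Hysteresis fractions of the signal maximum.
#' @return An `oscillation_metrics` list: `max_ratio`, `min_ratio`,
#'   `n_cycles`, `cycle_amplitudes` (signal maximum within each completed
#'   cycle).
#' @export
oscillation_metrics <- function(values, low_frac = 0.5, high_frac = 0.8) {
  if (length(values) == 0L) {
    stop("oscillation_metrics: empty signal", call. = FALSE)
  }
  if (!(low_frac > 0 && low_frac < high_frac)) {
    stop("oscillation_metrics: need 0 < low_frac < high_frac", call. = FALSE)
  }
  mx <- max(values)
  lo <- low_frac * mx; hi <- high_frac * mx
  n_cycles <- 0L
  amplitudes <- numeric(0)
  state <- "high"           # armed once the signal has been low
  seg_min <- Inf
  for (v in values) {
    if (state == "high") {
      if (v < lo) { state <- "low"; seg_min <- v }
    } else {
      seg_min <- min(seg_min, v)
      if (v > hi) {
        state <- "high"
        n_cycles <- n_cycles + 1L
        amplitudes <- c(amplitudes, mx - seg_min)
      }
    }
  }
  structure(list(max_ratio = mx, min_ratio = min(values),
                 n_cycles = n_cycles, cycle_amplitudes = amplitudes),
            class = "oscillation_metrics")
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  cat(sprintf("<oscillation_metrics> max %.3g, min %.3g, %d cycle(s)\n",
              x$max_ratio, x$min_ratio, x$n_cycles))
  invisible(x)
}

#' Trajectory ensemble through a concentration field
#'
#' Convenience wrapper: simulates `n` trajectories with consecutive seeds and
#' samples one or more fields along each.
#'
#' @inheritParams simulate_trajectory
#' @param n Number of trajectories.
#' @param fields Named list of `concentration_field`s to sample.
#' @param base_seed Seed of the first trajectory; trajectory k uses
#'   `base_seed + k - 1`.
#' @return A list with `trajectories` and, per field name, a matrix of
#'   sampled values (points x trajectories).
#' @export
trajectory_ensemble <- function(flow, D, n = 20, duration = 600,
                                fields = list(), base_seed = 1,
                                start = NULL, dt = NULL, save_dt = 0.05) {
  trajs <- lapply(seq_len(n), function(k) {
    simulate_trajectory(flow, D, start = start, duration = duration,
                        dt = dt, seed = base_seed + k - 1L,
                        save_dt = save_dt)
  })
  samples <- lapply(fields, function(f) {
    vapply(trajs, function(tr) sample_along(tr, f),
           numeric(nrow(trajs[[1]]$path)))
  })
  list(trajectories = trajs, samples = samples)
}
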