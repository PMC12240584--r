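#' Build the discretization grid of the liquid chamber
#'
#' Tensor-product finite-volume grid: uniform in x, geometrically graded in y
#' so that the finest cells sit against the gas-water interface (`y = height`),
#' where the solute accumulation boundary layer of thickness `delta = D / v_e`
#' must be resolved. The grading ratio (`refine` = coarsest/finest cell height)
#' comes from the configuration.
#'
#' @param config A [chamber_config()].
#' @param min_diffusivity Optional smallest solute diffusivity (um^2/s) to be
#'   simulated on this grid. If given, the finest interfacial cell height must
#'   be at most a third of the boundary-layer thickness `D / v_e` (with `v_e`
#'   the mean inflow velocity); otherwise an error reports the required `ny`.
#' @return An object of class `grid2d` with faces (`xf`, `yf`), centers
#'   (`xc`, `yc`), spacings (`dx`, `dy`) and the cell `areas` matrix (um^2).
#' @export
#' @examples
#' g <- build_grid(chamber_config(nx = 60, ny = 200, refine = 1))
#' range(g$dy) # uniform 20 um
build_grid <- function(config, min_diffusivity = NULL) {
  validate_chamber_config(config)
  nx <- config$nx; ny <- config$ny
  dx <- rep(config$width / nx, nx)
  dy <- graded_spacings(config$height, ny, config$refine)
  if (!is.null(min_diffusivity)) {
    v_bar <- mean_inflow_velocity(config$inflow_rate, config$width,
                                  config$depth)
    delta <- min_diffusivity / v_bar
    if (dy[ny] > delta / 3) {
      ny_req <- required_ny(config$height, config$refine, delta / 3)
      stop(sprintf(paste0(
        "build_grid: finest cell (%.3g um) does not resolve the boundary ",
        "layer delta = D/v = %.3g um (need <= delta/3); use ny >= %d at ",
        "refine = %g"), dy[ny], delta, ny_req, config$refine), call. = FALSE)
    }
  }
  xf <- c(0, cumsum(dx))
  yf <- c(0, cumsum(dy))
  # guard against accumulation round-off on the last face
  xf[nx + 1] <- config$width
  yf[ny + 1] <- config$height
  g <- list(
    nx = nx, ny = ny,
    xf = xf, yf = yf,
    xc = (xf[-1] + xf[-(nx + 1)]) / 2,
    yc = (yf[-1] + yf[-(ny + 1)]) / 2,
    dx = diff(xf), dy = diff(yf),
    areas = outer(diff(xf), diff(yf)),
    width = config$width, height = config$height, depth = config$depth
  )
  class(g) <- "grid2d"
  g
}

## Geometric cell heights summing to `total`: coarsest at the bottom, finest
## (coarsest/refine) adjacent to the interface.
graded_spacings <- function(total, n, refine) {
  if (refine == 1) return(rep(total / n, n))
  s <- refine^(-1 / (n - 1))
  h1 <- total * (1 - s) / (1 - s^n)
  h1 * s^(seq_len(n) - 1)
}

## Smallest ny whose finest graded cell is below `target` um.
required_ny <- function(total, refine, target) {
  for (n in 2^(4:14)) {
    if (min(graded_spacings(total, n, refine)) <= target) {
      # refine by bisection to the smallest admissible n
      lo <- n / 2; hi <- n
      while (hi - lo > 1) {
        mid <- (lo + hi) %/% 2
        if (min(graded_spacings(total, mid, refine)) <= target) hi <- mid
        else lo <- mid
      }
      return(hi)
    }
  }
  stop("build_grid: no feasible ny below 16384; increase 'refine'",
       call. = FALSE)
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d cells over %g x %g um\n",
              x$nx, x$ny, x$width, x$height))
  cat(sprintf("  dx %.3g um; dy %.3g (interface) .. %.3g (bottom) um\n",
              x$dx[1], x$dy[x$ny], x$dy[1]))
  invisible(x)
}
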