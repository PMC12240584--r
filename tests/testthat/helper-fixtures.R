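## Shared fixtures. Expensive reference runs are computed once per session
## and memoised here; small-scale configs keep unit tests fast.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## small chamber for unit tests: coarse but boundary-layer-resolving for
## fast solutes (D >= 400)
small_config <- function(...) {
  args <- modifyList(list(nx = 48, ny = 64, refine = 30, nz_gas = 36,
                          refine_gas = 20), list(...))
  do.call(chamber_config, args)
}

## zero-evaporation profile on a grid (for cavity-style tests)
zero_evap <- function(grid) {
  structure(list(x = grid$xc, dx = grid$dx, v_e = rep(0, grid$nx),
                 v_bar = 0, kappa = 1, calibrated = FALSE),
            class = "evaporation_profile")
}

## uniform evaporation profile balancing the configured inflow
uniform_evap <- function(grid, config) {
  v <- mean_inflow_velocity(config$inflow_rate, config$width, config$depth)
  structure(list(x = grid$xc, dx = grid$dx, v_e = rep(v, grid$nx),
                 v_bar = v, kappa = 1, calibrated = TRUE),
            class = "evaporation_profile")
}

## small solved flow (gas -> vapor -> evap -> liquid), memoised
small_flow <- function() {
  memo("small_flow", {
    cfg <- small_config()
    p <- physical_params(45)
    gas <- solve_gas_flow(cfg, p)
    sh <- interface_shear(gas, p)
    vap <- solve_vapor_field(gas, p, cfg)
    ev <- evaporation_profile(vap, p, cfg)
    g <- build_grid(cfg, min_diffusivity = 400)
    fl <- solve_liquid_flow(cfg, p, ev, sh, grid = g)
    list(config = cfg, params = p, gas = gas, shear = sh, vapor = vap,
         evap = ev, grid = g, flow = fl)
  })
}

## quiescent flow on a uniform grid (psi = 0)
still_flow <- function(nx = 32, ny = 32, width = 1000, height = 1000) {
  cfg <- chamber_config(width = width, height = height, nx = nx, ny = ny,
                        refine = 1, inflow_rate = 0)
  g <- build_grid(cfg)
  flow_from_psi(g, matrix(0, nx + 1, ny + 1))
}

## steady Mg2+ field on the small chamber, shared by several test files
small_mg_steady <- function() {
  memo("small_mg_steady",
       steady_state_field(small_flow()$flow, solute_spec("mg", 705),
                          tol = 1e-3))
}

## full-scale reference pipelines (used by the acceptance tests), memoised
ref_fig2 <- function() memo("ref_fig2", run_fig2_accumulation())
ref_fig3 <- function() memo("ref_fig3", run_fig3_saltcycle(seed = 101))
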