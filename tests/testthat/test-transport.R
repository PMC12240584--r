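test_that("quiescent chamber stays at the loaded concentration", {
  fl <- still_flow()
  fld <- simulate_transport(fl, solute_spec("x", 100), duration = 50,
                            dt = 0.5, snapshot_times = 50)
  expect_equal(max(abs(fld$c - 1)), 0, tolerance = 1e-12)
})

test_that("solute mass is conserved through advection and diffusion", {
  fx <- small_flow()
  fld <- simulate_transport(fx$flow, solute_spec("mg", 705), duration = 120,
                            snapshot_times = 120)
  expect_lt(fld$mass_error, 1e-9)
})

test_that("1D evaporation column matches an independent fine-grid solver", {
  # uniform upward flow v toward a no-flux interface: the boundary layer
  # c ~ exp(-(H - y) v / D) builds from a uniform load
  v <- 10; D <- 95; H <- 600
  # package side: exact uniform upward flux imposed via the streamfunction,
  # so every column is the same 1D problem on the graded grid
  cfg <- chamber_config(width = 200, height = H, depth = 250,
                        inflow_rate = v * 200 * 250 / 1e6,
                        nx = 16, ny = 96, refine = 30)
  g <- build_grid(cfg, min_diffusivity = D)
  fl <- flow_from_psi(g, -v * matrix(g$xf, g$nx + 1, g$ny + 1))
  fl$evap <- uniform_evap(g, cfg)
  fld <- simulate_transport(fl, solute_spec("dna", D), duration = 200,
                            snapshot_times = c(60, 200))
  # independent method-of-lines reference on a fine uniform 1D grid
  n_ref <- 2400
  dy <- H / n_ref
  yc_ref <- (seq_len(n_ref) - 0.5) * dy
  deriv <- function(t, cc, parms) {
    # upward total flux through faces 0..n (inlet carries c = 0; the
    # interface passes no solute)
    f_adv <- c(0, v * cc[-n_ref], 0)
    f_dif <- c(0, -D * diff(cc) / dy, 0)
    f <- f_adv + f_dif
    f[n_ref + 1] <- 0
    list((f[seq_len(n_ref)] - f[seq_len(n_ref) + 1]) / dy)
  }
  sol <- deSolve::ode(y = rep(1, n_ref), times = c(0, 60, 200), func = deriv,
                      parms = NULL, method = "lsoda", rtol = 1e-9,
                      atol = 1e-11, jactype = "bandint", bandup = 1,
                      banddown = 1)
  for (k in 1:2) {
    pkg_prof <- fld$c[8, , k]
    ref_prof <- stats::approx(yc_ref, sol[k + 1, -1], xout = g$yc, rule = 2)$y
    expect_lt(max(abs(pkg_prof - ref_prof)) / max(ref_prof), 0.02)
  }
  # e-folding depth of the developing boundary layer matches D / v
  prof <- fld$c[8, , 2]
  top <- prof[g$ny]
  j_e <- max(which(prof < top / exp(1)))
  depth_e <- g$height - g$yc[j_e]
  expect_equal(depth_e, D / v, tolerance = 0.35)
})

test_that("transport is positivity-preserving for a sharp step load", {
  fx <- small_flow()
  sol <- solute_spec("step", 705, support = "plug", plug_height = 400)
  fld <- simulate_transport(fx$flow, sol, duration = 60, snapshot_times = 60)
  expect_gte(min(fld$c), 0)
  expect_lt(fld$mass_error, 1e-9)
})

test_that("accumulation decreases with diffusivity and respects the 1D bound", {
  fx <- small_flow()
  maxes <- vapply(c(500, 1000, 4000), function(D) {
    fld <- simulate_transport(fx$flow, solute_spec("s", D), duration = 400,
                              snapshot_times = 400)
    max(fld$c)
  }, numeric(1))
  expect_true(all(diff(maxes) < 0))
  # pile-up bound: max c/c0 <= height / (D / v_bar)
  v_bar <- fx$evap$v_bar
  expect_true(all(maxes <= fx$config$height / (c(500, 1000, 4000) / v_bar)))
})

test_that("very large diffusivity keeps the chamber well mixed", {
  fx <- small_flow()
  fld <- steady_state_field(fx$flow, solute_spec("fast", 1e6), tol = 1e-4)
  expect_equal(max(fld$c), 1, tolerance = 0.05)
})

test_that("time step above the advective CFL limit is refused with the bound", {
  fx <- small_flow()
  lim <- evapopore:::advective_dt_limit(fx$flow)
  expect_error(simulate_transport(fx$flow, solute_spec("mg", 705),
                                  duration = 10, dt = 2 * lim),
               "stability limit")
})

test_that("under-resolved boundary layer is refused", {
  fx <- small_flow()
  expect_error(simulate_transport(fx$flow, solute_spec("slow", 20),
                                  duration = 10),
               "cannot resolve")
})

test_that("max series excludes the boundary ring and handles empty input", {
  fx <- small_flow()
  fld <- simulate_transport(fx$flow, solute_spec("mg", 705), duration = 30,
                            snapshot_times = c(10, 30))
  ser <- max_accumulation_series(fld)
  expect_equal(nrow(ser), 2)
  expect_true(all(ser$max_c >= 1))
  fld0 <- fld; fld0$times <- numeric(0)
  expect_error(max_accumulation_series(fld0), "no snapshots")
})

test_that("constant field stays constant in the accumulation series", {
  fl <- still_flow()
  fld <- simulate_transport(fl, solute_spec("x", 50), duration = 20,
                            dt = 0.5, snapshot_times = c(5, 20))
  ser <- max_accumulation_series(fld)
  expect_equal(ser$max_c, c(1, 1), tolerance = 1e-12)
})

test_that("steady-state integration reports convergence", {
  fx <- small_flow()
  fld <- small_mg_steady()
  expect_s3_class(fld, "concentration_field")
  expect_true(is.finite(attr(fld, "settling_time")))
  # a further 100 s changes the field by less than tol
  nxt <- evapopore:::continue_transport(fx$flow, solute_spec("mg", 705),
                                        fld$c[, , 1], 100)
  expect_lt(max(abs(nxt$c[, , 1] - fld$c[, , 1])) / max(fld$c), 2e-3)
})
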