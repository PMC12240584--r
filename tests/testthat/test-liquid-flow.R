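test_that("solver reproduces the Stokes lid-driven cavity benchmark", {
  # converged independent benchmark for the square creeping-flow cavity:
  # psi_min = -0.10007 U L at (0.5 L, 0.765 L)
  cfg <- chamber_config(width = 1000, height = 1000, inflow_rate = 0,
                        gas_flow = 0, nx = 64, ny = 64, refine = 1)
  g <- build_grid(cfg)
  fl <- solve_liquid_flow(cfg, physical_params(45), zero_evap(g),
                          coupling = "prescribed", u_t = rep(1, g$nx + 1),
                          grid = g, hele_shaw = FALSE)
  k <- which.min(fl$psi)
  ij <- arrayInd(k, dim(fl$psi))
  expect_equal(min(fl$psi), -0.10007 * 1 * 1000, tolerance = 0.02)
  expect_equal(g$xf[ij[1]] / 1000, 0.5, tolerance = 0.02)
  expect_equal(g$yf[ij[2]] / 1000, 0.765, tolerance = 0.02)
})

test_that("uniform evaporation with no shear gives near-plug upward flow", {
  cfg <- small_config()
  g <- build_grid(cfg)
  ev <- uniform_evap(g, cfg)
  fl <- solve_liquid_flow(cfg, physical_params(45), ev,
                          coupling = "prescribed",
                          u_t = rep(0, g$nx + 1), grid = g)
  v_in <- mean_inflow_velocity(cfg$inflow_rate, cfg$width, cfg$depth)
  mid <- fl$v[seq(10, 38), seq(10, 55)]
  # away from the side-wall layers the vertical velocity is the plug value
  expect_equal(stats::median(mid), v_in, tolerance = 0.25)
  # and there is no recirculation vortex
  expect_true(all(is.na(fl$diagnostics$vortex_center)))
})

test_that("discrete incompressibility holds to round-off", {
  fx <- small_flow()
  fl <- fx$flow
  g <- fx$grid
  ux <- evapopore:::apply_d1(fl$u, g$xf, along = 1L)
  vy <- evapopore:::apply_d1(fl$v, g$yf, along = 2L)
  expect_lt(max(abs(ux + vy)), 1e-6 * max(abs(fl$u)))
})

test_that("gas shear creates the interfacial vortex", {
  fx <- small_flow()
  # driven case: an interior streamfunction extremum beyond the boundary range
  expect_false(any(is.na(fx$flow$diagnostics$vortex_center)))
  # the vortex center sits below the interface, inside the chamber
  vc <- fx$flow$diagnostics$vortex_center
  expect_true(vc[2] > 0.75 * fx$config$height && vc[2] < fx$config$height)
  # tangential speed at the interface equals the calibrated peak
  expect_equal(fx$flow$diagnostics$max_interface_speed,
               fx$config$interface_peak_speed, tolerance = 0.01)
})

test_that("Stokes superposition: inflow-driven and shear-driven parts add", {
  cfg <- small_config()
  g <- build_grid(cfg)
  p <- physical_params(45)
  ev <- uniform_evap(g, cfg)
  ut <- 500 * sin(pi * g$xf / cfg$width)
  both <- solve_liquid_flow(cfg, p, ev, coupling = "prescribed", u_t = ut,
                            grid = g)
  only_in <- solve_liquid_flow(cfg, p, ev, coupling = "prescribed",
                               u_t = rep(0, g$nx + 1), grid = g)
  cfg0 <- small_config(inflow_rate = 0)
  only_sh <- solve_liquid_flow(cfg0, p, zero_evap(g),
                               coupling = "prescribed", u_t = ut, grid = g)
  expect_equal(both$psi, only_in$psi + only_sh$psi,
               tolerance = 1e-8 * max(abs(both$psi)))
})

test_that("solver refuses an unbalanced evaporation profile", {
  cfg <- small_config()
  g <- build_grid(cfg)
  ev <- uniform_evap(g, cfg)
  ev$v_e <- ev$v_e * 0.5                     # uncalibrated: kappa halved
  expect_error(solve_liquid_flow(cfg, physical_params(45), ev,
                                 coupling = "prescribed",
                                 u_t = rep(0, g$nx + 1), grid = g),
               "no steady solution")
})

test_that("mass balance diagnostic reflects calibration", {
  fx <- small_flow()
  expect_lt(check_mass_balance(fx$flow, fx$config), 0.005)
  # zero-inflow configuration reports the absolute outflux, flagged
  cfg0 <- chamber_config(width = 1000, height = 1000, inflow_rate = 0,
                         gas_flow = 0, nx = 32, ny = 32, refine = 1)
  g0 <- build_grid(cfg0)
  fl0 <- solve_liquid_flow(cfg0, physical_params(45), zero_evap(g0),
                           coupling = "prescribed",
                           u_t = rep(0, g0$nx + 1), grid = g0)
  mb <- check_mass_balance(fl0, cfg0)
  expect_true(isTRUE(attr(mb, "zero_inflow")))
  expect_equal(as.numeric(mb), 0)
})

test_that("velocity histogram is a unit-mass distribution", {
  fx <- small_flow()
  h <- velocity_histogram(fx$flow, breaks = 30)
  expect_equal(sum(h$density), 1, tolerance = 1e-12)
  # support spans bulk (~10 um/s) to interface (~1 mm/s) speeds
  expect_lt(10^h$lower[1], 15)
  expect_gt(10^h$upper[nrow(h)], 500)
  # uniform flow concentrates in a single bin
  g <- build_grid(chamber_config(width = 1000, height = 1000, nx = 32,
                                 ny = 32, refine = 1, inflow_rate = 0))
  uni <- flow_from_psi(g, outer(g$xf, rep(-5, g$ny + 1)))  # v = 5 um/s
  hu <- velocity_histogram(uni, breaks = c(0, 4.9, 5.1, 10), log10 = FALSE)
  expect_equal(hu$density[2], 1, tolerance = 1e-12)
  expect_error(velocity_histogram(still_flow()), "empty")
})

test_that("grid refinement changes the interfacial peak by less than 5%", {
  fx <- small_flow()
  cfg2 <- small_config(nx = 96, ny = 128)
  p <- physical_params(45)
  gas2 <- solve_gas_flow(cfg2, p)
  sh2 <- interface_shear(gas2, p)
  vp2 <- solve_vapor_field(gas2, p, cfg2)
  ev2 <- evaporation_profile(vp2, p, cfg2)
  g2 <- build_grid(cfg2, min_diffusivity = 400)
  fl2 <- solve_liquid_flow(cfg2, p, ev2, sh2, grid = g2)
  expect_equal(fl2$diagnostics$max_interface_speed,
               fx$flow$diagnostics$max_interface_speed, tolerance = 0.05)
})
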