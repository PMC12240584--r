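## Orchestration of the two reference computational experiments and the
## machine-readable comparison report against the study's printed numbers.

#' Reference metric values and comparison tolerances
#'
#' The printed simulation-derived quantities the pipelines compare against:
#' chamber-averaged and minimum evaporation velocity, peak interfacial
#' tangential speed, DNA fold-accumulation at 5 min / 1 h, ninefold Mg2+
#' enrichment, trajectory-sampled Mg (3x) and DNA (4x) oscillation maxima,
#' and the 83-day RNA half-life.
#'
#' @format A data.frame with columns `metric`, `reference`, `tolerance`
#'   (relative).
#' @export
reference_values <- data.frame(
  metric = c("v_bar_evap", "v_min_evap", "max_interface_speed",
             "dna_max_300s", "dna_max_3600s", "mg_steady_max",
             "traj_mg_max", "traj_dna_max", "rna_half_life_days"),
  reference = c(10.5, 5, 900, 3, 30, 9, 3, 4, 83),
  tolerance = c(0.10, 0.20, 0.25, 0.15, 0.15, 0.15, NA, NA, 0.20)
)

compare_metric <- function(name, value) {
  row <- reference_values[reference_values$metric == name, ]
  if (nrow(row) == 0L || is.na(row$tolerance)) {
    return(list(value = value, reference = row$reference %||% NA_real_,
                deviation = NA_real_, pass = NA))
  }
  dev <- (value - row$reference) / row$reference
  list(value = value, reference = row$reference, deviation = dev,
       pass = abs(dev) <= row$tolerance)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Run the gas-to-accumulation reference experiment
#'
#' Chains gas flow, vapor transport, evaporation calibration, liquid Stokes
#' flow and one hour of 63mer DNA transport at the reference configuration
#' (4 nl/s, 250 ml/min, 45 degC), and reports the headline metrics next to
#' the printed values.
#'
#' @param config A [chamber_config()]; default [fig2_config()].
#' @param params A [physical_params()]; default 45 degC.
#' @param duration Transport time, s.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return A `scenario_report` (list): `metrics`, `comparisons`, intermediate
#'   objects (`flow`, `evap`, `field`), and a run `manifest`.
#' @export
run_fig2_accumulation <- function(config = fig2_config(),
                                  params = physical_params(45),
                                  duration = 3600, out_dir = NULL) {
  gas <- solve_gas_flow(config, params)
  shear <- interface_shear(gas, params)
  vapor <- solve_vapor_field(gas, params, config)
  evap <- evaporation_profile(vapor, params, config)
  grid <- build_grid(config, min_diffusivity = 95)
  flow <- solve_liquid_flow(config, params, evap, shear, grid = grid)
  dna <- solute_spec("dna63", 95)
  snaps <- sort(unique(c(if (duration >= 300) 300,
                         seq(0, duration, length.out = 7)[-1], duration)))
  field <- simulate_transport(flow, dna, duration, snapshot_times = snaps)
  i300 <- which.min(abs(field$times - 300))
  iend <- length(field$times)
  hist <- velocity_histogram(flow)
  metrics <- list(
    v_bar_evap = evap$v_bar,
    v_min_evap = min(evap$v_e[2:(length(evap$v_e) - 1L)]),
    max_interface_speed = flow$diagnostics$max_interface_speed,
    dna_max_300s = max(field$c[, , i300]),
    dna_max_3600s = max(field$c[, , iend]),
    mass_error = field$mass_error,
    speed_range = range(sqrt(flow$u^2 + flow$v^2))
  )
  comparisons <- lapply(
    setNames(nm = c("v_bar_evap", "v_min_evap", "max_interface_speed",
                    "dna_max_300s", "dna_max_3600s")),
    function(nm) compare_metric(nm, metrics[[nm]]))
  report <- structure(list(
    scenario = "fig2_accumulation",
    metrics = metrics, comparisons = comparisons,
    accumulation = max_accumulation_series(field),
    histogram = hist,
    flow = flow, evap = evap, field = field,
    manifest = run_manifest(config, params, seeds = NULL)
  ), class = "scenario_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Run the salt-cycling reference experiment
#'
#' Steady Mg2+ and 61mer DNA fields in the FRET-buffer configuration
#' (3 nl/s, 230 ml/min, 45 degC), a seeded random-walk ensemble through both
#' fields, oscillation metrics, the duplex-fraction map and separation-cycle
#' counts.
#'
#' @param config A [chamber_config()]; default [fig3_config()].
#' @param params A [physical_params()].
#' @param n_traj Ensemble size (0 = fields only).
#' @param seed Base seed for the ensemble.
#' @param traj_duration Trajectory length, s.
#' @param out_dir Optional directory for artifacts.
#' @param fields Optional cached `list(mg = , dna = )` of steady
#'   `concentration_field`s from a previous run with the same configuration,
#'   skipping the steady-state solves.
#' @param cycle_dt Time resolution (s) at which trajectory samples are fed
#'   into the strand-state timeline (melt/anneal residences are seconds to
#'   minutes, so sub-second resolution only adds cost).
#' @return A `scenario_report`.
#' @export
run_fig3_saltcycle <- function(config = fig3_config(),
                               params = physical_params(45),
                               n_traj = 20, seed = 1,
                               traj_duration = 600, out_dir = NULL,
                               fields = NULL, cycle_dt = 0.25) {
  gas <- solve_gas_flow(config, params)
  shear <- interface_shear(gas, params)
  vapor <- solve_vapor_field(gas, params, config)
  evap <- evaporation_profile(vapor, params, config)
  grid <- build_grid(config, min_diffusivity = 95)
  flow <- solve_liquid_flow(config, params, evap, shear, grid = grid)
  if (is.null(fields)) {
    mg_field <- steady_state_field(flow, solute_spec("mg", 705), tol = 1e-3)
    dna_field <- steady_state_field(flow, solute_spec("dna61", 95),
                                    tol = 1e-3)
  } else {
    mg_field <- fields$mg
    dna_field <- fields$dna
  }
  metrics <- list(
    v_bar_evap = evap$v_bar,
    mg_steady_max = max(mg_field$c[, , 1]),
    dna_steady_max = max(dna_field$c[, , 1])
  )
  osc <- NULL
  if (n_traj > 0) {
    ens <- trajectory_ensemble(flow, D = 95, n = n_traj,
                               duration = traj_duration,
                               fields = list(mg = mg_field, dna = dna_field),
                               base_seed = seed)
    mg_osc <- apply(ens$samples$mg, 2, function(v)
      oscillation_metrics(v)$max_ratio)
    dna_osc <- apply(ens$samples$dna, 2, function(v)
      oscillation_metrics(v)$max_ratio)
    thermo <- nn_thermo(oligo_sequences[["fret24_1"]])
    ions <- fret_buffer_ions()
    thin <- max(1L, as.integer(round(
      cycle_dt / ens$trajectories[[1]]$save_dt)))
    cycles <- vapply(seq_len(n_traj), function(k) {
      tr <- ens$trajectories[[k]]
      keep <- seq(1, nrow(tr$path), by = thin)
      separation_cycles(
        thermo, tr$path$time[keep],
        mg = ions$mg * ens$samples$mg[keep, k],
        ct = ions$ct * pmax(ens$samples$dna[keep, k], 1e-6),
        monovalent = ions$na + ions$tris_factor * ions$tris,
        temperature = params$temperature)$n_cycles
    }, numeric(1))
    metrics$traj_mg_max <- max(mg_osc)
    metrics$traj_dna_max <- max(dna_osc)
    metrics$mean_cycles <- mean(cycles)
    osc <- list(mg_max_per_traj = mg_osc, dna_max_per_traj = dna_osc,
                cycles_per_traj = cycles, ensemble = ens)
  }
  comparisons <- lapply(
    setNames(nm = intersect(names(metrics), reference_values$metric)),
    function(nm) compare_metric(nm, metrics[[nm]]))
  report <- structure(list(
    scenario = "fig3_saltcycle",
    metrics = metrics, comparisons = comparisons,
    flow = flow, evap = evap,
    mg_field = mg_field, dna_field = dna_field, oscillations = osc,
    manifest = run_manifest(config, params, seeds = seed)
  ), class = "scenario_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

run_manifest <- function(config, params, seeds = NULL) {
  cfg_str <- paste(utils::capture.output(utils::str(unclass(config))),
                   collapse = "\n")
  list(
    config = unclass(config),
    params = unclass(params),
    config_hash = sum(utf8ToInt(cfg_str) * seq_along(utf8ToInt(cfg_str))) %%
      .Machine$integer.max,
    seeds = seeds,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("evapopore")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  slim <- report[c("scenario", "metrics", "comparisons", "manifest")]
  jsonlite::write_json(slim, file.path(out_dir,
                                       paste0(report$scenario, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(report$accumulation)) {
    write.csv(report$accumulation,
              file.path(out_dir, paste0(report$scenario, "_accumulation.csv")),
              row.names = FALSE)
  }
  invisible(out_dir)
}

#' Run both reference experiments and the half-life estimate
#'
#' Executes the accumulation and salt-cycling pipelines plus the RNA
#' hydrolysis estimate and collects every headline metric into one report.
#'
#' @param out_dir Optional directory for JSON/CSV artifacts.
#' @param seed Base seed for the stochastic (trajectory) stage.
#' @param n_traj Trajectory ensemble size.
#' @return A `scenario_report` combining all metrics and comparisons.
#' @export
run_acceptance_suite <- function(out_dir = NULL, seed = 1, n_traj = 20) {
  fig2 <- run_fig2_accumulation(out_dir = out_dir)
  fig3 <- run_fig3_saltcycle(seed = seed, n_traj = n_traj, out_dir = out_dir)
  t_half <- as.numeric(rna_half_life(hydrolysis_conditions()))
  metrics <- c(fig2$metrics[c("v_bar_evap", "v_min_evap",
                              "max_interface_speed", "dna_max_300s",
                              "dna_max_3600s", "mass_error")],
               fig3$metrics[c("mg_steady_max", "dna_steady_max",
                              "traj_mg_max", "traj_dna_max",
                              "mean_cycles")],
               list(rna_half_life_days = t_half))
  comparisons <- c(fig2$comparisons, fig3$comparisons,
                   list(rna_half_life_days =
                          compare_metric("rna_half_life_days", t_half)))
  report <- structure(list(
    scenario = "acceptance_suite", metrics = metrics,
    comparisons = comparisons, fig2 = fig2, fig3 = fig3,
    manifest = fig3$manifest
  ), class = "scenario_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report>", x$scenario, "\n")
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf("  %-22s %10.4g  (ref %g, dev %+.1f%%, %s)\n", nm, cmp$value,
                cmp$reference, 100 * cmp$deviation,
                if (isTRUE(cmp$pass)) "ok" else "off"))
  }
  extra <- setdiff(names(x$metrics), names(x$comparisons))
  for (nm in extra) {
    cat(sprintf("  %-22s %s\n", nm,
                paste(signif(x$metrics[[nm]], 4), collapse = " ")))
  }
  invisible(x)
}
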