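# Scenario configuration, packaged presets reproducing the four headline
# runs (albumin/fibrinogen x constant outlet velocity / pulsatile v(x,t)),
# and the end-to-end pipeline: waveform -> hemodynamics -> wall mechanics ->
# transport-adsorption -> summary.

scenario_schema <- c("name", "geometry", "material", "fluid", "waveform",
                     "flow", "protein", "kinetics", "transport", "seed")

#' Construct a complete simulation scenario
#'
#' A scenario is a fully serializable definition of one coupled run. All
#' physical quantities are SI; key names carry unit suffixes in the saved
#' file.
#'
#' @param name Scenario name.
#' @param geometry,material,fluid,protein,kinetics Lists of constructor
#'   arguments for [graft_geometry()], [wall_material()], [fluid_properties()],
#'   [protein_spec()], [kinetic_params()] (defaults used for omitted fields).
#' @param waveform List: `mean_inlet_pa`, `mean_outlet_pa`,
#'   `pulse_amplitude_pa`, `period_s`, `n_samples`, `n_harmonics`.
#' @param flow List: `rate_m3_s` (mean flow), `pulsatility_index`
#'   ((Qmax-Qmin)/Qmean of the pulsatile gradient scaling), `n_harmonics`.
#' @param transport List: `mode` ("vxt" or "constant"), `outlet_velocity_m_s`
#'   (constant mode), `nz`, `nr`, `dt_s`, `t_end_s`, `dt_out_s`,
#'   `diffusivity` ("auto" or m^2/s).
#' @param seed Integer seed (the pipeline is deterministic; the seed feeds the
#'   synthetic waveform generator's optional noise).
#' @return Object of class `tevg_scenario`.
#' @export
tevg_scenario <- function(name,
                          geometry = list(), material = list(), fluid = list(),
                          waveform = list(), flow = list(),
                          protein = "albumin", kinetics = list(),
                          transport = list(), seed = 1L) {
  wf_default <- list(mean_inlet_pa = 11819, mean_outlet_pa = 12784,
                     pulse_amplitude_pa = 2650, period_s = 1.5,
                     n_samples = 512L, n_harmonics = 8L)
  fl_default <- list(rate_m3_s = 3.33e-7, pulsatility_index = 3,
                     n_harmonics = 8L)
  tr_default <- list(mode = "vxt", outlet_velocity_m_s = 0.047,
                     nz = 120L, nr = 24L, dt_s = 1e-3, t_end_s = 1.5,
                     dt_out_s = 0.009, diffusivity = "auto")
  check_named_subset <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop_invalid("unknown key(s) in `", section, "`: ",
                   paste(bad, collapse = ", "))
    }
  }
  check_named_subset(waveform, names(wf_default), "waveform")
  check_named_subset(flow, names(fl_default), "flow")
  check_named_subset(transport, names(tr_default), "transport")
  structure(list(
    name = name,
    geometry = utils::modifyList(formals_defaults(graft_geometry), geometry),
    material = utils::modifyList(formals_defaults(wall_material), material),
    fluid = utils::modifyList(formals_defaults(fluid_properties), fluid),
    waveform = utils::modifyList(wf_default, waveform),
    flow = utils::modifyList(fl_default, flow),
    protein = protein,
    kinetics = utils::modifyList(formals_defaults(kinetic_params), kinetics),
    transport = utils::modifyList(tr_default, transport),
    seed = as.integer(seed)
  ), class = "tevg_scenario")
}

formals_defaults <- function(f) {
  fx <- formals(f)
  fx <- fx[vapply(fx, function(x) !is.symbol(x) || nzchar(as.character(x)),
                  TRUE)]
  lapply(fx, eval, envir = baseenv())
}

#' @export
print.tevg_scenario <- function(x, ...) {
  cat("TEVG scenario:", x$name, "\n")
  cat("  protein:", if (is.character(x$protein)) x$protein else x$protein$name,
      "| outlet condition:", x$transport$mode,
      "| window:", x$transport$t_end_s, "s | seed:", x$seed, "\n")
  invisible(x)
}

#' Packaged scenario presets
#'
#' The four headline runs: `"fibrinogen_vxt"`, `"albumin_vxt"`,
#' `"fibrinogen_constant"`, `"albumin_constant"` — each protein under either
#' the pulsatile space-time velocity field or a constant 0.047 m/s outlet
#' velocity. Kinetic and protein parameters carry the packaged parameter-table
#' values verbatim (`k_f = 9`, `CF_max_inlet = 0.0118`,
#' `CA_max_inlet = 0.753`, ...).
#'
#' @param name Preset name; `list_presets()` returns the available names.
#' @param seed Integer seed.
#' @return A `tevg_scenario`.
#' @export
preset_scenario <- function(name = list_presets(), seed = 1L) {
  name <- match.arg(name)
  parts <- strsplit(name, "_")[[1]]
  tevg_scenario(
    name = name,
    protein = parts[1],
    transport = list(mode = if (parts[2] == "vxt") "vxt" else "constant"),
    seed = seed
  )
}

#' @rdname preset_scenario
#' @export
list_presets <- function() {
  c("fibrinogen_vxt", "albumin_vxt", "fibrinogen_constant", "albumin_constant")
}

resolve_protein <- function(p) {
  if (inherits(p, "protein_spec")) return(p)
  if (is.character(p)) {
    return(switch(p, albumin = albumin_spec(), fibrinogen = fibrinogen_spec(),
                  stop_invalid("unknown protein preset `", p, "`")))
  }
  do.call(protein_spec, p)
}

#' Save / load a scenario (YAML)
#'
#' `load_scenario(save_scenario(s, path))` is the identity. Unknown or missing
#' top-level sections are rejected with a named error.
#'
#' @param scenario A `tevg_scenario`.
#' @param path File path.
#' @export
save_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "tevg_scenario"))
  x <- unclass(scenario)
  if (inherits(x$protein, "protein_spec")) {
    x$protein <- Filter(Negate(is.null), unclass(x$protein))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_scenario
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop_invalid("no such scenario file: ", path)
  x <- yaml::read_yaml(path)
  missing <- setdiff(scenario_schema, names(x))
  if (length(missing)) {
    stop_invalid("scenario file is missing section(s): ",
                 paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(x), scenario_schema)
  if (length(extra)) {
    stop_invalid("scenario file has unknown section(s): ",
                 paste(extra, collapse = ", "))
  }
  protein <- if (is.list(x$protein)) x$protein[
    intersect(names(x$protein),
              c("name", "molar_mass", "effective_density", "shape", "diameter",
                "cross_section", "length", "inlet_max_concentration"))
  ] else x$protein
  tevg_scenario(name = x$name, geometry = x$geometry, material = x$material,
                fluid = x$fluid, waveform = x$waveform, flow = x$flow,
                protein = protein, kinetics = x$kinetics,
                transport = x$transport, seed = x$seed)
}

#' Pulsatile pressure-gradient series for a scenario
#'
#' Mean axial gradient from the experimental flow rate via Hagen-Poiseuille
#' (`8 mu Q / (pi R^4)` per unit length), plus the band-limited physiological
#' pulse shape scaled so the resulting flow waveform has the requested
#' pulsatility index `(Qmax - Qmin) / Qmean`. The per-harmonic flow response
#' uses the analytic Womersley flow-rate factors, so the scaling is exact for
#' the linear model.
#'
#' @param fluid A [fluid_properties()].
#' @param geom A [graft_geometry()].
#' @param flow_rate Mean flow rate (m^3/s).
#' @param pulsatility_index Target (Qmax - Qmin)/Qmean; 0 gives a steady
#'   gradient.
#' @param period Cycle period (s).
#' @param n_harmonics Number of gradient harmonics.
#' @return A [harmonic_series()] for `-dP/dz` (Pa/m).
#' @export
scenario_gradient_series <- function(fluid, geom, flow_rate = 3.33e-7,
                                     pulsatility_index = 3, period = 1.5,
                                     n_harmonics = 8L) {
  check_scalar(flow_rate, "flow_rate", positive = TRUE)
  check_scalar(pulsatility_index, "pulsatility_index", nonneg = TRUE)
  R <- geom$inner_radius
  g0 <- 8 * fluid$viscosity * flow_rate / (pi * R^4)
  w <- 2 * pi / period
  sh <- pulse_shape_coeffs(n_harmonics = n_harmonics)
  if (pulsatility_index == 0) return(harmonic_series(g0, omega = w))
  # flow waveform of the unit-amplitude shape via analytic flow factors
  tt <- seq(0, period, length.out = 513)[-513]
  Q <- rep(0, length(tt))
  for (n in seq_len(n_harmonics)) {
    wn <- n * w
    alpha <- R * sqrt(wn * fluid$density / fluid$viscosity)
    fac <- womersley_flow_factor(R, alpha, fluid$density * wn)
    Cn <- complex(real = sh$An[n], imaginary = -sh$Bn[n])
    Q <- Q + Re(fac * Cn * exp(1i * wn * tt))
  }
  scale <- pulsatility_index * flow_rate / (max(Q) - min(Q))
  harmonic_series(A0 = g0, An = scale * sh$An, Bn = scale * sh$Bn, omega = w)
}

#' Run the full coupled pipeline for a scenario
#'
#' Executes waveform synthesis/fitting, pulsatile hemodynamics, quasi-static
#' wall mechanics and transport-adsorption in order, and assembles a
#' machine-readable summary (Reynolds number, Hagen-Poiseuille pressure drop,
#' peak wall shear stress, peak hoop stress and safety factor, near-wall
#' max/mean concentrations at the probe times 0.3 s and 1.179 s, and the
#' saturation time of the near-wall maximum trajectory at 99% of its
#' end-of-run plateau). Runs are deterministic for a fixed scenario and seed.
#'
#' @param scenario A `tevg_scenario` (see [preset_scenario()]).
#' @param outdir Optional output directory; if given, CSV exports and
#'   `summary.json` are written there.
#' @param keep_fields If `FALSE`, the bulky concentration frames are dropped
#'   from the returned object (summaries are unaffected).
#' @return Object of class `tevg_result`: list with elements `scenario`,
#'   `waveforms`, `gradient`, `flow_field`, `wall`, `transport`, `summary`,
#'   `timings`.
#' @export
run_pipeline <- function(scenario, outdir = NULL, keep_fields = TRUE) {
  stopifnot(inherits(scenario, "tevg_scenario"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  geom <- do.call(graft_geometry, scenario$geometry)
  mat <- do.call(wall_material, scenario$material)
  fluid <- do.call(fluid_properties, scenario$fluid)
  protein <- resolve_protein(scenario$protein)
  kin <- do.call(kinetic_params, scenario$kinetics)
  wf <- scenario$waveform
  tr <- scenario$transport

  # 1. waveform: synthetic inlet/outlet traces, fitted back to harmonics
  inlet_trace <- synthesize_trace(wf$mean_inlet_pa, wf$pulse_amplitude_pa,
                                  wf$period_s, wf$n_samples, scenario$seed)
  outlet_trace <- synthesize_trace(wf$mean_outlet_pa, wf$pulse_amplitude_pa,
                                   wf$period_s, wf$n_samples, scenario$seed)
  inlet_series <- fit_dft(inlet_trace, wf$n_harmonics)
  outlet_series <- fit_dft(outlet_trace, wf$n_harmonics)
  timings["waveform_s"] <- tic() - t0; t0 <- tic()

  # 2. hemodynamics: gradient waveform scaled to the target pulsatility,
  #    Womersley field and diagnostics
  grad <- scenario_gradient_series(fluid, geom,
                                   flow_rate = scenario$flow$rate_m3_s,
                                   pulsatility_index = scenario$flow$pulsatility_index,
                                   period = wf$period_s,
                                   n_harmonics = scenario$flow$n_harmonics)
  field <- womersley_field(grad, fluid, geom,
                           t = seq(0, tr$t_end_s, by = 0.003))
  Re_num <- reynolds_number(fluid, geom, scenario$flow$rate_m3_s)
  dP <- hagen_poiseuille_dp(fluid, geom, scenario$flow$rate_m3_s)
  wss <- wall_shear_stress(field, fluid)
  timings["hemodynamics_s"] <- tic() - t0; t0 <- tic()

  # 3. wall mechanics: quasi-static response to the outlet pressure waveform
  wall <- couple_quasi_static(outlet_series, geom, mat,
                              t = seq(0, tr$t_end_s, by = 0.003))
  timings["wall_s"] <- tic() - t0; t0 <- tic()

  # 4. transport-adsorption
  vel <- if (identical(tr$mode, "constant")) {
    build_velocity(tr$outlet_velocity_m_s, geom, t_end = tr$t_end_s)
  } else {
    build_velocity(field, geom, t_end = tr$t_end_s)
  }
  tsc <- transport_scenario(geom, fluid, protein, kin, vel,
                            diffusivity = tr$diffusivity,
                            nz = tr$nz, nr = tr$nr, dt = tr$dt_s,
                            t_end = tr$t_end_s, dt_out = tr$dt_out_s)
  res <- simulate_transport(tsc)
  timings["transport_s"] <- tic() - t0

  probes <- c(0.3, 1.179)
  probes <- probes[probes <= tr$t_end_s]
  probe_stats <- lapply(probes, function(tp) surface_stats(res, tp))
  names(probe_stats) <- paste0("t_", probes)
  sat <- plateau_time(res$near_wall$t_s, res$near_wall$max, fraction = 0.99,
                      require_plateau = FALSE)

  summary <- list(
    scenario = scenario$name,
    protein = protein$name,
    reynolds = Re_num,
    hagen_poiseuille_dp_pa = dP,
    womersley_alpha = womersley_number(fluid, geom, grad$omega),
    max_wss_pa = max(wss),
    mean_flow_rate_m3_s = mean(flow_rate(field)),
    max_hoop_stress_pa = max(wall$sigma_theta_pa),
    min_safety_factor = min(wall$safety_factor),
    max_strain = max(wall$strain),
    diffusivity_m2_s = tsc$diffusivity,
    max_near_wall_mol_m3 = max(res$near_wall$max),
    saturation_time_s = sat,
    mass_balance_error = res$mass_balance$relative_error,
    probes = lapply(probe_stats, function(d) {
      stats::setNames(as.list(d$max), paste0("max_", d$quantity))
    }),
    unit_normalization = list(
      k_r = "printed m^3/(s mol) used as 1/s",
      k_i = "printed L/s used as 1/s",
      R_Area = "printed 2.00e4 m^2 used as 2.00e-4 m^2",
      CA_max_inlet = "printed mol/m^2 used as mol/m^3"
    )
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    save_scenario(scenario, file.path(outdir, "scenario.yaml"))
    write_harmonic_series(inlet_series, file.path(outdir, "inlet_series.json"))
    write_wall_response(wall, file.path(outdir, "wall_response.csv"))
    utils::write.csv(res$near_wall, file.path(outdir, "near_wall.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!keep_fields) res$C <- NULL

  structure(list(scenario = scenario,
                 waveforms = list(inlet_trace = inlet_trace,
                                  inlet_series = inlet_series,
                                  outlet_series = outlet_series),
                 gradient = grad, flow_field = field, wall = wall,
                 transport = res, summary = summary, timings = timings),
            class = "tevg_result")
}

#' @export
print.tevg_result <- function(x, ...) {
  s <- x$summary
  cat("Pipeline result:", s$scenario, "(", s$protein, ")\n")
  cat(sprintf("  Re = %.2f | dP(HP) = %.3g Pa | alpha = %.2f | max WSS = %.3g Pa\n",
              s$reynolds, s$hagen_poiseuille_dp_pa, s$womersley_alpha,
              s$max_wss_pa))
  cat(sprintf("  max hoop stress = %.3g Pa (safety factor %.1f) | max strain = %.2f%%\n",
              s$max_hoop_stress_pa, s$min_safety_factor, 100 * s$max_strain))
  cat(sprintf("  max near-wall bulk = %.4g mol/m^3 | saturation time = %.3g s\n",
              s$max_near_wall_mol_m3, s$saturation_time_s))
  invisible(x)
}
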