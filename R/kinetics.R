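# Langmuir-type reversible/irreversible protein-surface adsorption kinetics:
#   P + S <-> P.S  (k_f forward, k_r reverse)    P.S -> Pbar.Sbar  (k_i)
# implemented as a well-mixed (CSTR) ODE system. Surface species are carried
# as volumetric concentrations through a configurable area-to-volume ratio
# (default: lumen area/volume of the graft, 2/R). Water released on hydrolysis
# is tracked only as a stoichiometric audit: with water at ~55,600 mol/m^3 it
# never limits the rates.

#' Protein specification
#'
#' Geometry (sphere or cylinder), molar mass, effective density and maximum
#' inlet concentration of a plasma protein.
#'
#' @param name Protein name.
#' @param molar_mass kg/mol.
#' @param effective_density kg/m^3 (density of the protein envelope used for
#'   volume bookkeeping).
#' @param shape `"sphere"` or `"cylinder"`.
#' @param diameter Sphere diameter (m); required for spheres.
#' @param cross_section Cylinder cross-sectional area (m^2); required for cylinders.
#' @param length Cylinder length (m); required for cylinders.
#' @param inlet_max_concentration mol/m^3.
#' @export
protein_spec <- function(name, molar_mass, effective_density,
                         shape = c("sphere", "cylinder"),
                         diameter = NULL, cross_section = NULL, length = NULL,
                         inlet_max_concentration) {
  shape <- match.arg(shape)
  check_scalar(molar_mass, "molar_mass", positive = TRUE)
  check_scalar(effective_density, "effective_density", positive = TRUE)
  check_scalar(inlet_max_concentration, "inlet_max_concentration", positive = TRUE)
  if (shape == "sphere") {
    check_scalar(diameter, "diameter", positive = TRUE)
  } else {
    check_scalar(cross_section, "cross_section", positive = TRUE)
    check_scalar(length, "length", positive = TRUE)
  }
  structure(list(name = name, molar_mass = molar_mass,
                 effective_density = effective_density, shape = shape,
                 diameter = diameter, cross_section = cross_section,
                 length = length,
                 inlet_max_concentration = inlet_max_concentration),
            class = "protein_spec")
}

#' Packaged protein presets
#'
#' Albumin: sphere of diameter 8.50e-3 um, M = 66.5 kg/mol, effective density
#' 70.69 kg/m^3, maximum inlet concentration 0.753 mol/m^3. Fibrinogen:
#' cylinder of cross-section 6.50e-4 um^2 and length 4.75e-3 um, M = 340
#' kg/mol, effective density 35.82 kg/m^3, maximum inlet concentration
#' 0.0118 mol/m^3.
#'
#' @return A [protein_spec()].
#' @export
albumin_spec <- function() {
  protein_spec("albumin", molar_mass = 66.5, effective_density = 70.69,
               shape = "sphere", diameter = 8.50e-9,
               inlet_max_concentration = 0.753)
}

#' @rdname albumin_spec
#' @export
fibrinogen_spec <- function() {
  protein_spec("fibrinogen", molar_mass = 340, effective_density = 35.82,
               shape = "cylinder", cross_section = 6.50e-16, length = 4.75e-9,
               inlet_max_concentration = 0.0118)
}

#' Adsorption kinetic parameters
#'
#' Defaults follow the packaged parameter table: `k_f = 9` m^3/(mol s),
#' `k_r = 1` /s, `k_i = 1e-4` /s, initial site density `G0 = 1e-5` mol/m^2
#' plus initial free surface concentration `CS0 = 9.9e-6` mol/m^2 (both start
#' as free sites; complexes start at zero), water 55,600 mol/m^3 at 310 K.
#' `k_r` and `k_i` are first-order rates: dimensional analysis of the kinetic
#' ODEs requires 1/s even though the source table prints volumetric units.
#' `fig4_kinetic_params()` is the named preset with `k_i = 1` /s used by the
#' pulse-injection demonstration.
#'
#' @param k_f Forward (adsorption) rate, m^3/(mol s), `>= 0`.
#' @param k_r Reverse (desorption) rate, 1/s, `>= 0`.
#' @param k_i Irreversible conversion rate, 1/s, `>= 0`.
#' @param G0 Initial surface site density, mol/m^2.
#' @param CS0 Additional initial free surface concentration, mol/m^2
#'   (`G0 >= CS0 >= 0`).
#' @param water_conc Bulk water concentration, mol/m^3.
#' @param m,n,r,v Stoichiometric water counts of the reaction scheme
#'   (audit only; water is in vast excess and does not feed back into rates).
#' @param temperature K, `> 0`.
#' @param area_to_volume Surface-to-volume ratio (1/m) converting surface
#'   densities (mol/m^2) to the volumetric basis of the well-mixed model;
#'   default `2 / R` for the 4-mm-ID graft lumen, i.e. 1000 /m.
#' @export
kinetic_params <- function(k_f = 9, k_r = 1, k_i = 1e-4,
                           G0 = 1e-5, CS0 = 9.9e-6, water_conc = 55600,
                           m = 1L, n = 1L, r = 1L, v = 1L,
                           temperature = 310, area_to_volume = 1000) {
  check_scalar(k_f, "k_f", nonneg = TRUE)
  check_scalar(k_r, "k_r", nonneg = TRUE)
  check_scalar(k_i, "k_i", nonneg = TRUE)
  check_scalar(G0, "G0", nonneg = TRUE)
  check_scalar(CS0, "CS0", nonneg = TRUE)
  if (CS0 > G0) stop_invalid("`CS0` must not exceed `G0`")
  check_scalar(water_conc, "water_conc", positive = TRUE)
  check_scalar(temperature, "temperature", positive = TRUE)
  check_scalar(area_to_volume, "area_to_volume", positive = TRUE)
  structure(list(k_f = k_f, k_r = k_r, k_i = k_i, G0 = G0, CS0 = CS0,
                 water_conc = water_conc,
                 m = as.integer(m), n = as.integer(n), r = as.integer(r),
                 v = as.integer(v), temperature = temperature,
                 area_to_volume = area_to_volume),
            class = "kinetic_params")
}

#' @rdname kinetic_params
#' @export
fig4_kinetic_params <- function() kinetic_params(k_i = 1)

# Total surface site density (mol/m^2) and its volumetric equivalent.
site_total_surface <- function(params) params$G0 + params$CS0
site_total_volumetric <- function(params) {
  (params$G0 + params$CS0) * params$area_to_volume
}

#' Right-hand side of the well-mixed adsorption system
#'
#' State is `c(P, S, PS, PS_irr)` in a consistent volumetric basis (mol/m^3).
#' Default (conservation-corrected) form:
#' \deqn{d[P\cdot S]/dt = k_f [P][S] - k_r [P\cdot S] - k_i [P\cdot S]}
#' \deqn{d[\bar P\cdot\bar S]/dt = k_i [P\cdot S]}
#' \deqn{d[S]/dt = -k_f [P][S] + k_r [P\cdot S]}
#' \deqn{d[P]/dt = -k_f [P][S] + k_r [P\cdot S] + inflow}
#' `literal_printed_equations = TRUE` replaces the desorption terms of the
#' `[S]` and `[P]` equations by `+k_r [S]` and `+k_r [P]` (the form printed in
#' the source kinetics table, which does not conserve sites; retained only for
#' comparison).
#'
#' @param state Named or positional numeric vector `c(P, S, PS, PS_irr)`,
#'   all `>= 0`.
#' @param params A [kinetic_params()].
#' @param inflow Bulk protein source rate, mol/(m^3 s).
#' @param literal_printed_equations Logical; see above.
#' @return Numeric vector of time derivatives, same order as `state`.
#' @export
cstr_rhs <- function(state, params, inflow = 0,
                     literal_printed_equations = FALSE) {
  if (any(state < 0)) stop_invalid("negative concentrations in `state`")
  P <- state[[1]]; S <- state[[2]]; PS <- state[[3]]
  fwd <- params$k_f * P * S
  if (literal_printed_equations) {
    dP  <- -fwd + params$k_r * P + inflow
    dS  <- -fwd + params$k_r * S
  } else {
    dP  <- -fwd + params$k_r * PS + inflow
    dS  <- -fwd + params$k_r * PS
  }
  dPS <- fwd - params$k_r * PS - params$k_i * PS
  dPSi <- params$k_i * PS
  c(P = dP, S = dS, PS = dPS, PS_irr = dPSi)
}

#' Pulse injection schedule
#'
#' Each pulse `(start, duration, concentration)` delivers its stated bulk
#' concentration over its duration, i.e. acts as a source of
#' `concentration/duration` mol/(m^3 s) while active. Pulses must be sorted
#' and non-overlapping.
#'
#' @param start Pulse start times (s).
#' @param duration Pulse durations (s), `> 0`.
#' @param concentration Delivered concentrations (mol/m^3).
#' @export
injection_schedule <- function(start, duration, concentration) {
  n <- length(start)
  if (length(duration) == 1L) duration <- rep(duration, n)
  if (length(concentration) == 1L) concentration <- rep(concentration, n)
  if (length(duration) != n || length(concentration) != n) {
    stop_invalid("schedule fields must have equal length")
  }
  if (n > 0) {
    if (any(duration <= 0)) stop_invalid("pulse durations must be > 0")
    if (is.unsorted(start, strictly = TRUE) && n > 1L) {
      stop_invalid("pulses must be sorted by start time")
    }
    if (n > 1L && any(start[-1] < (start + duration)[-n] - 1e-12)) {
      stop_invalid("pulses must not overlap")
    }
  }
  structure(data.frame(start = as.numeric(start),
                       duration = as.numeric(duration),
                       concentration = as.numeric(concentration)),
            class = c("injection_schedule", "data.frame"))
}

#' The packaged pulse-injection protocols
#'
#' Albumin: one 1.0-s pulse at its maximum inlet concentration. Fibrinogen:
#' fifty back-to-back 1.0-s pulses at its maximum inlet concentration.
#'
#' @param protein A [protein_spec()].
#' @export
pulse_protocol <- function(protein) {
  stopifnot(inherits(protein, "protein_spec"))
  cmax <- protein$inlet_max_concentration
  if (identical(protein$name, "fibrinogen")) {
    injection_schedule(start = 0:49, duration = 1.0, concentration = cmax)
  } else {
    injection_schedule(start = 0, duration = 1.0, concentration = cmax)
  }
}

schedule_inflow <- function(schedule, t) {
  if (nrow(schedule) == 0L) return(0)
  hit <- which(t >= schedule$start - 1e-12 &
               t < schedule$start + schedule$duration - 1e-12)
  if (length(hit)) {
    sum(schedule$concentration[hit] / schedule$duration[hit])
  } else 0
}

#' Integrate the well-mixed adsorption system
#'
#' Stiff-safe adaptive integration (lsoda) of [cstr_rhs()] under a pulse
#' [injection_schedule()], piecewise between pulse boundaries so the
#' discontinuous source is handled exactly, with non-negativity projection and
#' output on a fixed grid.
#'
#' @param params A [kinetic_params()].
#' @param schedule An [injection_schedule()] (may be empty).
#' @param t_end End time (s), `>= dt`.
#' @param dt Output step (s), `> 0`; default 0.009.
#' @param init_P Initial bulk protein concentration (mol/m^3).
#' @param hold_bulk If `TRUE`, `[P]` is held constant at `init_P` (open
#'   reservoir), used e.g. to expose the reversible equilibrium.
#' @param literal_printed_equations Passed to [cstr_rhs()].
#' @return Object of class `cstr_trajectory`: data frame with columns
#'   `t_s, P, S, PS, PS_irr, water_released` (volumetric basis, mol/m^3),
#'   with the parameters attached as attributes.
#' @export
integrate_cstr <- function(params, schedule = injection_schedule(numeric(0),
                                                                 numeric(0),
                                                                 numeric(0)),
                           t_end, dt = 0.009, init_P = 0, hold_bulk = FALSE,
                           literal_printed_equations = FALSE) {
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(t_end, "t_end", positive = TRUE)
  if (t_end < dt) stop_invalid("`t_end` must be >= dt")
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "injection_schedule"))

  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end - 1e-12) times <- c(times, t_end)
  # segment boundaries where the source is discontinuous
  brk <- sort(unique(c(0, t_end,
                       schedule$start, schedule$start + schedule$duration)))
  brk <- brk[brk >= 0 & brk <= t_end]

  y <- c(P = init_P, S = site_total_volumetric(params), PS = 0, PS_irr = 0)
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    d <- cstr_rhs(y, params, inflow = parms$inflow,
                  literal_printed_equations = literal_printed_equations)
    if (hold_bulk) d[1] <- 0
    list(d)
  }

  out <- matrix(NA_real_, nrow = length(times), ncol = 4,
                dimnames = list(NULL, names(y)))
  out[1, ] <- y
  for (s in seq_len(length(brk) - 1L)) {
    t0 <- brk[s]; t1 <- brk[s + 1L]
    seg_times <- unique(c(t0, times[times > t0 + 1e-12 & times <= t1 + 1e-12], t1))
    inflow <- schedule_inflow(schedule, (t0 + t1) / 2)
    sol <- deSolve::lsoda(y, seg_times, rhs, parms = list(inflow = inflow),
                          rtol = 1e-9, atol = 1e-14)
    if (attr(sol, "istate")[1] < 0) {
      stop("CSTR integration failed near t = ", signif(sol[nrow(sol), 1], 6), " s")
    }
    y <- pmax(sol[nrow(sol), -1], 0)
    idx <- match(round(sol[, 1], 12), round(times, 12))
    keep <- !is.na(idx)
    out[idx[keep], ] <- pmax(sol[keep, -1, drop = FALSE], 0)
  }

  traj <- data.frame(t_s = times, P = out[, "P"], S = out[, "S"],
                     PS = out[, "PS"], PS_irr = out[, "PS_irr"])
  # stoichiometric water audit (net released per Eq. scheme):
  # (m + r) waters per P.S formed (net) and (n + v) per irreversible complex.
  traj$water_released <- (params$m + params$r) * (traj$PS + traj$PS_irr) +
    (params$n + params$v) * traj$PS_irr
  structure(traj, class = c("cstr_trajectory", "data.frame"),
            params = params, schedule = schedule,
            site_total = site_total_volumetric(params))
}

#' @export
print.cstr_trajectory <- function(x, ...) {
  cat("CSTR adsorption trajectory:", nrow(x), "steps to t =",
      format(x$t_s[nrow(x)]), "s\n")
  cat("  final [P] =", format(signif(x$P[nrow(x)], 4)),
      " [P.S] =", format(signif(x$PS[nrow(x)], 4)),
      " [Pbar.Sbar] =", format(signif(x$PS_irr[nrow(x)], 4)), "mol/m^3\n")
  invisible(x)
}

#' @export
plot.cstr_trajectory <- function(x, ...) {
  graphics::matplot(x$t_s, cbind(x$P, x$S, x$PS, x$PS_irr), type = "l",
                    lty = 1, xlab = "t (s)", ylab = "concentration (mol/m^3)",
                    ...)
  graphics::legend("right", legend = c("[P]", "[S]", "[P.S]", "[Pbar.Sbar]"),
                   col = 1:4, lty = 1, bty = "n")
  invisible(x)
}

#' @rdname integrate_cstr
#' @param x A `cstr_trajectory`.
#' @param path CSV path; the concentration basis is recorded in a header comment.
#' @export
write_cstr_trajectory <- function(x, path) {
  stopifnot(inherits(x, "cstr_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- attr(x, "params")
  writeLines(paste0("# volumetric basis, area_to_volume = ",
                    p$area_to_volume, " 1/m"), con)
  utils::write.csv(data.frame(t_s = x$t_s, P = x$P, S = x$S, PS = x$PS,
                              PS_irr = x$PS_irr),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Core plateau-crossing computation shared by the kinetics and transport
# modules: first time y reaches `fraction` of its end value, with linear
# interpolation between stored steps.
plateau_time <- function(t, y, fraction = 0.99, require_plateau = TRUE) {
  stopifnot(length(t) == length(y), length(t) >= 2)
  n <- length(t)
  y_end <- y[n]
  if (require_plateau) {
    k <- max(2L, n - 4L)
    slope <- (y[n] - y[k]) / (t[n] - t[k])
    scale <- max(abs(y_end), max(abs(y)) * 1e-6)
    if (scale > 0 && abs(slope) / scale >= 1e-4) {
      stop("not saturated: trajectory has not reached a plateau ",
           "(relative end slope ", signif(abs(slope) / scale, 3), " /s)")
    }
  }
  target <- fraction * y_end
  if (y[1] >= target) return(t[1])
  above <- which(y >= target)
  if (!length(above)) return(t[n])
  i <- above[1]
  # linear interpolation on [i-1, i]
  t[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Saturation time of a species trajectory
#'
#' First time a species reaches `fraction` (default 0.99) of its final plateau
#' value, with linear interpolation between stored steps. Errors with
#' "not saturated" if the trajectory's relative end slope exceeds 1e-4 /s.
#'
#' @param trajectory A `cstr_trajectory` (or any data frame with a `t_s`
#'   column and the species column).
#' @param species Column name, e.g. `"PS_irr"`.
#' @param fraction Plateau fraction in `(0, 1]`.
#' @param require_plateau If `FALSE`, the end-of-run value is used as the
#'   plateau without the slope check.
#' @return Time (s).
#' @examples
#' t <- seq(0, 5, by = 0.01)
#' tr <- data.frame(t_s = t, c = 1 - exp(-t / 0.2))
#' saturation_time(tr, "c")  # ~ -0.2 * log(0.01) = 0.921 s
#' @export
saturation_time <- function(trajectory, species, fraction = 0.99,
                            require_plateau = TRUE) {
  if (!species %in% names(trajectory)) {
    stop_invalid("no column `", species, "` in trajectory")
  }
  if (fraction <= 0 || fraction > 1) stop_invalid("`fraction` must be in (0, 1]")
  plateau_time(trajectory$t_s, trajectory[[species]], fraction,
               require_plateau = require_plateau)
}

#' Protein footprint and maximum monolayer density
#'
#' Spheres occupy their projected disc `pi d^2 / 4`; cylinders adsorb side-on
#' and occupy `length x equivalent diameter`, with the equivalent diameter of
#' the circular cross-section `2 sqrt(A/pi)`. Maximum monolayer density is one
#' molecule per footprint: `1 / (area N_A)`.
#'
#' @param protein A [protein_spec()].
#' @return List with `area_m2` (m^2 per molecule) and `max_density_mol_m2`.
#' @export
protein_footprint <- function(protein) {
  stopifnot(inherits(protein, "protein_spec"))
  area <- if (protein$shape == "sphere") {
    pi * protein$diameter^2 / 4
  } else {
    d_eq <- 2 * sqrt(protein$cross_section / pi)
    protein$length * d_eq
  }
  avogadro <- 6.02214076e23
  list(area_m2 = area, max_density_mol_m2 = 1 / (area * avogadro))
}
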