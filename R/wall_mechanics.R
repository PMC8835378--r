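# Reduced-order elastic response of the graft wall: thick-wall (Lame) stresses
# under internal gauge pressure, plane-strain radial displacement with fixed
# ends, and quasi-static pressure-radius coupling over a pulse cycle. The pulse
# timescale (~1 s) is far slower than the wall's elastic timescale, so wall
# inertia is neglected.

#' Graft wall material
#'
#' Defaults are the decellularized porcine carotid TEVG: E = 1.34 MPa from
#' uniaxial tensile tests, Poisson ratio 0.49, with the ultimate tensile
#' strength of native porcine arteries (0.49 MPa) as the reference constant
#' for safety factors.
#'
#' @param young_modulus E (Pa), `> 0`.
#' @param poisson_ratio nu, in `(0, 0.5)` (0.5 exactly is singular in plane strain).
#' @param ultimate_tensile_strength Reference UTS (Pa).
#' @export
wall_material <- function(young_modulus = 1.34e6, poisson_ratio = 0.49,
                          ultimate_tensile_strength = 0.49e6) {
  check_scalar(young_modulus, "young_modulus", positive = TRUE)
  check_scalar(poisson_ratio, "poisson_ratio")
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5) {
    stop_invalid("`poisson_ratio` must lie strictly in (0, 0.5); ",
                 "the incompressible limit 0.5 is singular in plane strain")
  }
  check_scalar(ultimate_tensile_strength, "ultimate_tensile_strength",
               positive = TRUE)
  structure(list(young_modulus = young_modulus, poisson_ratio = poisson_ratio,
                 ultimate_tensile_strength = ultimate_tensile_strength),
            class = "wall_material")
}

#' Lame hoop stress at the inner surface of a thick-walled tube
#'
#' `sigma_theta(r_i) = P (r_i^2 + r_o^2) / (r_o^2 - r_i^2)` for internal gauge
#' pressure `P` and zero external pressure, `r_o = r_i + thickness`.
#'
#' @param pressure Internal gauge pressure (Pa), `>= 0` (vectorized).
#' @param geom A [graft_geometry()].
#' @return Hoop stress (Pa), same length as `pressure`.
#' @export
lame_hoop_stress <- function(pressure, geom) {
  if (any(pressure < 0)) stop_invalid("`pressure` must be >= 0 (gauge)")
  ri <- geom$inner_radius
  ro <- ri + geom$wall_thickness
  pressure * (ri^2 + ro^2) / (ro^2 - ri^2)
}

#' Radial displacement of the inner surface (plane strain, thick wall)
#'
#' Closed-form Lame solution with fixed ends (plane strain):
#' `u(r_i) = (1+nu) P r_i / (E (r_o^2 - r_i^2)) * ((1-2 nu) r_i^2 + r_o^2)`.
#' Linear in `P`; hoop strain is `u(r_i)/r_i`.
#'
#' @inheritParams lame_hoop_stress
#' @param material A [wall_material()].
#' @return Displacement (m), same length as `pressure`.
#' @export
radial_displacement <- function(pressure, geom, material) {
  if (any(pressure < 0)) stop_invalid("`pressure` must be >= 0 (gauge)")
  ri <- geom$inner_radius
  ro <- ri + geom$wall_thickness
  nu <- material$poisson_ratio
  E <- material$young_modulus
  (1 + nu) * pressure * ri / (E * (ro^2 - ri^2)) *
    ((1 - 2 * nu) * ri^2 + ro^2)
}

#' Quasi-static wall response to a pulsatile pressure waveform
#'
#' Evaluates the thick-wall elastic response pointwise in time ("quasi-static"
#' coupling): `R(t) = r_i + u(P(t))`, hoop stress and strain series, and the
#' safety factor `UTS / sigma_theta(t)`.
#'
#' @param pressure_series A [harmonic_series()] of the luminal pressure (Pa).
#' @param geom A [graft_geometry()].
#' @param material A [wall_material()].
#' @param t Time grid (s).
#' @return Object of class `wall_response`: data frame with columns
#'   `t_s, pressure_pa, R_m, sigma_theta_pa, strain, safety_factor`.
#' @export
couple_quasi_static <- function(pressure_series, geom, material,
                                t = seq(0, 1.5, by = 0.003)) {
  stopifnot(inherits(pressure_series, "harmonic_series"))
  p <- evaluate_series(pressure_series, t)
  if (any(p < 0)) stop_invalid("pressure waveform goes negative (gauge)")
  u <- radial_displacement(p, geom, material)
  sig <- lame_hoop_stress(p, geom)
  out <- data.frame(
    t_s = t, pressure_pa = p,
    R_m = geom$inner_radius + u,
    sigma_theta_pa = sig,
    strain = u / geom$inner_radius,
    safety_factor = ifelse(sig > 0, material$ultimate_tensile_strength / sig, Inf)
  )
  structure(out, class = c("wall_response", "data.frame"),
            material = material, geometry = geom)
}

#' @export
print.wall_response <- function(x, ...) {
  cat("Quasi-static wall response over", nrow(x), "time steps\n")
  cat("  max hoop stress:", format(signif(max(x$sigma_theta_pa), 4)),
      "Pa; max strain:", format(signif(max(x$strain) * 100, 3)),
      "%; min safety factor:", format(signif(min(x$safety_factor), 3)), "\n")
  invisible(x)
}

#' @export
plot.wall_response <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(x$t_s, x$R_m * 1e3, type = "l", xlab = "t (s)",
                 ylab = "inner radius (mm)", ...)
  graphics::plot(x$t_s, x$sigma_theta_pa / 1e3, type = "l", xlab = "t (s)",
                 ylab = "hoop stress (kPa)", ...)
  invisible(x)
}

#' @rdname couple_quasi_static
#' @param x A `wall_response`.
#' @param path CSV path.
#' @export
write_wall_response <- function(x, path) {
  stopifnot(inherits(x, "wall_response"))
  d <- data.frame(t_s = x$t_s, R_m = x$R_m, sigma_theta_pa = x$sigma_theta_pa,
                  strain = x$strain, safety_factor = x$safety_factor)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
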