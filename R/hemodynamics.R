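# Pulsatile laminar flow in a cylindrical lumen. The nonlinear convective term
# is dropped (fully developed flow), so each pressure-gradient harmonic has the
# exact analytic Womersley solution and the mean gradient drives a Poiseuille
# parabola; the total field is their superposition.

#' Fluid properties
#' @param density Mass density (kg/m^3), `> 0`.
#' @param viscosity Dynamic viscosity (Pa s), `> 0`.
#' @export
fluid_properties <- function(density = 1000, viscosity = 1e-3) {
  check_scalar(density, "density", positive = TRUE)
  check_scalar(viscosity, "viscosity", positive = TRUE)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Graft geometry
#'
#' Defaults are the decellularized porcine carotid TEVG: 4.00 mm internal
#' diameter, 0.90 mm wall, 60.00 mm length.
#'
#' @param inner_radius Lumen radius (m), `> 0`.
#' @param wall_thickness Wall thickness (m), `> 0` and `< 2*inner_radius`.
#' @param length Axial length (m), `> 0`.
#' @export
graft_geometry <- function(inner_radius = 2e-3, wall_thickness = 0.9e-3,
                           length = 60e-3) {
  check_scalar(inner_radius, "inner_radius", positive = TRUE)
  check_scalar(wall_thickness, "wall_thickness", positive = TRUE)
  check_scalar(length, "length", positive = TRUE)
  if (wall_thickness >= 2 * inner_radius) {
    stop_invalid("`wall_thickness` must be < 2 * inner_radius")
  }
  structure(list(inner_radius = inner_radius, wall_thickness = wall_thickness,
                 length = length),
            class = "graft_geometry")
}

#' Flow diagnostics: Reynolds number and Hagen-Poiseuille pressure drop
#'
#' `reynolds_number` returns `rho * vbar * D / mu` with
#' `vbar = Q / (pi R^2)` and `D = 2R`; `hagen_poiseuille_dp` returns
#' `8 mu L Q / (pi R^4)`.
#'
#' @param fluid A [fluid_properties()].
#' @param geom A [graft_geometry()].
#' @param flow_rate Volumetric flow rate Q (m^3/s), `>= 0`.
#' @return Dimensionless Reynolds number / pressure drop (Pa).
#' @examples
#' reynolds_number(fluid_properties(), graft_geometry(), 3.33e-7)  # ~106
#' @export
reynolds_number <- function(fluid, geom, flow_rate) {
  check_scalar(flow_rate, "flow_rate", nonneg = TRUE)
  R <- geom$inner_radius
  vbar <- flow_rate / (pi * R^2)
  fluid$density * vbar * (2 * R) / fluid$viscosity
}

#' @rdname reynolds_number
#' @export
hagen_poiseuille_dp <- function(fluid, geom, flow_rate) {
  check_scalar(flow_rate, "flow_rate", nonneg = TRUE)
  8 * fluid$viscosity * geom$length * flow_rate / (pi * geom$inner_radius^4)
}

#' Womersley number
#'
#' `alpha = R * sqrt(omega * rho / mu)` for the fundamental (or a given
#' harmonic of) angular frequency.
#'
#' @inheritParams reynolds_number
#' @param omega Angular frequency (rad/s).
#' @export
womersley_number <- function(fluid, geom, omega) {
  check_scalar(omega, "omega", positive = TRUE)
  geom$inner_radius * sqrt(omega * fluid$density / fluid$viscosity)
}

#' Axial pressure gradient series from an inlet/outlet pressure pair
#'
#' Returns `-dP/dz` as a harmonic series: `(P_in - P_out) / L` coefficient by
#' coefficient. The two series must share `omega` and harmonic count.
#'
#' @param inlet,outlet [harmonic_series()] objects (Pa).
#' @param length Distance between the two stations (m).
#' @export
gradient_from_pressures <- function(inlet, outlet, length) {
  stopifnot(inherits(inlet, "harmonic_series"),
            inherits(outlet, "harmonic_series"))
  check_scalar(length, "length", positive = TRUE)
  if (length(inlet$An) != length(outlet$An) ||
      abs(inlet$omega - outlet$omega) > 1e-9 * inlet$omega) {
    stop_invalid("inlet and outlet series must share omega and harmonic count")
  }
  harmonic_series(A0 = (inlet$A0 - outlet$A0) / length,
                  An = (inlet$An - outlet$An) / length,
                  Bn = (inlet$Bn - outlet$Bn) / length,
                  omega = inlet$omega)
}

# Radial grid with clustering near the wall: r_j = R sin(theta_j),
# theta uniform on [0, pi/2]; includes the axis and the wall.
radial_grid <- function(R, n = 64L) {
  R * sin(seq(0, pi / 2, length.out = n))
}

# Complex amplitude profile of one Womersley harmonic, per unit gradient
# amplitude: uhat(r) = (1/(i rho w_n)) [1 - J0(i^{3/2} a r/R)/J0(i^{3/2} a)].
womersley_profile <- function(rhat, alpha, rho_wn) {
  lam <- complex(modulus = 1, argument = 3 * pi / 4) * alpha  # i^{3/2} alpha
  (1 / (1i * rho_wn)) *
    (1 - besselJ_complex(lam * rhat, 0L) /
       as.vector(besselJ_complex(lam, 0L)))
}

# Complex flow-rate factor per unit gradient amplitude:
# Qhat = (pi R^2 /(i rho w_n)) [1 - 2 J1(L)/(L J0(L))], L = i^{3/2} alpha.
womersley_flow_factor <- function(R, alpha, rho_wn) {
  lam <- complex(modulus = 1, argument = 3 * pi / 4) * alpha
  (pi * R^2 / (1i * rho_wn)) *
    (1 - 2 * besselJ_complex(lam, 1L) / (lam * besselJ_complex(lam, 0L)))
}

#' Pulsatile axial velocity field from a pressure-gradient series
#'
#' Solves linearized axisymmetric momentum balance for a rigid cylindrical
#' lumen driven by `-dP/dz = A0 + sum_n An cos(n w t) + Bn sin(n w t)`:
#' the mean term drives the steady Poiseuille parabola and each harmonic its
#' analytic Womersley profile. The field is fully developed (independent of z).
#'
#' @param gradient_series A [harmonic_series()] giving `-dP/dz` in Pa/m.
#' @param fluid A [fluid_properties()].
#' @param geom A [graft_geometry()].
#' @param r Radial grid (m), from 0 to the lumen radius; default 64 points
#'   clustered near the wall.
#' @param t Time grid (s); default `seq(0, 1.5, by = 0.003)`.
#' @param z Axial grid (m); metadata only (the field is z-invariant).
#' @return Object of class `flow_field`: list with `r`, `t`, `z`, lumen radius
#'   `R`, and velocity matrix `u` of dim `length(r) x length(t)` (m/s).
#' @export
womersley_field <- function(gradient_series, fluid, geom,
                            r = NULL, t = seq(0, 1.5, by = 0.003),
                            z = c(0, geom$length)) {
  stopifnot(inherits(gradient_series, "harmonic_series"))
  R <- geom$inner_radius
  if (R <= 0) stop_invalid("zero or negative radius")
  if (is.null(r)) r <- radial_grid(R)
  if (max(r) > R * (1 + 1e-12) || min(r) < 0) {
    stop_invalid("radial grid must lie in [0, R]")
  }
  mu <- fluid$viscosity
  rho <- fluid$density
  rhat <- r / R

  # steady Poiseuille component
  u <- outer((gradient_series$A0 / (4 * mu)) * (R^2 - r^2), rep(1, length(t)))

  N <- length(gradient_series$An)
  if (N > 0) {
    for (n in seq_len(N)) {
      wn <- n * gradient_series$omega
      alpha <- R * sqrt(wn * rho / mu)
      Cn <- complex(real = gradient_series$An[n],
                    imaginary = -gradient_series$Bn[n])
      prof <- womersley_profile(rhat, alpha, rho * wn)   # per unit gradient
      u <- u + Re(outer(prof * Cn, exp(1i * wn * t)))
    }
  }
  structure(list(r = r, t = t, z = z, R = R, u = u,
                 omega = gradient_series$omega,
                 gradient_series = gradient_series),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("Axisymmetric flow field:", length(x$r), "radial x", length(x$t),
      "time samples; R =", format(x$R), "m\n")
  cat("  peak |u_z| =", format(signif(max(abs(x$u)), 4)), "m/s; mean flow rate =",
      format(signif(mean(flow_rate(x)), 4)), "m^3/s\n")
  invisible(x)
}

#' Cross-section volumetric flow rate of a flow field
#'
#' `Q(t) = 2 pi \int_0^R u_z(r,t) r dr` by trapezoid quadrature on the field's
#' radial grid.
#'
#' @param field A `flow_field`.
#' @return Numeric vector over the field's time grid (m^3/s).
#' @export
flow_rate <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  apply(field$u, 2, function(ur) 2 * pi * trapz(field$r, ur * field$r))
}

#' Wall shear stress of a flow field
#'
#' `tau_w(t) = mu |du_z/dr|` at `r = R`, by a one-sided second-order finite
#' difference on the last three (possibly non-uniform) radial nodes. For a
#' steady Poiseuille field this equals `4 mu Q / (pi R^3)`.
#'
#' @param field A `flow_field` with at least 3 radial points.
#' @param fluid A [fluid_properties()].
#' @return Numeric vector `tau_w(t)` (Pa). The field is z-invariant, so one
#'   axial station represents all.
#' @export
wall_shear_stress <- function(field, fluid) {
  stopifnot(inherits(field, "flow_field"))
  r <- field$r
  n <- length(r)
  if (n < 3L) stop_invalid("radial grid too coarse for wall shear stress (need >= 3 points)")
  # second-order one-sided derivative at r[n] on non-uniform nodes
  h1 <- r[n] - r[n - 1]
  h2 <- r[n - 1] - r[n - 2]
  w_n  <- (2 * h1 + h2) / (h1 * (h1 + h2))
  w_n1 <- -(h1 + h2) / (h1 * h2)
  w_n2 <- h1 / (h2 * (h1 + h2))
  dudr <- w_n * field$u[n, ] + w_n1 * field$u[n - 1, ] + w_n2 * field$u[n - 2, ]
  fluid$viscosity * abs(dudr)
}

#' Export a flow field as a long-format data frame / CSV
#'
#' Columns `z_m, r_m, t_s, u_z_mps`; the field is fully developed so values
#' repeat over `z`.
#'
#' @param field A `flow_field`.
#' @param path Optional CSV path; if given the table is also written there.
#' @export
flow_field_table <- function(field, path = NULL) {
  stopifnot(inherits(field, "flow_field"))
  d <- expand.grid(r_m = field$r, t_s = field$t, z_m = field$z,
                   KEEP.OUT.ATTRS = FALSE)
  d$u_z_mps <- rep(as.vector(field$u), times = length(field$z))
  d <- d[, c("z_m", "r_m", "t_s", "u_z_mps")]
  if (!is.null(path)) utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  d
}
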