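water <- fluid_properties(density = 1000, viscosity = 1e-3)
geom <- graft_geometry()   # 4.00 mm ID, 0.90 mm wall, 60.00 mm length
Q_exp <- 3.33e-7           # experimental pump flow rate, m^3/s

test_that("Reynolds number and Hagen-Poiseuille drop match closed forms", {
  expect_equal(reynolds_number(water, geom, Q_exp), 106.09, tolerance = 0.01)
  expect_equal(reynolds_number(water, geom, 0), 0)
  expect_equal(reynolds_number(water, geom, 2 * Q_exp),
               2 * reynolds_number(water, geom, Q_exp))

  expect_equal(hagen_poiseuille_dp(water, geom, Q_exp), 3.12, tolerance = 0.05)
  expect_equal(hagen_poiseuille_dp(water, geom, 0), 0)
  thick <- fluid_properties(viscosity = 2e-3)
  expect_equal(hagen_poiseuille_dp(thick, geom, Q_exp),
               2 * hagen_poiseuille_dp(water, geom, Q_exp))
})

test_that("Womersley number matches its definition", {
  # alpha = R sqrt(w rho / mu), direct evaluation
  expect_equal(womersley_number(water, geom, 0.8184),
               2e-3 * sqrt(0.8184 * 1000 / 1e-3), tolerance = 1e-12)
  expect_equal(womersley_number(water, geom, 0.8184), 1.81, tolerance = 0.005)
})

test_that("Womersley field reduces to Poiseuille in the omega -> 0 limit", {
  g0 <- 52.0
  hs <- harmonic_series(A0 = 0, An = g0, Bn = 0, omega = 1e-6)
  fld <- womersley_field(hs, water, geom, t = 0)
  # at t = 0 the quasi-steady gradient is g0; compare with the parabola
  u_exact <- g0 / (4 * water$viscosity) * (geom$inner_radius^2 - fld$r^2)
  expect_lt(max(abs(fld$u[, 1] - u_exact)) / max(u_exact), 1e-3)
})

test_that("no-slip, axis regularity, and flow-rate closed form hold", {
  hs <- harmonic_series(A0 = 52, An = c(120, 60), Bn = c(-40, 25),
                        omega = 2 * pi / 1.5)
  fld <- womersley_field(hs, water, geom,
                         r = tevgsim:::radial_grid(geom$inner_radius, 128))
  # no-slip at the wall
  expect_lt(max(abs(fld$u[length(fld$r), ])), 1e-12 * max(abs(fld$u)))
  # axis symmetry: second-order one-sided difference of u_z at r = 0
  # (exact for the even-in-r profile up to its vanishing odd derivatives)
  h1 <- fld$r[2] - fld$r[1]; h2 <- fld$r[3] - fld$r[2]
  w1 <- -(2 * h1 + h2) / (h1 * (h1 + h2))
  w2 <- (h1 + h2) / (h1 * h2)
  w3 <- -h1 / (h2 * (h1 + h2))
  dudr0 <- abs(w1 * fld$u[1, ] + w2 * fld$u[2, ] + w3 * fld$u[3, ])
  dr <- h1
  expect_lt(max(dudr0), 1e-6 * max(abs(fld$u)) / dr)

  # quadrature flow rate vs analytic per-harmonic formula (oracle):
  # Q(t) = pi R^4 g0 / (8 mu) + sum_n Re[Qhat_n exp(i n w t)]
  R <- geom$inner_radius
  Qt <- pi * R^4 * hs$A0 / (8 * water$viscosity)
  Q_oracle <- rep(Qt, length(fld$t))
  for (n in 1:2) {
    wn <- n * hs$omega
    alpha <- R * sqrt(wn * water$density / water$viscosity)
    lam <- complex(modulus = 1, argument = 3 * pi / 4) * alpha
    J0 <- tevgsim:::besselJ_complex(lam, 0L)
    J1 <- tevgsim:::besselJ_complex(lam, 1L)
    Qhat <- (pi * R^2 / (1i * water$density * wn)) * (1 - 2 * J1 / (lam * J0))
    Cn <- complex(real = hs$An[n], imaginary = -hs$Bn[n])
    Q_oracle <- Q_oracle + Re(Qhat * Cn * exp(1i * wn * fld$t))
  }
  expect_lt(max(abs(flow_rate(fld) - Q_oracle)) / max(abs(Q_oracle)), 5e-3)
})

test_that("superposition of gradient series gives superposed fields", {
  w <- 2 * pi / 1.5
  h1 <- harmonic_series(30, An = 100, Bn = 0, omega = w)
  h2 <- harmonic_series(22, An = -40, Bn = 55, omega = w)
  hsum <- harmonic_series(52, An = 60, Bn = 55, omega = w)
  tgrid <- seq(0, 1.5, by = 0.05)
  f1 <- womersley_field(h1, water, geom, t = tgrid)
  f2 <- womersley_field(h2, water, geom, t = tgrid)
  fs <- womersley_field(hsum, water, geom, t = tgrid)
  expect_equal(fs$u, f1$u + f2$u, tolerance = 1e-10)
})

test_that("wall shear stress recovers the Poiseuille closed form", {
  # steady field at the experimental flow rate
  g0 <- 8 * water$viscosity * Q_exp / (pi * geom$inner_radius^4)
  hs <- harmonic_series(A0 = g0, omega = 2 * pi / 1.5)
  tau_exact <- 4 * water$viscosity * Q_exp / (pi * geom$inner_radius^3)
  expect_equal(tau_exact, 0.0530, tolerance = 0.001)

  fld <- womersley_field(hs, water, geom, t = 0)
  expect_equal(wall_shear_stress(fld, water)[1], tau_exact, tolerance = 2e-3)

  # grid refinement: 128 radial points within 0.2%
  fld128 <- womersley_field(hs, water, geom,
                            r = tevgsim:::radial_grid(geom$inner_radius, 128),
                            t = 0)
  expect_equal(wall_shear_stress(fld128, water)[1], tau_exact,
               tolerance = 2e-3)

  # zero field -> zero stress; steady WSS positive for positive gradient
  f0 <- womersley_field(harmonic_series(0, omega = 1), water, geom, t = 0)
  expect_equal(wall_shear_stress(f0, water)[1], 0)
  expect_true(all(wall_shear_stress(fld, water) > 0))

  coarse <- womersley_field(hs, water, geom, r = c(0, geom$inner_radius),
                            t = 0)
  expect_error(wall_shear_stress(coarse, water), "too coarse")
})

test_that("gradient series from an inlet/outlet pair divides by length", {
  w <- 2 * pi / 1.5
  hin <- harmonic_series(110, An = 10, Bn = 2, omega = w)
  hout <- harmonic_series(50, An = 4, Bn = -1, omega = w)
  g <- gradient_from_pressures(hin, hout, 0.06)
  expect_equal(g$A0, 1000)
  expect_equal(g$An, 100)
  expect_equal(g$Bn, 50)
})
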