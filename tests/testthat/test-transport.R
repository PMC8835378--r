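test_that("Stokes-Einstein diffusivity follows the formula and protein sizes", {
  water <- fluid_properties()
  D_alb <- stokes_einstein_diffusivity(albumin_spec(), water, 310)
  kB <- 1.380649e-23
  expect_equal(D_alb, kB * 310 / (6 * pi * 1e-3 * 4.25e-9))
  expect_equal(D_alb, 5.3e-11, tolerance = 0.01)
  # doubling viscosity halves D
  thick <- fluid_properties(viscosity = 2e-3)
  expect_equal(stokes_einstein_diffusivity(albumin_spec(), thick, 310),
               D_alb / 2)
  # fibrinogen has the larger equivalent radius, hence smaller D
  expect_lt(stokes_einstein_diffusivity(fibrinogen_spec(), water, 310), D_alb)
})

test_that("velocity interpolants: plug mode, NN identity, flow-rate fidelity", {
  geom <- graft_geometry()
  v <- build_velocity(0.047, geom)
  expect_identical(v$query(c(1e-4, 1e-3, 1.9e-3), 0.7), rep(0.047, 3))

  fld <- womersley_field(
    scenario_gradient_series(fluid_properties(), geom), fluid_properties(),
    geom, t = seq(0, 1.5, by = 0.003))
  vi <- build_velocity(fld, geom)
  # querying exactly at a stored sample returns it bit-exactly
  expect_identical(vi$query(vi$r_samples[7], vi$t_samples[31]), vi$u[7, 31])
  expect_error(vi$query(1e-3, 2.0), "outside")

  # NN-resampled profile preserves instantaneous flow rate within 5%
  R <- geom$inner_radius
  edges <- seq(0, R, length.out = 23)
  ring_w <- (edges[-1]^2 - edges[-23]^2) / 2      # \int r dr per NN cell
  Q_peak <- max(abs(flow_rate(fld)))
  for (k in c(1, 60, 120)) {
    kk <- which.min(abs(fld$t - vi$t_samples[k]))
    Q_src <- 2 * pi * tevgsim:::trapz(fld$r, fld$u[, kk] * fld$r)
    Q_nn <- 2 * pi * sum(vi$u[, k] * ring_w)
    expect_lt(abs(Q_nn - Q_src), 0.05 * Q_peak)
  }
})

test_that("zero inlet gives identically zero fields; CFL violations are caught", {
  geom <- graft_geometry(length = 5e-3)
  sc <- transport_scenario(geom, fluid_properties(), fibrinogen_spec(),
                           kinetic_params(), velocity = 0.047,
                           inlet_concentration = 0, nz = 10, nr = 6,
                           dt = 5e-4, t_end = 0.05)
  res <- simulate_transport(sc)
  expect_equal(max(abs(res$C)), 0)
  expect_equal(max(abs(res$gamma_PS)), 0)

  expect_error(
    transport_scenario(geom, fluid_properties(), fibrinogen_spec(),
                       kinetic_params(), velocity = 2.0, nz = 10, nr = 6,
                       dt = 5e-4, t_end = 0.05),
    "CFL")
})

test_that("well-mixed zero-flow transport converges to the CSTR oracle", {
  # closed box, uniform initial fibrinogen, Table-parameter kinetics.
  # At D = 1e-6 the adsorption Biot number k_f Gamma_tot R/(2D) ~ 0.36 keeps a
  # few-percent wall boundary layer; the bulk already matches to <2% there and
  # both trajectories converge to the CSTR limit as D grows.
  oracle <- cached_cstr_oracle()
  res6 <- cached_wellmixed(1e-6)
  n <- min(nrow(oracle), length(res6$t_s))

  mb6 <- mean_bulk(res6)[1:n]
  expect_lt(max(abs(mb6 - oracle$P[1:n])) / max(oracle$P), 0.02)

  surf_err <- function(res) {
    g <- colMeans(res$gamma_PS)[1:n] * kinetic_params()$area_to_volume
    max(abs(g - oracle$PS[1:n])) / max(oracle$PS)
  }
  e6 <- surf_err(res6)
  e5 <- surf_err(cached_wellmixed(5e-6))
  expect_lt(e5, e6)          # monotone approach to the well-mixed limit
  expect_lt(e5, 0.02)        # within 2% once genuinely well mixed
  expect_lt(max(abs(mean_bulk(cached_wellmixed(5e-6))[1:n] - oracle$P[1:n])) /
              max(oracle$P), 0.02)
})

test_that("transport invariants: bounds, monotonicity, conservation", {
  res <- cached_run("fibrinogen_vxt")$transport
  cmax <- fibrinogen_spec()$inlet_max_concentration
  # bulk concentration never exceeds the inlet maximum
  expect_lte(max(res$C), cmax * (1 + 1e-9))
  expect_gte(min(res$C), 0)
  # irreversible complex non-decreasing at every axial station
  mono <- apply(res$gamma_irr, 1, function(g) !is.unsorted(g))
  expect_true(all(mono))
  # site conservation on the wall at every frame
  kin <- res$scenario$kinetics
  stot <- kin$G0 + kin$CS0
  gS <- stot - res$gamma_PS - res$gamma_irr
  expect_lt(max(abs(gS + res$gamma_PS + res$gamma_irr - stot)) / stot, 1e-9)
  expect_gte(min(gS), 0)
  # species mass balance closes within 0.5%
  expect_lt(abs(res$mass_balance$relative_error), 0.005)
})

test_that("surface_stats interpolates and orders max >= mean", {
  res <- cached_run("fibrinogen_vxt")$transport
  s <- surface_stats(res, 0.3)
  expect_true(all(s$max >= s$mean - 1e-15))
  expect_error(surface_stats(res, 99), "outside")
  # frame-aligned query equals the stored frame
  k <- 21
  s2 <- surface_stats(res, res$t_s[k])
  nr <- dim(res$C)[1]
  expect_equal(s2$max[s2$quantity == "near_wall_bulk"], max(res$C[nr, , k]))
})

test_that("bulk summary statistics are grid-converged within 5%", {
  # Peak and volume-mean bulk concentration converge under refinement. (The
  # wall-ring observable is anchored to the wall-adjacent cell and carries the
  # sub-grid adsorption boundary layer, so it is excluded by design; see the
  # methods vignette.)
  base <- preset_scenario("fibrinogen_vxt")
  run_short <- function(nz, nr) {
    sc <- base
    sc$transport$nz <- nz; sc$transport$nr <- nr
    sc$transport$t_end_s <- 0.6
    res <- run_pipeline(sc)$transport
    k <- length(res$t_s)
    c(max = max(res$C[, , k]), mean = mean_bulk(res)[k])
  }
  m1 <- run_short(120, 24)
  m2 <- run_short(240, 48)
  expect_lt(abs(m2[["max"]] - m1[["max"]]) / m1[["max"]], 0.05)
  expect_lt(abs(m2[["mean"]] - m1[["mean"]]) / m1[["mean"]], 0.05)
})
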