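# Axisymmetric advection-diffusion transport of bulk protein with a reactive
# wall boundary: finite volumes on a cell-centred (r, z) grid, first-order
# upwind advection (explicit), central diffusion (implicit, one sparse
# Cholesky factorization reused every step), and the Langmuir surface ODEs
# integrated in lockstep by operator splitting. The wall carries a uniformly
# reactive continuum of sites of total density G0 + CS0.

#' Stokes-Einstein diffusivity of a protein
#'
#' `D = kB T / (6 pi mu r_eq)` with `r_eq = d/2` for spheres and the
#' volume-equivalent sphere radius for cylinders.
#'
#' @param protein A [protein_spec()].
#' @param fluid A [fluid_properties()].
#' @param temperature K.
#' @return Diffusivity (m^2/s).
#' @export
stokes_einstein_diffusivity <- function(protein, fluid, temperature = 310) {
  check_scalar(temperature, "temperature", positive = TRUE)
  r_eq <- if (protein$shape == "sphere") {
    protein$diameter / 2
  } else {
    vol <- protein$cross_section * protein$length
    (3 * vol / (4 * pi))^(1 / 3)
  }
  kB <- 1.380649e-23
  kB * temperature / (6 * pi * fluid$viscosity * r_eq)
}

#' Sampled space-time velocity interpolant
#'
#' Builds the advecting velocity `v(r, t)` for the transport model, either a
#' constant plug value everywhere or a nearest-neighbour interpolant of a
#' [womersley_field()] sampled at `n_radial` radial points (cell-centred on
#' `[0, R]`, so the degenerate no-slip node itself is not a sample) and a
#' fixed time step. Queries snap to the nearest stored sample in both `r` and
#' `t`; a query exactly at a sample returns the stored value bit-exactly.
#'
#' @param source Either a single number (m/s, constant plug mode) or a
#'   `flow_field`.
#' @param geom A [graft_geometry()].
#' @param t_end Latest time that will be queried (s).
#' @param n_radial Number of radial samples (default 22).
#' @param dt_sample Time sampling step (s, default 0.009).
#' @return Object of class `velocity_interpolant` with a `$query(r, t)` method
#'   returning velocities at radial positions `r` (vector) and scalar time `t`.
#' @export
build_velocity <- function(source, geom, t_end = 1.5, n_radial = 22L,
                           dt_sample = 0.009) {
  R <- geom$inner_radius
  t_samples <- seq(0, t_end, by = dt_sample)
  if (is.numeric(source) && length(source) == 1L) {
    val <- as.numeric(source)
    obj <- list(mode = "constant", value = val, R = R,
                t_range = c(0, Inf), u_max = abs(val),
                query = function(r, t) rep(val, length(r)))
    return(structure(obj, class = "velocity_interpolant"))
  }
  stopifnot(inherits(source, "flow_field"))
  if (max(source$t) < t_end - 1e-9) {
    stop_invalid("flow field covers t <= ", signif(max(source$t), 6),
                 " s but t_end = ", t_end, " s was requested")
  }
  r_samples <- (seq_len(n_radial) - 0.5) * R / n_radial
  u <- matrix(0, n_radial, length(t_samples))
  for (k in seq_along(t_samples)) {
    kk <- which.min(abs(source$t - t_samples[k]))
    u[, k] <- stats::approx(source$r, source$u[, kk], xout = r_samples,
                            rule = 2)$y
  }
  dr_s <- R / n_radial
  query <- function(r, t) {
    if (t < 0 - 1e-12 || t > t_end + 1e-12) {
      stop_invalid("time ", t, " s outside interpolant range [0, ", t_end, "]")
    }
    i <- pmin(pmax(round(r / dr_s + 0.5), 1L), n_radial)
    k <- pmin(pmax(round(t / dt_sample) + 1L, 1L), length(t_samples))
    u[cbind(i, rep(k, length(i)))]
  }
  structure(list(mode = "field", r_samples = r_samples, t_samples = t_samples,
                 u = u, R = R, t_range = c(0, t_end), u_max = max(abs(u)),
                 query = query),
            class = "velocity_interpolant")
}

#' Transport-adsorption scenario definition
#'
#' @param geometry A [graft_geometry()].
#' @param fluid A [fluid_properties()].
#' @param protein A [protein_spec()].
#' @param kinetics A [kinetic_params()].
#' @param velocity A [build_velocity()] interpolant, or a single number
#'   (constant plug velocity, m/s).
#' @param inlet_concentration Scalar (sustained inlet concentration, mol/m^3)
#'   or a function of time; default the protein's maximum inlet concentration,
#'   sustained.
#' @param diffusivity `"auto"` (Stokes-Einstein at the kinetics temperature)
#'   or a number (m^2/s), `> 0`.
#' @param nz,nr Grid sizes (axial x radial); defaults 120 x 24.
#' @param dt Internal time step (s); default 1e-3. The CFL number
#'   `max|u| dt / dz` must be `<= 0.9`.
#' @param t_end Simulated window (s); default 1.5.
#' @param dt_out Output sampling step (s); default 0.009.
#' @param init_concentration Initial uniform bulk concentration (mol/m^3).
#' @return Object of class `transport_scenario`.
#' @export
transport_scenario <- function(geometry, fluid, protein, kinetics,
                               velocity, inlet_concentration = NULL,
                               diffusivity = "auto",
                               nz = 120L, nr = 24L, dt = 1e-3, t_end = 1.5,
                               dt_out = 0.009, init_concentration = 0) {
  stopifnot(inherits(geometry, "graft_geometry"),
            inherits(fluid, "fluid_properties"),
            inherits(protein, "protein_spec"),
            inherits(kinetics, "kinetic_params"))
  if (is.numeric(velocity) && length(velocity) == 1L) {
    velocity <- build_velocity(velocity, geometry, t_end = t_end)
  }
  stopifnot(inherits(velocity, "velocity_interpolant"))
  if (identical(diffusivity, "auto")) {
    diffusivity <- stokes_einstein_diffusivity(protein, fluid,
                                               kinetics$temperature)
  }
  check_scalar(diffusivity, "diffusivity", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(t_end, "t_end", positive = TRUE)
  check_scalar(init_concentration, "init_concentration", nonneg = TRUE)
  nz <- as.integer(nz); nr <- as.integer(nr)
  if (nz < 4L || nr < 4L) stop_invalid("grid too coarse (need nz, nr >= 4)")
  if (is.null(inlet_concentration)) {
    inlet_concentration <- protein$inlet_max_concentration
  }
  cin_fun <- if (is.function(inlet_concentration)) {
    inlet_concentration
  } else {
    check_scalar(inlet_concentration, "inlet_concentration", nonneg = TRUE)
    local({ v <- inlet_concentration; function(t) v })
  }
  dz <- geometry$length / nz
  cfl <- velocity$u_max * dt / dz
  if (cfl > 0.9) {
    stop_invalid("CFL number ", signif(cfl, 4), " exceeds 0.9 ",
                 "(max |u| = ", signif(velocity$u_max, 4), " m/s, dt = ", dt,
                 " s, dz = ", signif(dz, 4), " m)")
  }
  structure(list(geometry = geometry, fluid = fluid, protein = protein,
                 kinetics = kinetics, velocity = velocity,
                 inlet_concentration = cin_fun, diffusivity = diffusivity,
                 nz = nz, nr = nr, dt = dt, t_end = t_end, dt_out = dt_out,
                 init_concentration = init_concentration),
            class = "transport_scenario")
}

# Weighted diffusion Laplacian (K, positive semidefinite) and cell "volume"
# diagonal W (both per unit 2*pi), for the implicit diffusion solve
# (W + dt K) C_new = W C_star.
build_diffusion_operator <- function(rc, dz, dr, nz, D, dt) {
  nr <- length(rc)
  np <- nr * nz
  idx <- function(i, j) i + (j - 1L) * nr
  ii <- jj <- xx <- list()
  # radial faces between (i, i+1) at r = i*dr: conductance D * (i*dr) * dz / dr
  i <- rep(seq_len(nr - 1L), times = nz)
  j <- rep(seq_len(nz), each = nr - 1L)
  g <- D * (i * dr) * dz / dr
  p <- idx(i, j); q <- idx(i + 1L, j)
  # axial faces between (j, j+1): conductance D * rc_i * dr / dz
  i2 <- rep(seq_len(nr), times = nz - 1L)
  j2 <- rep(seq_len(nz - 1L), each = nr)
  g2 <- D * rc[i2] * dr / dz
  p2 <- idx(i2, j2); q2 <- idx(i2, j2 + 1L)
  Ki <- c(p, q, p, q, p2, q2, p2, q2)
  Kj <- c(q, p, p, q, q2, p2, p2, q2)
  Kx <- c(-g, -g, g, g, -g2, -g2, g2, g2)
  K <- Matrix::sparseMatrix(i = Ki, j = Kj, x = Kx, dims = c(np, np))
  W <- Matrix::Diagonal(np, x = rep(rc * dr * dz, times = nz))
  M <- W + dt * K
  Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
}

#' Simulate coupled bulk transport and wall adsorption
#'
#' Advances the axisymmetric concentration field and the wall surface species
#' from zero (or a uniform initial concentration) to `t_end`, storing output
#' frames every `dt_out`. Errors before stepping on CFL violation; aborts with
#' diagnostics if bulk concentration drops below -1e-12 of the inlet maximum.
#'
#' @param scenario A [transport_scenario()].
#' @return Object of class `transport_result`: output times `t_s`, bulk
#'   concentration frames `C` (array `nr x nz x n_frames`, mol/m^3), surface
#'   species `gamma_PS`, `gamma_irr` (`nz x n_frames`, mol/m^2), near-wall
#'   max/mean trajectories `near_wall`, the grids, and a mass-balance audit.
#' @export
simulate_transport <- function(scenario) {
  stopifnot(inherits(scenario, "transport_scenario"))
  sc <- scenario
  R <- sc$geometry$inner_radius
  L <- sc$geometry$length
  nr <- sc$nr; nz <- sc$nz
  dr <- R / nr; dz <- L / nz
  rc <- (seq_len(nr) - 0.5) * dr
  zc <- (seq_len(nz) - 0.5) * dz
  dt <- sc$dt
  nsteps <- ceiling(sc$t_end / dt - 1e-9)
  out_every <- max(1L, round(sc$dt_out / dt))
  kin <- sc$kinetics
  gamma_tot <- kin$G0 + kin$CS0
  a_w <- R / (rc[nr] * dr)          # wall face area per wall-cell volume, 1/m
  cmax_ref <- max(sc$protein$inlet_max_concentration, sc$init_concentration)

  chol_M <- build_diffusion_operator(rc, dz, dr, nz, sc$diffusivity, dt)
  Wvec <- rep(rc * dr * dz, times = nz)

  C <- matrix(sc$init_concentration, nr, nz)
  gPS <- rep(0, nz); gIr <- rep(0, nz)

  n_frames <- floor(nsteps / out_every) + 1L
  Cfr <- array(NA_real_, c(nr, nz, n_frames))
  gPSfr <- gIrfr <- matrix(NA_real_, nz, n_frames)
  t_out <- numeric(n_frames)
  Cfr[, , 1L] <- C; gPSfr[, 1L] <- gPS; gIrfr[, 1L] <- gIr
  frame <- 1L

  ring_area <- rc * dr               # per unit 2*pi
  net_influx <- 0                    # boundary advective moles in (per 2*pi)

  bulk_inventory <- function(C) sum(as.vector(C) * Wvec)
  bound_inventory <- function() sum((gPS + gIr) * R * dz)
  B0 <- bulk_inventory(C) + bound_inventory()

  react <- function(Cw, gPS, gIr, dt) {
    # RK2 midpoint on the per-station (C_wall, Gamma_PS, Gamma_irr) system;
    # the bulk update is slaved to the surface update so moles balance exactly.
    f <- function(Cw, gPS, gIr) {
      gS <- gamma_tot - gPS - gIr
      J <- kin$k_f * Cw * gS - kin$k_r * gPS
      list(dPS = J - kin$k_i * gPS, dIr = kin$k_i * gPS, dC = -J * a_w)
    }
    k1 <- f(Cw, gPS, gIr)
    k2 <- f(pmax(Cw + dt / 2 * k1$dC, 0), gPS + dt / 2 * k1$dPS,
            gIr + dt / 2 * k1$dIr)
    dPS <- dt * k2$dPS; dIr <- dt * k2$dIr
    gPS2 <- pmax(gPS + dPS, 0)
    gIr2 <- gIr + dIr
    over <- gPS2 + gIr2 - gamma_tot
    gPS2 <- ifelse(over > 0, gPS2 - over, gPS2)   # site-conservation clamp
    Cw2 <- Cw - ((gPS2 - gPS) + (gIr2 - gIr)) * a_w
    list(C = Cw2, gPS = gPS2, gIr = gIr2)
  }

  for (k in seq_len(nsteps)) {
    t_k <- (k - 1) * dt
    u <- sc$velocity$query(rc, t_k)            # length nr
    cin <- sc$inlet_concentration(t_k)
    pos <- pmax(u, 0); neg <- pmin(u, 0)

    CL <- cbind(cin, C[, -nz, drop = FALSE])
    CR <- cbind(C[, -1L, drop = FALSE], C[, nz])
    # net boundary influx of the discrete upwind update (exact telescoping of
    # the flux form, evaluated on the pre-update field)
    net_influx <- net_influx +
      dt * sum(pos * ring_area * (cin - C[, nz])) +
      dt * sum(neg * ring_area * (C[, 1L] - C[, nz]))
    C <- C - (dt / dz) * (pos * (C - CL) + neg * (CR - C))

    # implicit diffusion
    rhs <- Wvec * as.vector(C)
    C <- matrix(as.numeric(Matrix::solve(chol_M, rhs, system = "A")), nr, nz)

    # wall reaction
    rr <- react(C[nr, ], gPS, gIr, dt)
    C[nr, ] <- rr$C; gPS <- rr$gPS; gIr <- rr$gIr

    if (any(C < -1e-12 * cmax_ref)) {
      bad <- which(C == min(C), arr.ind = TRUE)[1, ]
      stop("negative bulk concentration ", signif(min(C), 4), " mol/m^3 at r = ",
           signif(rc[bad[1]], 4), " m, z = ", signif(zc[bad[2]], 4),
           " m, t = ", signif(t_k + dt, 6), " s")
    }
    C[C < 0] <- 0

    if (k %% out_every == 0L) {
      frame <- frame + 1L
      if (frame <= n_frames) {
        Cfr[, , frame] <- C
        gPSfr[, frame] <- gPS
        gIrfr[, frame] <- gIr
        t_out[frame] <- k * dt
      }
    }
  }
  n_frames <- frame
  Cfr <- Cfr[, , seq_len(n_frames), drop = FALSE]
  gPSfr <- gPSfr[, seq_len(n_frames), drop = FALSE]
  gIrfr <- gIrfr[, seq_len(n_frames), drop = FALSE]
  t_out <- t_out[seq_len(n_frames)]

  nw <- t(apply(Cfr[nr, , , drop = TRUE], 2, function(col) {
    c(max = max(col), mean = mean(col))
  }))
  near_wall <- data.frame(t_s = t_out, max = nw[, "max"], mean = nw[, "mean"])

  B1 <- bulk_inventory(C) + bound_inventory()
  denom <- max(abs(net_influx), B1, cmax_ref * sum(Wvec) * 1e-9)
  mass_balance <- list(net_boundary_influx = net_influx,
                       inventory_change = B1 - B0,
                       relative_error = (B1 - B0 - net_influx) / denom)

  structure(list(t_s = t_out, C = Cfr, gamma_PS = gPSfr, gamma_irr = gIrfr,
                 near_wall = near_wall, r = rc, z = zc,
                 mass_balance = mass_balance, scenario = sc),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  nfr <- length(x$t_s)
  cat("Transport-adsorption result:", dim(x$C)[1], "x", dim(x$C)[2],
      "cells,", nfr, "frames to t =", format(x$t_s[nfr]), "s\n")
  cat("  protein:", x$scenario$protein$name,
      "| peak near-wall bulk:", format(signif(max(x$near_wall$max), 4)),
      "mol/m^3 | mass-balance error:",
      format(signif(x$mass_balance$relative_error, 3)), "\n")
  invisible(x)
}

#' Near-wall and surface statistics at a given time
#'
#' Max and mean over the axial extent of the wall-adjacent cell ring (bulk
#' concentration) and of each surface species, linearly interpolated between
#' stored frames.
#'
#' @param result A `transport_result`.
#' @param t Time (s) within the simulated window.
#' @return Data frame with one row per quantity (`near_wall_bulk`, `gamma_S`,
#'   `gamma_PS`, `gamma_irr`) and columns `max`, `mean`.
#' @export
surface_stats <- function(result, t) {
  stopifnot(inherits(result, "transport_result"))
  ts <- result$t_s
  if (t < ts[1] - 1e-9 || t > ts[length(ts)] + 1e-9) {
    stop_invalid("t = ", t, " s outside the simulated window [",
                 ts[1], ", ", ts[length(ts)], "]")
  }
  i2 <- min(max(findInterval(t, ts), 1L) + 1L, length(ts))
  i1 <- i2 - 1L
  w <- if (ts[i2] > ts[i1]) (t - ts[i1]) / (ts[i2] - ts[i1]) else 0
  nr <- dim(result$C)[1]
  wall <- (1 - w) * result$C[nr, , i1] + w * result$C[nr, , i2]
  gPS <- (1 - w) * result$gamma_PS[, i1] + w * result$gamma_PS[, i2]
  gIr <- (1 - w) * result$gamma_irr[, i1] + w * result$gamma_irr[, i2]
  kin <- result$scenario$kinetics
  gS <- (kin$G0 + kin$CS0) - gPS - gIr
  data.frame(
    quantity = c("near_wall_bulk", "gamma_S", "gamma_PS", "gamma_irr"),
    max = c(max(wall), max(gS), max(gPS), max(gIr)),
    mean = c(mean(wall), mean(gS), mean(gPS), mean(gIr))
  )
}

#' Export transport snapshots as long-format tables
#'
#' @param result A `transport_result`.
#' @param path Optional CSV path for the concentration field
#'   (`z_m,r_m,t_s,c_mol_m3`).
#' @param surface_path Optional CSV path for the surface state
#'   (`t_s,z_m,gamma_S,gamma_PS,gamma_PS_irr`).
#' @param times Subset of output times to export (default: all frames).
#' @export
transport_tables <- function(result, path = NULL, surface_path = NULL,
                             times = result$t_s) {
  keep <- vapply(times, function(t) which.min(abs(result$t_s - t)), 1L)
  d <- expand.grid(r_m = result$r, z_m = result$z, t_s = result$t_s[keep],
                   KEEP.OUT.ATTRS = FALSE)
  d$c_mol_m3 <- as.vector(result$C[, , keep])
  d <- d[, c("z_m", "r_m", "t_s", "c_mol_m3")]
  if (!is.null(path)) utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  kin <- result$scenario$kinetics
  s <- expand.grid(z_m = result$z, t_s = result$t_s[keep],
                   KEEP.OUT.ATTRS = FALSE)
  s$gamma_S <- as.vector((kin$G0 + kin$CS0) - result$gamma_PS[, keep] -
                           result$gamma_irr[, keep])
  s$gamma_PS <- as.vector(result$gamma_PS[, keep])
  s$gamma_PS_irr <- as.vector(result$gamma_irr[, keep])
  s <- s[, c("t_s", "z_m", "gamma_S", "gamma_PS", "gamma_PS_irr")]
  if (!is.null(surface_path)) {
    utils::write.csv(s, surface_path, row.names = FALSE, quote = FALSE)
  }
  invisible(list(field = d, surface = s))
}
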