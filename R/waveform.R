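# Fourier-harmonic representation of periodic pressure signals:
# P(t) = A0 + sum_n [ An cos(n w t) + Bn sin(n w t) ]  (one-sided real series,
# so A0 is the arithmetic mean over one period).

#' Harmonic series representation of a periodic pressure signal
#'
#' Constructs the one-sided real Fourier representation
#' \deqn{P(t) = A_0 + \sum_{n=1}^{N} A_n \cos(n\omega t) + B_n \sin(n\omega t)}
#' used to impose measured pulsatile pressure (or pressure-gradient) waveforms
#' as boundary conditions.
#'
#' @param A0 Mean term (Pa, or Pa/m for gradient series).
#' @param An,Bn Cosine and sine coefficients for harmonics `1..N`; equal length,
#'   possibly length 0 for a constant signal.
#' @param omega Fundamental angular frequency (rad/s), `> 0`.
#' @return An object of class `harmonic_series`.
#' @examples
#' hs <- harmonic_series(A0 = 11819, An = c(500, 120), Bn = c(-300, 80),
#'                       omega = 2 * pi / 1.5)
#' predict(hs, t = seq(0, 1.5, by = 0.01))
#' @export
harmonic_series <- function(A0, An = numeric(0), Bn = numeric(0), omega) {
  check_scalar(A0, "A0")
  check_scalar(omega, "omega", positive = TRUE)
  if (length(An) != length(Bn)) {
    stop_invalid("`An` and `Bn` must have the same length (got ",
                 length(An), " and ", length(Bn), ")")
  }
  if (length(An) && (!is.numeric(An) || !is.numeric(Bn) ||
                     any(!is.finite(An)) || any(!is.finite(Bn)))) {
    stop_invalid("harmonic coefficients must be finite numerics")
  }
  structure(
    list(A0 = as.numeric(A0), An = as.numeric(An), Bn = as.numeric(Bn),
         omega = as.numeric(omega)),
    class = "harmonic_series"
  )
}

#' @export
print.harmonic_series <- function(x, ...) {
  cat("Harmonic series: A0 =", format(x$A0),
      "| N =", length(x$An), "harmonics | omega =", format(x$omega), "rad/s",
      "| period =", format(2 * pi / x$omega), "s\n")
  if (length(x$An)) {
    amp <- sqrt(x$An^2 + x$Bn^2)
    k <- utils::head(order(amp, decreasing = TRUE), 5L)
    cat("  dominant harmonics (n: amplitude):",
        paste0(k, ": ", signif(amp[k], 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.harmonic_series <- function(object, ...) {
  n <- length(object$An)
  c(A0 = object$A0,
    if (n) stats::setNames(object$An, paste0("A", seq_len(n))),
    if (n) stats::setNames(object$Bn, paste0("B", seq_len(n))))
}

#' Evaluate a harmonic series at given times
#'
#' @param object A [harmonic_series()].
#' @param t Times (s), any shape.
#' @param ... Unused.
#' @return Pressures (Pa), same shape as `t`.
#' @export
predict.harmonic_series <- function(object, t, ...) {
  evaluate_series(object, t)
}

#' @rdname predict.harmonic_series
#' @param series A [harmonic_series()].
#' @export
evaluate_series <- function(series, t) {
  stopifnot(inherits(series, "harmonic_series"))
  tt <- as.numeric(t)
  out <- rep(series$A0, length(tt))
  N <- length(series$An)
  if (N) {
    ph <- outer(tt, seq_len(N)) * series$omega   # [time x harmonic]
    out <- out + cos(ph) %*% series$An + sin(ph) %*% series$Bn
  }
  out <- as.numeric(out)
  attributes(out) <- attributes(t)[c("dim", "dimnames")]
  out
}

#' Uniformly sampled periodic pressure trace
#'
#' @param times Sample times (s); strictly increasing, uniformly spaced
#'   (relative tolerance 1e-9).
#' @param pressures Pressures (Pa), same length as `times`.
#' @param period Declared period of the signal (s).
#' @return An object of class `pressure_trace` (a data frame with attributes).
#' @export
pressure_trace <- function(times, pressures, period) {
  if (length(times) != length(pressures) || length(times) < 2L) {
    stop_invalid("`times` and `pressures` must have equal length >= 2")
  }
  if (any(diff(times) <= 0)) stop_invalid("`times` must be strictly increasing")
  if (!is_uniform_grid(times)) {
    stop_invalid("`times` must be uniformly spaced (relative tolerance 1e-9)")
  }
  check_scalar(period, "period", positive = TRUE)
  structure(
    data.frame(time_s = as.numeric(times), pressure_pa = as.numeric(pressures)),
    period = as.numeric(period),
    class = c("pressure_trace", "data.frame")
  )
}

#' Fit the Fourier-harmonic representation of a periodic trace
#'
#' Least-squares projection of a uniformly sampled periodic pressure trace on
#' the harmonic basis `{1, cos(n w t), sin(n w t)}`; for uniform sampling over
#' whole periods this coincides with the discrete Fourier transform, and `A0`
#' equals the trace mean over one period.
#'
#' @param trace A [pressure_trace()].
#' @param n_harmonics Number of harmonics `N >= 0` to fit; must respect the
#'   Nyquist limit of the sampling (at least 2 samples per period of the
#'   highest harmonic).
#' @param fundamental Fundamental angular frequency (rad/s). Default `2*pi`
#'   over the trace's declared period.
#' @return A [harmonic_series()].
#' @examples
#' t <- seq(0, 1.5, length.out = 129)[-129]
#' tr <- pressure_trace(t, 5 + 2 * cos(2 * pi * t / 1.5), period = 1.5)
#' coef(fit_dft(tr, n_harmonics = 3))
#' @export
fit_dft <- function(trace, n_harmonics, fundamental = NULL) {
  stopifnot(inherits(trace, "pressure_trace"))
  check_scalar(n_harmonics, "n_harmonics", nonneg = TRUE)
  n_harmonics <- as.integer(n_harmonics)
  period <- attr(trace, "period")
  if (is.null(fundamental)) fundamental <- 2 * pi / period
  check_scalar(fundamental, "fundamental", positive = TRUE)

  t <- trace$time_s
  p <- trace$pressure_pa
  dt <- t[2] - t[1]
  span <- t[length(t)] - t[1] + dt
  fit_period <- 2 * pi / fundamental
  if (span < fit_period * (1 - 1e-9)) {
    stop_invalid("trace spans ", signif(span, 6), " s but one period at the ",
                 "given fundamental is ", signif(fit_period, 6), " s")
  }
  # Nyquist: need > 2 samples per period of the highest harmonic.
  nyq <- floor(fit_period / (2 * dt))
  if (n_harmonics > nyq) {
    stop_invalid("n_harmonics = ", n_harmonics, " exceeds the Nyquist limit ",
                 nyq, " for sampling interval ", signif(dt, 6), " s")
  }

  X <- matrix(1, nrow = length(t), ncol = 1 + 2 * n_harmonics)
  if (n_harmonics > 0) {
    ph <- outer(t, seq_len(n_harmonics)) * fundamental
    X[, 1 + seq_len(n_harmonics)] <- cos(ph)
    X[, 1 + n_harmonics + seq_len(n_harmonics)] <- sin(ph)
  }
  beta <- qr.coef(qr(X), p)
  beta[is.na(beta)] <- 0
  harmonic_series(
    A0 = beta[1],
    An = beta[1 + seq_len(n_harmonics)],
    Bn = beta[1 + n_harmonics + seq_len(n_harmonics)],
    omega = fundamental
  )
}

# Normalized band-limited physiological pulse shape on phase [0, 1):
# systolic upstroke peaking at phase `peak_phase`, diastolic minimum near
# `min_phase`, built from `n_harmonics` Fourier modes of a periodic Gaussian
# bump (so it round-trips exactly through fit_dft at N >= n_harmonics).
# Returned as zero-mean harmonic coefficients scaled to unit peak amplitude.
pulse_shape_coeffs <- function(n_harmonics = 8L, peak_phase = 0.786,
                               width = 0.11) {
  # Fourier coefficients of a periodic Gaussian bump centred at peak_phase:
  # g(phi) = sum_n 2 exp(-(pi n width)^2 /?) ... computed numerically for
  # robustness.
  phi <- seq(0, 1, length.out = 2049)[-2049]
  d <- (phi - peak_phase) - round(phi - peak_phase)     # wrapped distance
  g <- exp(-0.5 * (d / width)^2)
  g <- g - mean(g)
  An <- Bn <- numeric(n_harmonics)
  for (n in seq_len(n_harmonics)) {
    An[n] <- 2 * mean(g * cos(2 * pi * n * phi))
    Bn[n] <- 2 * mean(g * sin(2 * pi * n * phi))
  }
  # scale to unit maximum deviation from zero
  rec <- rep(0, length(phi))
  for (n in seq_len(n_harmonics)) {
    rec <- rec + An[n] * cos(2 * pi * n * phi) + Bn[n] * sin(2 * pi * n * phi)
  }
  s <- max(abs(rec))
  list(An = An / s, Bn = Bn / s)
}

#' Generate a synthetic physiological pressure trace
#'
#' Deterministic, band-limited surrogate for an experimental pulsatile pressure
#' recording: a periodic pulse with a systolic upstroke and diastolic decay,
#' with exact requested mean. The systolic peak sits at ~0.786 of the cycle and
#' the minimum near 0.2, matching the pressure-extreme timing of the packaged
#' scenarios (Pmax at 1.179 s, Pmin at 0.3 s on a 1.5 s cycle). Optional seeded
#' Gaussian measurement noise can be added; by default the trace is noise-free
#' and exactly band-limited to 8 harmonics.
#'
#' @param mean Mean pressure over one period (Pa).
#' @param pulse_amplitude Peak deviation of the pulse from the mean (Pa),
#'   `>= 0`; 0 gives a constant trace.
#' @param period Period (s), `> 0`.
#' @param n_samples Number of uniform samples over one period (`>= 16`).
#' @param seed Integer seed (used only if `noise_sd > 0`).
#' @param noise_sd Standard deviation of additive measurement noise (Pa).
#' @return A [pressure_trace()] covering exactly one period.
#' @export
synthesize_trace <- function(mean, pulse_amplitude, period = 1.5,
                             n_samples = 512L, seed = 1L, noise_sd = 0) {
  check_scalar(mean, "mean")
  check_scalar(pulse_amplitude, "pulse_amplitude", nonneg = TRUE)
  check_scalar(period, "period", positive = TRUE)
  check_scalar(n_samples, "n_samples")
  if (n_samples < 16) stop_invalid("`n_samples` must be >= 16")
  t <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  sh <- pulse_shape_coeffs()
  w <- 2 * pi / period
  p <- rep(mean, n_samples)
  for (n in seq_along(sh$An)) {
    p <- p + pulse_amplitude * (sh$An[n] * cos(n * w * t) +
                                sh$Bn[n] * sin(n * w * t))
  }
  p <- p - (base::mean(p) - mean)   # enforce exact requested mean
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(as.integer(seed))
    p <- p + stats::rnorm(n_samples, sd = noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  pressure_trace(t, p, period = period)
}

#' Read/write pressure traces and harmonic series
#'
#' Traces are 2-column CSV files with header `time_s,pressure_pa`; harmonic
#' series are JSON objects with keys `A0`, `An`, `Bn`, `omega_rad_s`.
#'
#' @param path File path.
#' @param trace A [pressure_trace()].
#' @param period Declared period (s) for `read_pressure_trace`.
#' @name waveform_io
NULL

#' @rdname waveform_io
#' @export
write_pressure_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname waveform_io
#' @export
read_pressure_trace <- function(path, period) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "pressure_pa") %in% names(d))) {
    stop_invalid("trace file must have columns `time_s` and `pressure_pa`")
  }
  pressure_trace(d$time_s, d$pressure_pa, period = period)
}

#' @rdname waveform_io
#' @param series A [harmonic_series()].
#' @export
write_harmonic_series <- function(series, path) {
  stopifnot(inherits(series, "harmonic_series"))
  jsonlite::write_json(
    list(A0 = series$A0, An = series$An, Bn = series$Bn,
         omega_rad_s = series$omega),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname waveform_io
#' @export
read_harmonic_series <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  harmonic_series(A0 = x$A0, An = as.numeric(x$An), Bn = as.numeric(x$Bn),
                  omega = x$omega_rad_s)
}
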