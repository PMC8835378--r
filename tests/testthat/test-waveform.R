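test_that("fit_dft recovers exact coefficients of band-limited signals", {
  # constant trace
  t <- seq(0, 1.5, length.out = 64 + 1)[1:64]
  tr <- pressure_trace(t, rep(100, 64), period = 1.5)
  hs <- fit_dft(tr, 5)
  expect_equal(hs$A0, 100)
  expect_equal(hs$An, rep(0, 5), tolerance = 1e-12)
  expect_equal(hs$Bn, rep(0, 5), tolerance = 1e-12)

  # p(t) = 5 + 2 cos(w t): compare against direct projection integrals
  # computed by trapezoid quadrature on a periodic extension (oracle)
  w <- 2 * pi / 1.5
  p <- 5 + 2 * cos(w * t)
  tr <- pressure_trace(t, p, period = 1.5)
  hs <- fit_dft(tr, 3)
  tp <- c(t, 1.5)                     # close the period for quadrature
  pp <- c(p, p[1])
  a0_oracle <- (sum((pp[-1] + pp[-65]) * diff(tp)) / 2) / 1.5
  a1_oracle <- (2 / 1.5) * sum((pp[-1] * cos(w * tp[-1]) +
                                pp[-65] * cos(w * tp[-65])) * diff(tp)) / 2
  expect_equal(hs$A0, a0_oracle, tolerance = 1e-9)
  expect_equal(hs$An[1], a1_oracle, tolerance = 1e-9)
  expect_equal(hs$An[1], 2, tolerance = 1e-9)
  expect_equal(max(abs(c(hs$An[-1], hs$Bn))), 0, tolerance = 1e-9)
})

test_that("fit_dft validates sampling and the Nyquist limit", {
  expect_error(pressure_trace(c(0, 0.1, 0.15), c(1, 2, 3), 1),
               "uniformly spaced")
  t <- seq(0, 1, length.out = 17)[1:16]
  tr <- pressure_trace(t, sin(2 * pi * t), period = 1)
  expect_error(fit_dft(tr, 20), "Nyquist limit 8")
  # trace shorter than one period at the requested fundamental
  expect_error(fit_dft(tr, 2, fundamental = 2 * pi / 5), "one period")
})

test_that("evaluate matches a naive term-by-term oracle and has mean A0", {
  set.seed(42)
  N <- 12
  hs <- harmonic_series(A0 = 7, An = rnorm(N), Bn = rnorm(N), omega = 3.1)
  tq <- runif(1000, -5, 5)
  naive <- vapply(tq, function(tt) {
    s <- hs$A0
    for (n in 1:N) s <- s + hs$An[n] * cos(hs$omega * tt * n) +
        hs$Bn[n] * sin(hs$omega * tt * n)
    s
  }, 0)
  expect_equal(evaluate_series(hs, tq), naive, tolerance = 1e-12)

  # constant series
  expect_equal(evaluate_series(harmonic_series(7, omega = 1), c(0, 1, 99)),
               c(7, 7, 7))

  # orthogonality: mean over one period equals A0
  period <- 2 * pi / hs$omega
  tgrid <- seq(0, period, length.out = 4097)[-4097]
  expect_equal(mean(evaluate_series(hs, tgrid)), hs$A0, tolerance = 1e-9)

  # periodicity
  expect_equal(evaluate_series(hs, tq + period), evaluate_series(hs, tq),
               tolerance = 1e-9)
})

test_that("fit/evaluate round trip and linearity hold on band-limited traces", {
  set.seed(7)
  period <- 1.2
  t <- seq(0, period, length.out = 257)[1:256]
  for (rep in 1:5) {
    N <- sample(1:10, 1)
    An <- rnorm(N); Bn <- rnorm(N); A0 <- rnorm(1, 100, 10)
    hs <- harmonic_series(A0, An, Bn, omega = 2 * pi / period)
    p <- evaluate_series(hs, t)
    fit <- fit_dft(pressure_trace(t, p, period), N)
    expect_equal(evaluate_series(fit, t), p, tolerance = 1e-9)
    expect_equal(fit$An, An, tolerance = 1e-8)
  }
  # linearity of the projection
  p1 <- 3 + cos(2 * pi * t / period)
  p2 <- 1 + sin(4 * pi * t / period)
  f1 <- fit_dft(pressure_trace(t, p1, period), 3)
  f2 <- fit_dft(pressure_trace(t, p2, period), 3)
  f12 <- fit_dft(pressure_trace(t, p1 + p2, period), 3)
  expect_equal(f12$A0, f1$A0 + f2$A0, tolerance = 1e-10)
  expect_equal(f12$An, f1$An + f2$An, tolerance = 1e-10)
  expect_equal(f12$Bn, f1$Bn + f2$Bn, tolerance = 1e-10)
})

test_that("synthesize_trace hits the requested mean and round-trips", {
  tr <- synthesize_trace(11819, 2650)
  expect_equal(mean(tr$pressure_pa), 11819, tolerance = 1e-9)
  expect_equal(attr(tr, "period"), 1.5)

  # zero amplitude -> constant at mean
  tr0 <- synthesize_trace(500, 0, n_samples = 32)
  expect_equal(tr0$pressure_pa, rep(500, 32))

  # full-order fit reproduces the (8-harmonic) trace exactly
  fit8 <- fit_dft(tr, 8)
  expect_equal(evaluate_series(fit8, tr$time_s), tr$pressure_pa,
               tolerance = 1e-9)

  # truncated fit residual equals the energy in the dropped harmonics
  # (Parseval): oracle from the full fit's high-order coefficients
  fit4 <- fit_dft(tr, 4)
  resid <- tr$pressure_pa - evaluate_series(fit4, tr$time_s)
  dropped <- 0.5 * sum(fit8$An[5:8]^2 + fit8$Bn[5:8]^2)
  expect_equal(mean(resid^2), dropped, tolerance = 1e-6)

  expect_error(synthesize_trace(100, 10, period = -1), "period")
  expect_error(synthesize_trace(100, 10, n_samples = 8), "n_samples")
})

test_that("trace and series survive CSV/JSON round trips", {
  tr <- synthesize_trace(12784, 2650, n_samples = 64)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pressure_trace(tr, f)
  tr2 <- read_pressure_trace(f, period = 1.5)
  expect_equal(tr2$pressure_pa, tr$pressure_pa, tolerance = 1e-9)

  hs <- fit_dft(tr, 6)
  g <- withr::local_tempfile(fileext = ".json")
  write_harmonic_series(hs, g)
  hs2 <- read_harmonic_series(g)
  expect_equal(coef(hs2), coef(hs))
  expect_equal(hs2$omega, hs$omega)
})
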