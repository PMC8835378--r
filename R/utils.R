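#' @keywords internal
"_PACKAGE"

# Shared argument checks used across modules. All physical quantities are SI
# unless a function's documentation says otherwise.

stop_invalid <- function(...) {
  stop(structure(
    class = c("tevgsim_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  if (positive && x <= 0) stop_invalid("`", name, "` must be > 0")
  if (nonneg && x < 0) stop_invalid("`", name, "` must be >= 0")
  invisible(x)
}

# Complex-argument Bessel function of the first kind, integer order 0 or 1,
# by the ascending power series.  The Womersley solution only ever needs
# arguments z = i^{3/2} * s with real s = alpha * r/R <= alpha; the series in
# double precision keeps ~9 significant digits up to |z| ~ 20-25, which covers
# Womersley numbers up to the spec'd alpha = 20.
besselJ_complex <- function(z, nu = 0L) {
  stopifnot(nu %in% c(0L, 1L))
  z <- as.complex(z)
  half <- z / 2
  term <- if (nu == 0L) rep(1 + 0i, length(z)) else half
  total <- term
  zz <- half * half
  for (k in 1:200) {
    term <- -term * zz / (k * (k + nu))
    total <- total + term
    if (all(Mod(term) <= 1e-17 * (Mod(total) + 1))) break
  }
  total
}

# Trapezoid rule on a (possibly non-uniform) grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

is_uniform_grid <- function(x, rtol = 1e-9) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  max(abs(d - d[1])) <= rtol * abs(d[1])
}
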