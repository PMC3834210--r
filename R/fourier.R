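#' Truncated Fourier series representation
#'
#' Represents one real band-limited periodic signal by its complex Fourier
#' coefficients `c_k`, `k = 0..F`, with the negative harmonics implied by
#' conjugate symmetry. The signal evaluated at `n` equally spaced points over
#' one period is `Re(c_0) + sum_k 2 Re(c_k exp(2i pi k m / n))`. Under this
#' convention `cos(2 pi t / T)` has `c_1 = 1/2`.
#'
#' @param coeffs Complex vector of length `F + 1` (`c_0` first). The
#'   imaginary part of `c_0` is forced to zero.
#' @param period Period in samples of the native sampling grid (> 0).
#' @param sample_rate Sampling rate in Hz of that grid (default 1), so the
#'   period in seconds is `period / sample_rate`.
#' @return Object of class `fourier_series`.
#' @export
fourier_series <- function(coeffs, period, sample_rate = 1) {
  coeffs <- as.complex(coeffs)
  if (length(coeffs) < 2L) abort("Need at least harmonics 0 and 1 (F >= 1).")
  coeffs[1L] <- complex(real = Re(coeffs[1L]), imaginary = 0)
  structure(list(coeffs = coeffs, order = length(coeffs) - 1L,
                 period = period, sample_rate = sample_rate),
            class = "fourier_series")
}

#' @export
print.fourier_series <- function(x, ...) {
  cat(sprintf("<fourier_series> order %d, period %g samples @ %g Hz\n",
              x$order, x$period, x$sample_rate))
  invisible(x)
}

#' Project a sampled signal onto its first F harmonics
#'
#' Computes the discrete Fourier projection of a real series onto harmonics
#' `0..F` of its own length (one period per record). The discarded harmonics
#' carry exactly the reconstruction error.
#'
#' @param y Real numeric vector (one period, `length(y) >= 2F + 1`).
#' @param F Highest retained harmonic (>= 1).
#' @param sample_rate Sampling rate in Hz (metadata only).
#' @return A [fourier_series()].
#' @export
#' @examples
#' s <- fourier_fit(cos(2 * pi * (0:99) / 100), F = 3)
#' Mod(s$coeffs) # 0, 0.5, 0, 0
fourier_fit <- function(y, F = 10L, sample_rate = 1) {
  n <- length(y)
  F <- as.integer(F)
  if (F < 1L) abort("`F` must be at least 1.")
  if (n < 2L * F + 1L)
    abort(sprintf("Signal of length %d cannot resolve %d harmonics (need T >= 2F+1).", n, F))
  c_all <- fft(y) / n
  fourier_series(c_all[seq_len(F + 1L)], period = n, sample_rate = sample_rate)
}

#' Evaluate a truncated Fourier series on a uniform grid
#'
#' @param series A [fourier_series()].
#' @param n_samples Number of equally spaced evaluation points over one
#'   period (>= 2).
#' @return Real numeric vector of length `n_samples`.
#' @export
fourier_eval <- function(series, n_samples = series$period) {
  stopifnot(inherits(series, "fourier_series"))
  n_samples <- as.integer(round(n_samples))
  if (n_samples < 2L) abort("`n_samples` must be at least 2.")
  k <- seq_len(series$order)
  m <- 0:(n_samples - 1L)
  ph <- exp(2i * pi * outer(m / n_samples, k))
  as.vector(Re(series$coeffs[1L]) + 2 * Re(ph %*% series$coeffs[-1L]))
}

#' Circularly delay a Fourier series
#'
#' Multiplies each harmonic by the unit phasor `exp(-2i pi k tau / T)`, the
#' exact frequency-domain form of a circular time shift by `tau` samples of
#' the native grid. Delays are periodic in the record length: `tau = T`
#' returns the identical series.
#'
#' @param series A [fourier_series()].
#' @param tau Delay in samples of the native grid (may be fractional or
#'   negative). Use `tau_seconds * sample_rate` for delays in seconds.
#' @return A delayed [fourier_series()].
#' @export
fourier_delay <- function(series, tau) {
  stopifnot(inherits(series, "fourier_series"))
  k <- 0:series$order
  fourier_series(series$coeffs * exp(-2i * pi * k * tau / series$period),
                 period = series$period, sample_rate = series$sample_rate)
}

# ---- internal coefficient-matrix helpers (rows = channels/sources) ----

# harmonics 1..F of every row of X (M x T) as an M x F complex matrix,
# plus the row means (harmonic 0 of the raw data)
coeff_matrix <- function(X, F) {
  Tn <- ncol(X)
  if (Tn < 2L * F + 1L)
    abort(sprintf("%d samples cannot resolve %d harmonics.", Tn, F))
  C <- t(apply(X, 1L, function(y) fft(y)[2:(F + 1L)] / Tn))
  if (F == 1L) C <- matrix(C, ncol = 1L)
  C
}

# evaluate an M x F coefficient matrix (harmonics 1..F, zero mean) into an
# M x n real matrix
coeff_eval <- function(C, n) {
  Fh <- ncol(C)
  ph <- exp(2i * pi * outer(seq_len(Fh), 0:(n - 1L)) / n)  # F x n
  2 * Re(C %*% ph)
}

# delay phasors: for delays tau (length M) return M x F matrix of
# exp(-2i pi k tau / Tn)
delay_phasors <- function(tau, Fh, Tn) {
  exp(-2i * pi * outer(tau, seq_len(Fh)) / Tn)
}
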