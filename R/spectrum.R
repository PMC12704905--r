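#' Extract amplitude and phase spectra from a uniformly sampled signal
#'
#' Discrete Fourier analysis of a real time series under the
#' `a * cos(2 pi f t + phase)` convention: a pure cosine of amplitude `a`
#' returns amplitude `a` and phase 0 at its frequency. If `frequencies` is
#' given, amplitude and phase are returned at those frequencies (which must
#' lie on the DFT grid; a record covering a non-integer number of periods
#' triggers a leakage warning).
#'
#' @param x real time series.
#' @param dt sampling interval, ms.
#' @param frequencies optional frequencies (Hz) at which to report.
#' @return a `data.frame` with columns `frequency` (Hz), `amplitude`,
#'   `phase` (radians).
#' @export
extractSpectrum <- function(x, dt, frequencies = NULL) {
  n <- length(x)
  X <- stats::fft(x) / n
  fgrid <- (seq_len(n) - 1L) / (n * dt) * 1000   # Hz
  amp <- c(Mod(X[1L]), 2 * Mod(X[2:(floor(n / 2) + 1L)]))
  ph <- c(Arg(X[1L]), Arg(X[2:(floor(n / 2) + 1L)]))
  out <- data.frame(frequency = fgrid[1:(floor(n / 2) + 1L)],
                    amplitude = amp, phase = ph)
  if (is.null(frequencies)) return(out)
  df <- 1000 / (n * dt)
  k <- frequencies / df
  if (any(abs(k - round(k)) > 1e-6 * pmax(1, k)))
    warning("leakage: record does not cover an integer number of periods ",
            "of every requested frequency")
  out[round(k) + 1L, , drop = FALSE]
}
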