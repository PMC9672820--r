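# Hilbert spectral analysis: analytic signal, instantaneous amplitude and
# frequency.

#' Discrete analytic signal
#'
#' FFT construction: negative-frequency bins are zeroed, positive bins
#' doubled, DC (and Nyquist, for even lengths) kept. The real part of the
#' result equals the input to machine precision.
#'
#' @param x Real numeric vector, length `>= 8`.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 8) {
    stop_memdbci("signal too short for Hilbert analysis (need >= 8 samples).",
                 "memdbci_too_short")
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Instantaneous amplitude and frequency
#'
#' Amplitude is the modulus of the analytic signal; frequency is the
#' unwrapped-phase derivative by central differences (one-sided at the
#' endpoints), scaled to Hz. Negative instantaneous frequencies — which arise
#' only at low-amplitude samples — are clamped to 0, and exactly
#' zero-amplitude samples report frequency 0 by convention, so the trace can
#' be used directly in amplitude-weighted masking statistics without 0/0.
#'
#' @param x Real numeric vector, length `>= 8`.
#' @param fs Sampling rate in Hz.
#' @return A tibble with per-sample columns `amplitude` (>= 0) and
#'   `frequency` (Hz), plus attribute `fs`.
#' @examples
#' tr <- inst_amp_freq(2 * cos(2 * pi * 10 * (0:999) / 250), fs = 250)
#' summary(tr$frequency[100:900])
#' @export
inst_amp_freq <- function(x, fs) {
  z <- analytic_signal(x)
  amp <- Mod(z)
  phase <- unwrap_phase(Arg(z))
  n <- length(x)
  freq <- numeric(n)
  if (n >= 3) {
    freq[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) / 2
  }
  freq[1] <- phase[2] - phase[1]
  freq[n] <- phase[n] - phase[n - 1]
  freq <- freq * fs / (2 * pi)
  freq[freq < 0] <- 0
  freq[amp == 0] <- 0
  structure(tibble::tibble(amplitude = amp, frequency = freq), fs = fs)
}
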