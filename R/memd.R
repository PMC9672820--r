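# Masking EMD: a sinusoidal mask derived from IMF1's Hilbert statistics is
# added to and subtracted from the signal; the first IMFs of the two sums are
# averaged, cancelling the mask while preventing intermittent slow content
# from mixing into the fast mode.

#' Masking-signal parameters from a Hilbert trace
#'
#' The mask amplitude is `a_z = (coef / N) * sum(a(i))` with `coef = 1.6`,
#' and the mask frequency is the amplitude-weighted mean instantaneous
#' frequency `f_z = sum(a * f^2) / sum(a * f)`. Zero-amplitude samples carry
#' zero weight. An all-zero amplitude trace yields `a_z = 0` (the
#' decomposition then degrades gracefully to plain EMD).
#'
#' @param trace A tibble with columns `amplitude` and `frequency`, as
#'   returned by [inst_amp_freq()].
#' @param coef Leading amplitude coefficient (default 1.6).
#' @return List with numeric scalars `a_z` and `f_z`.
#' @examples
#' masking_params(tibble::tibble(amplitude = rep(1, 100),
#'                               frequency = rep(10, 100)))
#' @export
masking_params <- function(trace, coef = 1.6) {
  a <- trace$amplitude
  f <- trace$frequency
  if (length(a) == 0) {
    stop_memdbci("empty Hilbert trace.", "memdbci_invalid_spec")
  }
  a_z <- coef * mean(a)
  den <- sum(a * f)
  f_z <- if (den > 0) sum(a * f^2) / den else 0
  list(a_z = a_z, f_z = f_z)
}

#' Render a sinusoidal masking signal
#'
#' `z(i) = a_z * sin(2 * pi * f_z * (i - 1) / fs + phase)`. A mask frequency
#' at or above the Nyquist is clamped to `0.45 * fs` with a warning.
#'
#' @param a_z Mask amplitude (`>= 0`).
#' @param f_z Mask frequency in Hz.
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param phase Phase offset in radians (`pi/2` gives a cosine mask).
#' @return A `mask_spec`: list with `a_z`, `f_z`, `phase`, `fs` and the
#'   rendered sequence `z`.
#' @export
build_mask <- function(a_z, f_z, n, fs, phase = 0) {
  stopifnot(a_z >= 0)
  if (f_z >= fs / 2) {
    warning("mask frequency at or above Nyquist; clamped to 0.45 * fs")
    f_z <- 0.45 * fs
  }
  z <- a_z * sin(2 * pi * f_z * (0:(n - 1)) / fs + phase)
  structure(list(a_z = a_z, f_z = f_z, phase = phase, fs = fs, z = z),
            class = "mask_spec")
}

zero_mask <- function(n, fs) build_mask(0, 0, n, fs)

#' Extract one IMF with a masking signal
#'
#' Pipeline: plain EMD extracts a provisional IMF1; its Hilbert trace gives
#' the mask parameters ([masking_params()]); the rendered mask `z` is added
#' to and subtracted from the input; the first IMFs `y+` and `y-` of
#' `x + z` and `x - z` are extracted by plain sifting; the returned IMF is
#' `y = (y+ + y-) / 2`. If `a_z` is zero the plain IMF1 is returned
#' unchanged (exact zero-mask equivalence with EMD), and if either masked
#' decomposition runs out of extrema the function falls back to the plain
#' IMF1 with a notice.
#'
#' @param x Numeric signal with at least 2 maxima and 2 minima.
#' @param fs Sampling rate in Hz.
#' @inheritParams extract_imf
#' @param phase Mask phase in radians.
#' @param coef Mask amplitude coefficient (see [masking_params()]).
#' @return List with `imf` (numeric) and `mask` (a `mask_spec`).
#' @export
memd_extract_imf <- function(x, fs, sd_tol = 0.2, max_sifts = 100,
                             phase = 0, coef = 1.6) {
  plain <- extract_imf(x, sd_tol = sd_tol, max_sifts = max_sifts)
  trace <- inst_amp_freq(plain$imf, fs)
  mp <- masking_params(trace, coef = coef)
  if (mp$a_z == 0) {
    return(list(imf = plain$imf, mask = zero_mask(length(x), fs)))
  }
  mask <- build_mask(mp$a_z, mp$f_z, length(x), fs, phase = phase)
  masked <- tryCatch({
    yp <- extract_imf(x + mask$z, sd_tol = sd_tol, max_sifts = max_sifts)
    ym <- extract_imf(x - mask$z, sd_tol = sd_tol, max_sifts = max_sifts)
    (yp$imf + ym$imf) / 2
  }, memdbci_insufficient_extrema = function(cnd) NULL)
  if (is.null(masked)) {
    message("masked decomposition ran out of extrema; falling back to plain EMD")
    return(list(imf = plain$imf, mask = zero_mask(length(x), fs)))
  }
  list(imf = masked, mask = mask)
}

#' Masking empirical mode decomposition
#'
#' Applies [memd_extract_imf()] level by level: the extracted IMF is
#' subtracted from the running residue and the mask is re-estimated from the
#' next residue's own IMF1 (set `remask_each_level = FALSE` to mask only the
#' first level and continue with plain sifting). Completeness is exact by
#' construction.
#'
#' @inheritParams emd_decompose
#' @inheritParams memd_extract_imf
#' @param remask_each_level Re-estimate the mask at every level (default) or
#'   only for the first IMF.
#' @return An `imf_set` with `method = "memd"` and a `masks` field recording
#'   `a_z` and `f_z` per level.
#' @export
memd_decompose <- function(x, fs, max_imfs = 10, sd_tol = 0.2,
                           max_sifts = 100, phase = 0, coef = 1.6,
                           remask_each_level = TRUE) {
  if (length(x) < 16) {
    stop_memdbci("signal too short to decompose (need >= 16 samples).",
                 "memdbci_too_short")
  }
  residue <- as.numeric(x)
  imfs <- list()
  masks <- list()
  while (length(imfs) < max_imfs) {
    ext <- find_extrema(residue)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) break
    if (remask_each_level || length(imfs) == 0L) {
      res <- memd_extract_imf(residue, fs, sd_tol = sd_tol,
                              max_sifts = max_sifts, phase = phase,
                              coef = coef)
      imf <- res$imf
      masks <- c(masks, list(list(a_z = res$mask$a_z, f_z = res$mask$f_z)))
    } else {
      imf <- extract_imf(residue, sd_tol = sd_tol, max_sifts = max_sifts)$imf
      masks <- c(masks, list(list(a_z = 0, f_z = 0)))
    }
    imfs <- c(imfs, list(imf))
    residue <- residue - imf
  }
  new_imf_set(imfs, residue, rep(NA_integer_, length(imfs)), fs, "memd",
              masks = masks)
}
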