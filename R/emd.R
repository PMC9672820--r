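# Classical empirical mode decomposition: extrema detection, cubic-spline
# envelopes with mirrored boundary extrema, Cauchy-criterion sifting.

#' Locate strict local extrema
#'
#' Extrema are detected by sign changes of the first difference on the
#' plateau-compressed series: runs of equal values count once, and a plateau
#' extremum is reported at its midpoint index (floor for even-length
#' plateaus).
#'
#' @param x Numeric vector, length `>= 3` (shorter input returns no extrema).
#' @return List with integer vectors `maxima` and `minima` (1-based indices).
#' @examples
#' find_extrema(c(0, 1, 1, 0))  # plateau maximum at index 2
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- as.integer(floor((starts + ends) / 2))  # plateau midpoint, floor
  v <- r$values
  m <- length(v)
  if (m < 3) return(list(maxima = integer(0), minima = integer(0)))
  interior <- 2:(m - 1)
  is_max <- v[interior] > v[interior - 1] & v[interior] > v[interior + 1]
  is_min <- v[interior] < v[interior - 1] & v[interior] < v[interior + 1]
  list(maxima = idx[interior[is_max]], minima = idx[interior[is_min]])
}

#' Upper and lower spline envelopes
#'
#' Natural cubic splines through the maxima (upper) and minima (lower),
#' extended past the signal ends by mirroring the two nearest extrema about
#' each end, then evaluated at every sample. Spline overshoot means
#' `upper >= lower` is not guaranteed pointwise and is not asserted.
#'
#' @param x Numeric vector.
#' @param maxima,minima Extrema indices, e.g. from [find_extrema()]. At least
#'   2 of each are required; otherwise an insufficient-extrema error
#'   (class `memdbci_insufficient_extrema`) signals the caller to stop
#'   sifting.
#' @return List with numeric vectors `upper` and `lower`.
#' @export
envelopes <- function(x, maxima, minima) {
  if (length(maxima) < 2 || length(minima) < 2) {
    stop_memdbci("fewer than 2 maxima or 2 minima: cannot build envelopes.",
                 "memdbci_insufficient_extrema")
  }
  n <- length(x)
  list(upper = mirrored_spline(maxima, x[maxima], n),
       lower = mirrored_spline(minima, x[minima], n))
}

# Natural cubic spline through (idx, val) knots, with the two knots nearest
# each signal end reflected about the end before fitting.
mirrored_spline <- function(idx, val, n) {
  k <- length(idx)
  left_t <- 2 - idx[c(2, 1)]
  left_v <- val[c(2, 1)]
  right_t <- 2 * n - idx[c(k, k - 1)]
  right_v <- val[c(k, k - 1)]
  t_all <- c(left_t, idx, right_t)
  v_all <- c(left_v, val, right_v)
  keep <- !duplicated(t_all)
  f <- stats::splinefun(t_all[keep], v_all[keep], method = "natural")
  f(seq_len(n))
}

#' One sifting step
#'
#' Subtracts the mean of the upper and lower envelopes:
#' `candidate = x - (upper + lower) / 2`.
#'
#' @inheritParams envelopes
#' @param x Numeric vector.
#' @return Numeric candidate of the same length.
#' @export
sift_once <- function(x) {
  ext <- find_extrema(x)
  env <- envelopes(x, ext$maxima, ext$minima)
  x - (env$upper + env$lower) / 2
}

#' Extract one intrinsic mode function by repeated sifting
#'
#' Sifting repeats until the Cauchy criterion
#' `SD = sum((h_prev - h_new)^2) / sum(h_prev^2) < sd_tol`
#' is met or `max_sifts` is reached.
#'
#' @param x Numeric vector with at least 2 maxima and 2 minima.
#' @param sd_tol Cauchy stopping tolerance (classic default 0.2).
#' @param max_sifts Maximum sifting iterations; `0` returns the input
#'   unchanged.
#' @return List with `imf` (numeric) and `n_sifts` (integer).
#' @export
extract_imf <- function(x, sd_tol = 0.2, max_sifts = 100) {
  h <- x
  n_sifts <- 0L
  while (n_sifts < max_sifts) {
    h_new <- if (n_sifts == 0L) {
      sift_once(h)  # insufficient extrema on the raw input propagates
    } else {
      tryCatch(sift_once(h), memdbci_insufficient_extrema = function(cnd) NULL)
    }
    if (is.null(h_new)) break  # candidate no longer siftable; keep it
    denom <- sum(h^2)
    sd_crit <- if (denom == 0) 0 else sum((h - h_new)^2) / denom
    h <- h_new
    n_sifts <- n_sifts + 1L
    if (sd_crit < sd_tol) break
  }
  list(imf = h, n_sifts = n_sifts)
}

new_imf_set <- function(imfs, residue, sift_counts, fs, method,
                        masks = NULL) {
  imfs <- if (length(imfs)) {
    matrix(unlist(imfs), nrow = length(residue), ncol = length(imfs),
           dimnames = list(NULL, paste0("imf", seq_along(imfs))))
  } else {
    matrix(numeric(0), nrow = length(residue), ncol = 0)
  }
  structure(list(imfs = imfs, residue = residue,
                 sift_counts = as.integer(sift_counts), fs = fs,
                 method = method, masks = masks),
            class = "imf_set")
}

#' Empirical mode decomposition
#'
#' Iteratively extracts IMFs from successive residues until the residue has
#' fewer than 2 maxima or 2 minima (e.g. it is monotone) or `max_imfs` is
#' reached. Completeness is exact by construction: the IMFs and the residue
#' sum back to the input (telescoping).
#'
#' @param x Numeric signal, length `>= 16`.
#' @param fs Sampling rate in Hz (carried for downstream Hilbert analysis).
#' @param max_imfs Maximum number of IMFs.
#' @inheritParams extract_imf
#' @return An `imf_set`: list with `imfs` (samples x K matrix, possibly zero
#'   columns), `residue`, `sift_counts`, `fs`, `method`.
#' @examples
#' x <- gen_signal(list(comp_tone(1, 10), comp_tone(1, 1)), 2500, 250)
#' dec <- emd_decompose(x, fs = 250)
#' ncol(dec$imfs)
#' @export
emd_decompose <- function(x, fs, max_imfs = 10, sd_tol = 0.2,
                          max_sifts = 100) {
  if (length(x) < 16) {
    stop_memdbci("signal too short to decompose (need >= 16 samples).",
                 "memdbci_too_short")
  }
  residue <- as.numeric(x)
  imfs <- list()
  counts <- integer(0)
  while (length(imfs) < max_imfs) {
    ext <- find_extrema(residue)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) break
    res <- extract_imf(residue, sd_tol = sd_tol, max_sifts = max_sifts)
    imfs <- c(imfs, list(res$imf))
    counts <- c(counts, res$n_sifts)
    residue <- residue - res$imf
  }
  new_imf_set(imfs, residue, counts, fs, "emd")
}

#' @export
print.imf_set <- function(x, ...) {
  cat("<imf_set> ", ncol(x$imfs), " IMF(s) + residue, ",
      length(x$residue), " samples @ ", x$fs, " Hz [", x$method, "]\n",
      sep = "")
  invisible(x)
}

#' @describeIn emd_decompose Long-format view of a decomposition: one row per
#'   sample per series (`imf1`, ..., `residue`), columns `series`, `time`,
#'   `value`.
#' @param object,... An `imf_set` and ignored extra arguments.
#' @export
tidy.imf_set <- function(object, ...) {
  n <- length(object$residue)
  wide <- tibble::as_tibble(cbind(object$imfs, residue = object$residue))
  wide$time <- (seq_len(n) - 1) / object$fs
  out <- tidyr::pivot_longer(wide, -"time", names_to = "series",
                             values_to = "value")
  out$series <- factor(out$series,
                       levels = c(colnames(object$imfs), "residue"))
  dplyr::arrange(out, .data$series, .data$time)
}

#' Plot an empirical mode decomposition
#'
#' One facet per IMF plus the residue, amplitude against time.
#'
#' @param object An `imf_set`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.imf_set <- function(object, ...) {
  ggplot2::ggplot(tidy.imf_set(object),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "amplitude",
                  title = paste0(toupper(object$method), " decomposition"))
}
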