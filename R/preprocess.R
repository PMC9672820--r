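# Min-max normalization of signals into a target range.

#' Min-max normalization
#'
#' Affinely rescales a sequence so that its observed minimum and maximum map
#' exactly onto `y_min` and `y_max`:
#' `z_i = (y_max - y_min) * (x_i - min(x)) / (max(x) - min(x)) + y_min`.
#' The default range is `[-1, +1]`. The map is monotone, so sample order is
#' preserved, and it is idempotent on already-normalized input.
#'
#' @param x Numeric vector with at least 2 samples.
#' @param y_min,y_max Target range bounds (`y_max > y_min`).
#' @param on_constant What to do when `max(x) == min(x)` (zero denominator):
#'   `"error"` (default) raises a degenerate-range error; `"zero"` returns an
#'   all-zero vector of the same length.
#'
#' @return Numeric vector of the same length as `x`.
#' @examples
#' minmax_normalize(c(1, 2, 3))        # -1 0 1
#' minmax_normalize(c(0, 5, 10, 2.5))  # -1 0 1 -0.5
#' @export
minmax_normalize <- function(x, y_min = -1, y_max = 1,
                             on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  if (length(x) < 2) {
    stop_memdbci("`x` must have at least 2 samples.", "memdbci_too_short")
  }
  if (y_max <= y_min) {
    stop_memdbci("`y_max` must exceed `y_min`.", "memdbci_invalid_spec")
  }
  x_min <- min(x)
  x_max <- max(x)
  if (x_max == x_min) {
    if (on_constant == "zero") return(numeric(length(x)))
    stop_memdbci("constant input: min(x) == max(x), normalization range degenerate.",
                 "memdbci_degenerate_range")
  }
  (y_max - y_min) * (x - x_min) / (x_max - x_min) + y_min
}

#' Audit record of a normalization
#'
#' @param x Input vector.
#' @inheritParams minmax_normalize
#' @return One-row tibble with `y_min`, `y_max` and the observed input
#'   extremes `x_min`, `x_max`.
#' @export
normalization_spec <- function(x, y_min = -1, y_max = 1) {
  tibble::tibble(y_min = y_min, y_max = y_max, x_min = min(x), x_max = max(x))
}

#' Normalize every channel of every trial in a trial set
#'
#' @param trials A `trial_set` (see [gen_mi_trials()]).
#' @param scope `"trial"` rescales each channel within each trial (the
#'   default; avoids inter-trial leakage), `"recording"` uses each channel's
#'   extremes pooled over all trials, `"off"` returns the input unchanged.
#' @inheritParams minmax_normalize
#' @return A `trial_set` with rescaled trials. Constant channels fall back to
#'   all zeros with a warning.
#' @export
normalize_trials <- function(trials, scope = c("trial", "recording", "off"),
                             y_min = -1, y_max = 1) {
  scope <- match.arg(scope)
  if (scope == "off") return(trials)
  stopifnot(inherits(trials, "trial_set"))
  norm_row <- function(row, lo, hi) {
    if (hi == lo) {
      warning("constant channel rescaled to all zeros")
      return(numeric(length(row)))
    }
    (y_max - y_min) * (row - lo) / (hi - lo) + y_min
  }
  if (scope == "trial") {
    trials$trials <- lapply(trials$trials, function(tr) {
      t(apply(tr, 1, function(row) norm_row(row, min(row), max(row))))
    })
  } else {
    n_ch <- nrow(trials$trials[[1]])
    lo <- vapply(seq_len(n_ch), function(ch) {
      min(vapply(trials$trials, function(tr) min(tr[ch, ]), numeric(1)))
    }, numeric(1))
    hi <- vapply(seq_len(n_ch), function(ch) {
      max(vapply(trials$trials, function(tr) max(tr[ch, ]), numeric(1)))
    }, numeric(1))
    trials$trials <- lapply(trials$trials, function(tr) {
      t(vapply(seq_len(nrow(tr)), function(ch) {
        norm_row(tr[ch, ], lo[ch], hi[ch])
      }, numeric(ncol(tr))))
    })
  }
  trials$meta$normalization <- list(scope = scope, y_min = y_min, y_max = y_max)
  trials
}
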