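# Per-IMF feature families: energy, morphological areas, fuzzy approximate
# entropy, autoregressive coefficients.

#' Signal energy
#'
#' Sum of squared samples, `E = sum(x^2)`.
#'
#' @param x Numeric vector (nonempty).
#' @return Scalar energy.
#' @export
energy <- function(x) {
  stopifnot(length(x) >= 1)
  sum(x^2)
}

#' Morphological area features
#'
#' Five amplitude-domain descriptors of a signal:
#' * `aa` — absolute area, `max(|x|)` by default (the literal definition
#'   used here; set `aa_as_area = TRUE` for `sum(|x|)` if you read the name
#'   as a genuine area),
#' * `pa` — positive area, `sum(0.5 * (x + |x|))`,
#' * `na` — negative area, `sum(0.5 * (x - |x|))` (nonpositive),
#' * `tt` — total area, `pa + na` (equals `sum(x)` algebraically),
#' * `taa` — total absolute area, `pa + |na|` (equals `sum(|x|)`).
#'
#' @param x Numeric vector (nonempty).
#' @param aa_as_area Use `sum(|x|)` instead of `max(|x|)` for `aa`.
#' @return Named numeric vector `c(aa, pa, na, tt, taa)`.
#' @examples
#' morphological(c(1, -2, 3))  # aa 3, pa 4, na -2, tt 2, taa 6
#' @export
morphological <- function(x, aa_as_area = FALSE) {
  stopifnot(length(x) >= 1)
  ax <- abs(x)
  pa <- sum(0.5 * (x + ax))
  na <- sum(0.5 * (x - ax))
  c(aa = if (aa_as_area) sum(ax) else max(ax),
    pa = pa, na = na, tt = pa + na, taa = pa + abs(na))
}

#' Fuzzy approximate entropy
#'
#' Regularity statistic with a fuzzy (exponential) similarity membership in
#' place of approximate entropy's hard threshold. For embedding length `m`:
#' the `N - m + 1` windows of length `m` have their window means removed;
#' `d_ij` is the Chebyshev (max-component) distance between centered
#' windows; the membership is `D_ij = exp(-d_ij^n_grad / r)`;
#' `phi_i = mean over j != i of D_ij`; `Phi^m = mean over i of log(phi_i)`;
#' and `FAP = Phi^m - Phi^(m+1)`. A constant signal returns exactly 0.
#'
#' @param x Numeric vector with `length(x) > m + 1`.
#' @param m Embedding (template) length in samples.
#' @param r Similarity tolerance; with `relative_r = TRUE` (default) it is a
#'   fraction of `sd(x)`, otherwise in the units of `x`. Must be `> 0`.
#' @param n_grad Membership gradient exponent.
#' @param relative_r Interpret `r` as a fraction of the signal's standard
#'   deviation.
#' @return Scalar fuzzy approximate entropy.
#' @examples
#' set.seed(1)
#' fuzzy_approx_entropy(rnorm(200))
#' @export
fuzzy_approx_entropy <- function(x, m = 2, r = 0.2, n_grad = 2,
                                 relative_r = TRUE) {
  N <- length(x)
  if (r <= 0) {
    stop_memdbci("`r` must be > 0.", "memdbci_invalid_spec")
  }
  if (N <= m + 1) {
    stop_memdbci("signal too short for the requested embedding length.",
                 "memdbci_too_short")
  }
  s <- sd(x)
  if (s == 0) return(0)  # all distances 0, all memberships 1, log 1 = 0
  r_abs <- if (relative_r) r * s else r
  phi_fuzzy(x, m, r_abs, n_grad) - phi_fuzzy(x, m + 1, r_abs, n_grad)
}

phi_fuzzy <- function(x, m, r_abs, n_grad) {
  N <- length(x)
  K <- N - m + 1
  w <- matrix(x[outer(seq_len(K) - 1L, seq_len(m), `+`)], nrow = K)
  w <- w - apply(w, 1, mean)  # two-pass mean: bit-stable centering
  d <- matrix(0, K, K)
  for (j in seq_len(m)) {
    d <- pmax(d, abs(outer(w[, j], w[, j], `-`)))
  }
  memb <- exp(-d^n_grad / r_abs)
  diag(memb) <- 0  # exclude self-matches without cancellation error
  phi_i <- rowSums(memb) / (K - 1)  # mean over j != i
  mean(log(phi_i))
}

#' Autoregressive coefficients by Burg's method
#'
#' Fits `x(t) = sum(a(i) * x(t - i)) + e(t)` of fixed order `p` (default 7,
#' the standard order for EEG features) by Burg's method
#' ([stats::ar.burg()]), after removing the sample mean.
#'
#' @param x Numeric vector with `length(x) > 2 * order` and non-constant.
#' @param order Model order `p >= 1`.
#' @return An `ar_model`: list with `order`, `coeffs` (length `p`, in the
#'   `x(t) = sum a(i) x(t-i) + e(t)` sign convention) and `noise_variance`.
#' @examples
#' x <- as.numeric(arima.sim(list(ar = c(0.75, -0.5)), 2000))
#' ar_coefficients(x, order = 2)$coeffs
#' @export
ar_coefficients <- function(x, order = 7) {
  stopifnot(order >= 1)
  if (length(x) <= 2 * order) {
    stop_memdbci("need more than 2 * order samples to fit the AR model.",
                 "memdbci_too_short")
  }
  if (max(x) == min(x)) {
    stop_memdbci("constant input: AR model undefined.",
                 "memdbci_degenerate_range")
  }
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  structure(list(order = order, coeffs = as.numeric(fit$ar),
                 noise_variance = fit$var.pred),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat("<ar_model> order", x$order, "\n  coeffs:",
      paste(signif(x$coeffs, 4), collapse = " "),
      "\n  innovation variance:", signif(x$noise_variance, 4), "\n")
  invisible(x)
}

#' Feature-extraction configuration
#'
#' @param method Decomposition feeding the features: `"memd"` (default),
#'   `"emd"`, or `"raw"` (features on the raw channel, one slot).
#' @param n_imfs Number of leading IMFs per channel to featurize; missing
#'   IMFs zero-pad their slots so the layout is stable.
#' @param fuzzy_m,fuzzy_r,fuzzy_n Fuzzy approximate entropy parameters
#'   (embedding length, relative tolerance, gradient exponent).
#' @param ar_order AR model order.
#' @param aa_as_area See [morphological()].
#' @param sd_tol,max_sifts Sifting controls (see [extract_imf()]).
#' @return A `feature_config` list.
#' @export
feature_config <- function(method = c("memd", "emd", "raw"), n_imfs = 3,
                           fuzzy_m = 2, fuzzy_r = 0.2, fuzzy_n = 2,
                           ar_order = 7, aa_as_area = FALSE,
                           sd_tol = 0.2, max_sifts = 100) {
  structure(list(method = match.arg(method), n_imfs = n_imfs,
                 fuzzy_m = fuzzy_m, fuzzy_r = fuzzy_r, fuzzy_n = fuzzy_n,
                 ar_order = ar_order, aa_as_area = aa_as_area,
                 sd_tol = sd_tol, max_sifts = max_sifts),
            class = "feature_config")
}

feature_slot_names <- function(ar_order) {
  c("energy", "aa", "pa", "na", "tt", "taa", "fap",
    paste0("ar", seq_len(ar_order)))
}

# all four families for one series; failures inside a family zero-fill it
slot_features <- function(h, cfg) {
  p <- cfg$ar_order
  fap <- tryCatch(
    fuzzy_approx_entropy(h, m = cfg$fuzzy_m, r = cfg$fuzzy_r,
                         n_grad = cfg$fuzzy_n),
    memdbci_error = function(cnd) 0)
  ar <- tryCatch(ar_coefficients(h, order = p)$coeffs,
                 memdbci_error = function(cnd) numeric(p))
  out <- c(energy(h), morphological(h, aa_as_area = cfg$aa_as_area), fap, ar)
  names(out) <- feature_slot_names(p)
  out
}

#' Extract the feature vector of one trial
#'
#' Each channel is decomposed (MEMD by default) and the four feature
#' families — energy, morphological areas, fuzzy approximate entropy and AR
#' coefficients — are computed on each of the first `n_imfs` IMFs, then
#' concatenated in a fixed, named order
#' (`ch<i>_imf<k>_<energy|aa|pa|na|tt|taa|fap|ar1..arp>`). Channels whose
#' decomposition fails are zero-filled with a warning, and absent IMFs
#' zero-pad their slots, so the layout is identical across trials.
#'
#' @param trial Channels x samples numeric matrix (a plain vector is treated
#'   as one channel).
#' @param fs Sampling rate in Hz.
#' @param cfg A [feature_config()].
#' @return Named numeric feature vector of length
#'   `n_channels * n_imfs * (7 + ar_order)`.
#' @examples
#' tr <- gen_mi_trials(2, 2, n_channels = 1, duration = 1, seed = 3)
#' length(extract_features(tr$trials[[1]], fs = tr$fs))
#' @export
extract_features <- function(trial, fs, cfg = feature_config()) {
  if (is.vector(trial)) trial <- matrix(trial, nrow = 1)
  stopifnot(length(trial) > 0)
  n_slot <- length(feature_slot_names(cfg$ar_order))
  per_channel <- function(ch) {
    row <- trial[ch, ]
    if (cfg$method == "raw") {
      series <- list(raw = row)
    } else {
      dec <- tryCatch({
        if (cfg$method == "memd") {
          memd_decompose(row, fs, max_imfs = cfg$n_imfs,
                         sd_tol = cfg$sd_tol, max_sifts = cfg$max_sifts)
        } else {
          emd_decompose(row, fs, max_imfs = cfg$n_imfs,
                        sd_tol = cfg$sd_tol, max_sifts = cfg$max_sifts)
        }
      }, memdbci_error = function(cnd) NULL)
      if (is.null(dec)) {
        warning(sprintf("decomposition failed on channel %d; features zero-filled", ch))
        series <- rep(list(NULL), cfg$n_imfs)
      } else {
        series <- lapply(seq_len(cfg$n_imfs), function(k) {
          if (k <= ncol(dec$imfs)) dec$imfs[, k] else NULL
        })
      }
      names(series) <- paste0("imf", seq_along(series))
    }
    vals <- lapply(names(series), function(nm) {
      h <- series[[nm]]
      v <- if (is.null(h)) {
        stats::setNames(numeric(n_slot), feature_slot_names(cfg$ar_order))
      } else {
        slot_features(h, cfg)
      }
      stats::setNames(v, paste0("ch", ch, "_", nm, "_", names(v)))
    })
    unlist(vals)
  }
  unlist(lapply(seq_len(nrow(trial)), per_channel))
}

#' Feature table for a whole trial set
#'
#' Applies [extract_features()] to every trial and binds the results into a
#' tibble with a leading `trial_id` and a trailing integer `label` column —
#' the layout consumed by [net_train()] and [run_pipeline()].
#'
#' @param trials A `trial_set` (see [gen_mi_trials()]).
#' @inheritParams extract_features
#' @return A tibble with one row per trial.
#' @export
extract_feature_table <- function(trials, cfg = feature_config()) {
  stopifnot(inherits(trials, "trial_set"))
  rows <- purrr::map(trials$trials, extract_features, fs = trials$fs,
                     cfg = cfg)
  out <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble::tibble(trial_id = seq_along(trials$trials)),
                   out,
                   tibble::tibble(label = trials$labels))
}
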