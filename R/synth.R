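# Synthetic signal and trial generation.
#
# Every downstream stage (EMD, masking EMD, Hilbert analysis, features,
# classifier) is exercised on signals built here, so each component keeps its
# ground-truth trace attached to the mixed signal for oracle comparisons.

#' Component specifications for synthetic signals
#'
#' Constructors for the building blocks of [gen_signal()]: pure tones,
#' amplitude-modulated tones, linear chirps, intermittently gated tone bursts
#' (the classic provocation for EMD mode mixing) and autoregressive background
#' noise.
#'
#' @param amplitude Peak amplitude (unitless, must be `>= 0`).
#' @param frequency Oscillation frequency in Hz; must lie below the Nyquist
#'   frequency of the signal it is rendered into.
#' @param phase Initial phase in radians. The default `0` keeps tones exactly
#'   reproducible from their closed form; pass `"random"` to draw a seeded
#'   uniform phase at render time.
#' @param mod_frequency,mod_depth Modulator frequency (Hz) and depth in
#'   `[0, 1]` for `comp_am_tone()`.
#' @param f0,f1 Start and end frequency (Hz) of the linear chirp.
#' @param burst_duty Fraction of each one-second gating window occupied by the
#'   burst, in `(0, 1]`.
#' @param ar_coeffs Autoregressive coefficients of the background-noise
#'   recursion `x[t] = sum(ar_coeffs[i] * x[t - i]) + e[t]`.
#' @param sd Standard deviation of the Gaussian innovations `e[t]`.
#'
#' @return A `component_spec` object (a tagged list understood by
#'   [gen_signal()]).
#' @seealso [gen_signal()], [gen_mi_trials()]
#' @name component_spec
NULL

new_component <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "component_spec")
}

#' @rdname component_spec
#' @export
comp_tone <- function(amplitude = 1, frequency = 10, phase = 0) {
  check_amp_freq(amplitude, frequency)
  new_component("tone", amplitude = amplitude, frequency = frequency,
                phase = phase)
}

#' @rdname component_spec
#' @export
comp_am_tone <- function(amplitude = 1, frequency = 10, mod_frequency = 1,
                         mod_depth = 0.5, phase = 0) {
  check_amp_freq(amplitude, frequency)
  stopifnot(mod_depth >= 0, mod_depth <= 1, mod_frequency > 0)
  new_component("am_tone", amplitude = amplitude, frequency = frequency,
                mod_frequency = mod_frequency, mod_depth = mod_depth,
                phase = phase)
}

#' @rdname component_spec
#' @export
comp_chirp <- function(amplitude = 1, f0 = 5, f1 = 20, phase = 0) {
  check_amp_freq(amplitude, max(f0, f1))
  new_component("chirp", amplitude = amplitude, f0 = f0, f1 = f1,
                phase = phase)
}

#' @rdname component_spec
#' @export
comp_burst <- function(amplitude = 1, frequency = 25, burst_duty = 0.25,
                       phase = 0) {
  check_amp_freq(amplitude, frequency)
  if (!(burst_duty > 0 && burst_duty <= 1)) {
    stop_memdbci("`burst_duty` must lie in (0, 1].", "memdbci_invalid_spec")
  }
  new_component("intermittent_burst", amplitude = amplitude,
                frequency = frequency, burst_duty = burst_duty, phase = phase)
}

#' @rdname component_spec
#' @export
comp_ar_noise <- function(ar_coeffs = 0.9, sd = 1) {
  stopifnot(sd >= 0, length(ar_coeffs) >= 1)
  new_component("ar_noise", ar_coeffs = as.numeric(ar_coeffs), sd = sd)
}

check_amp_freq <- function(amplitude, frequency) {
  if (amplitude < 0) {
    stop_memdbci("`amplitude` must be >= 0.", "memdbci_invalid_spec")
  }
  if (any(frequency < 0)) {
    stop_memdbci("`frequency` must be >= 0.", "memdbci_invalid_spec")
  }
  invisible(NULL)
}

# render one component; returns the per-sample trace
render_component <- function(comp, n, fs) {
  t <- (seq_len(n) - 1) / fs
  ph <- comp$phase
  if (identical(ph, "random")) ph <- runif(1, 0, 2 * pi)
  switch(comp$kind,
    tone = comp$amplitude * sin(2 * pi * comp$frequency * t + ph),
    am_tone = comp$amplitude *
      (1 + comp$mod_depth * sin(2 * pi * comp$mod_frequency * t)) *
      sin(2 * pi * comp$frequency * t + ph),
    chirp = {
      dur <- n / fs
      inst_phase <- 2 * pi * (comp$f0 * t + (comp$f1 - comp$f0) * t^2 / (2 * dur))
      comp$amplitude * sin(inst_phase + ph)
    },
    intermittent_burst = comp$amplitude *
      sin(2 * pi * comp$frequency * t + ph) * burst_gate(n, fs, comp$burst_duty),
    ar_noise = render_ar_noise(comp$ar_coeffs, comp$sd, n),
    stop_memdbci(paste0("unknown component kind: ", comp$kind),
                 "memdbci_invalid_spec")
  )
}

# Rectangular gate: one burst of length duty*window at a random offset inside
# each one-second window, with 10-sample raised-cosine edges to avoid the
# spectral splatter of a hard step.
burst_gate <- function(n, fs, duty) {
  window <- min(round(fs), n)
  gate <- numeric(n)
  starts <- seq(1L, n, by = window)
  for (s in starts) {
    w <- min(window, n - s + 1L)
    len <- max(1L, round(duty * w))
    off <- if (len >= w) 0L else sample.int(w - len + 1L, 1L) - 1L
    gate[(s + off):(s + off + len - 1L)] <- 1
  }
  smooth_edges(gate, 10L)
}

smooth_edges <- function(gate, edge) {
  d <- diff(c(0, gate, 0))
  rises <- which(d == 1)
  falls <- which(d == -1) - 1L
  ramp <- (1 - cos(pi * seq_len(edge) / (edge + 1))) / 2
  n <- length(gate)
  for (k in seq_along(rises)) {
    up <- rises[k] + seq_len(edge) - 1L
    up <- up[up <= falls[k]]
    gate[up] <- pmax(gate[up] * c(ramp, rep(1, length(up)))[seq_along(up)], 0)
    dn <- falls[k] - seq_len(edge) + 1L
    dn <- dn[dn >= rises[k]]
    gate[dn] <- gate[dn] * c(ramp, rep(1, length(dn)))[seq_along(dn)]
  }
  gate
}

# AR recursion driven by Gaussian innovations; a 10x-order burn-in is
# discarded so the startup transient never reaches the output.
render_ar_noise <- function(ar_coeffs, sd, n) {
  burn <- 10L * length(ar_coeffs)
  innov <- rnorm(n + burn, sd = sd)
  x <- stats::filter(innov, filter = ar_coeffs, method = "recursive")
  as.numeric(x)[(burn + 1L):(burn + n)]
}

#' Render a synthetic signal from component specifications
#'
#' Sums the rendered traces of a list of [component_spec] objects. The
#' per-component ground-truth traces are kept in the `"components"` attribute
#' so decomposition quality can be scored against the truth.
#'
#' @param components List of [component_spec] objects (may be empty, yielding
#'   an all-zero signal).
#' @param n Number of samples (`>= 16`).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; rendering is bit-identical for identical inputs
#'   and seed.
#'
#' @return Numeric vector of length `n` with attributes `fs`, `seed` and
#'   `components` (an `n` x `length(components)` matrix of ground-truth
#'   traces).
#' @examples
#' x <- gen_signal(list(comp_tone(1, 10)), n = 1000, fs = 250, seed = 1)
#' max(abs(x - sin(2 * pi * 10 * (0:999) / 250)))
#' @export
gen_signal <- function(components, n, fs, seed = 1L) {
  if (n < 16) {
    stop_memdbci("`n` must be at least 16 samples.", "memdbci_too_short")
  }
  freqs <- unlist(lapply(components, function(cmp) {
    c(cmp$frequency, cmp$f0, cmp$f1)
  }))
  if (any(freqs >= fs / 2)) {
    stop_memdbci("component frequencies must lie below the Nyquist (fs/2).",
                 "memdbci_invalid_spec")
  }
  traces <- withr::with_seed(seed, {
    vapply(components, render_component, numeric(n), n = n, fs = fs)
  })
  if (length(components) == 0L) {
    traces <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  x <- if (ncol(traces) > 0) rowSums(traces) else numeric(n)
  structure(x, fs = fs, seed = seed, components = traces)
}

#' Ground-truth component traces of a synthetic signal
#'
#' @param x A signal from [gen_signal()].
#' @return Matrix of per-component traces (samples x components).
#' @export
signal_components <- function(x) attr(x, "components")

#' Default class-effect table for the motor-imagery trial generator
#'
#' One row per class, giving the mu-band (~10 Hz) and beta-band (~22 Hz)
#' oscillation amplitudes. Classes take distinct high/low amplitude
#' combinations across the two bands (high 2.0, low 0.5 by default), the
#' band-power contrast that distinguishes imagined movements; with more
#' classes than combinations, intermediate amplitude levels are added.
#'
#' @param n_classes Number of classes (`>= 2`).
#' @param high,low Band amplitudes for the strong and weak condition.
#' @return A tibble with columns `class`, `mu_amp`, `beta_amp`.
#' @export
default_class_effect <- function(n_classes = 4, high = 2, low = 0.5) {
  n_levels <- max(2L, ceiling(sqrt(n_classes)))
  levels <- seq(high, low, length.out = n_levels)
  grid <- expand.grid(mu_amp = levels, beta_amp = levels)
  tibble::tibble(
    class = 0:(n_classes - 1L),
    mu_amp = grid$mu_amp[seq_len(n_classes)],
    beta_amp = grid$beta_amp[seq_len(n_classes)]
  )
}

#' Generate a labeled set of synthetic motor-imagery-like trials
#'
#' Each trial is a channels x samples matrix: class-specific mu (~10 Hz) and
#' beta (~22 Hz) tones with random phases and mild amplitude/frequency jitter,
#' superimposed on autoregressive background noise. The class-conditional
#' feature distributions differ only through the amplitudes in `class_effect`,
#' so setting identical rows yields a null (chance-level) data set.
#'
#' @param n_trials_per_class Trials generated for each class.
#' @param n_classes Number of classes (`>= 2`); labels are `0:(n_classes-1)`.
#' @param n_channels Channels per trial.
#' @param fs Sampling rate in Hz.
#' @param duration Trial length in seconds.
#' @param class_effect Tibble with one row per class and columns `mu_amp`,
#'   `beta_amp`; defaults to [default_class_effect()].
#' @param noise_ar AR coefficients of the background noise.
#' @param noise_sd Innovation standard deviation of the background noise.
#' @param mu_freq,beta_freq Band center frequencies in Hz; each trial jitters
#'   them by up to +/- 0.5 Hz.
#' @param seed Integer seed; regeneration is bit-identical.
#'
#' @return A `trial_set`: list with `trials` (list of matrices), `labels`
#'   (integer vector, class-major order), `fs` and `meta` (generator
#'   parameters including the seed).
#' @examples
#' ts <- gen_mi_trials(n_trials_per_class = 2, n_classes = 2,
#'                     n_channels = 1, duration = 1, seed = 7)
#' table(ts$labels)
#' @export
gen_mi_trials <- function(n_trials_per_class = 25, n_classes = 4,
                          n_channels = 3, fs = 250, duration = 2,
                          class_effect = NULL, noise_ar = 0.9,
                          noise_sd = 0.3, mu_freq = 10, beta_freq = 22,
                          seed = 1L) {
  if (n_classes < 2) {
    stop_memdbci("`n_classes` must be >= 2.", "memdbci_invalid_spec")
  }
  if (is.null(class_effect)) class_effect <- default_class_effect(n_classes)
  if (nrow(class_effect) != n_classes) {
    stop_memdbci("`class_effect` must have one row per class.",
                 "memdbci_invalid_spec")
  }
  n <- round(duration * fs)
  labels <- rep(0:(n_classes - 1L), each = n_trials_per_class)
  trials <- withr::with_seed(seed, lapply(labels, function(cl) {
    eff <- class_effect[cl + 1L, ]
    f_mu <- mu_freq + runif(1, -0.5, 0.5)
    f_beta <- beta_freq + runif(1, -0.5, 0.5)
    trial <- matrix(0, nrow = n_channels, ncol = n)
    for (ch in seq_len(n_channels)) {
      a_mu <- max(0, eff$mu_amp * (1 + 0.05 * rnorm(1)))
      a_beta <- max(0, eff$beta_amp * (1 + 0.05 * rnorm(1)))
      trial[ch, ] <-
        a_mu * sin(2 * pi * f_mu * (0:(n - 1)) / fs + runif(1, 0, 2 * pi)) +
        a_beta * sin(2 * pi * f_beta * (0:(n - 1)) / fs + runif(1, 0, 2 * pi)) +
        render_ar_noise(noise_ar, noise_sd, n)
    }
    trial
  }))
  structure(
    list(trials = trials, labels = as.integer(labels), fs = fs,
         meta = list(n_trials_per_class = n_trials_per_class,
                     n_classes = n_classes, n_channels = n_channels,
                     fs = fs, duration = duration,
                     class_effect = class_effect, noise_ar = noise_ar,
                     noise_sd = noise_sd, mu_freq = mu_freq,
                     beta_freq = beta_freq, seed = seed)),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set> ", length(x$trials), " trials, ",
      x$meta$n_classes, " classes, ",
      nrow(x$trials[[1]]), " channel(s) x ", ncol(x$trials[[1]]),
      " samples @ ", x$fs, " Hz\n", sep = "")
  print(table(label = x$labels))
  invisible(x)
}
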