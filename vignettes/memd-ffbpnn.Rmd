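---
title: "Masking EMD and backpropagation networks for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masking EMD and backpropagation networks for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(memdbci)
```

## The problem

Motor imagery — imagining a movement without performing it — modulates the
power of the sensorimotor mu (~8–12 Hz) and beta (~18–26 Hz) EEG rhythms.
A brain–computer interface decodes which movement was imagined from these
band-power changes. `memdbci` implements one complete decoding pipeline:

1. **min–max normalization** of each channel into $[-1, +1]$,
2. **masking empirical mode decomposition (MEMD)** into intrinsic mode
   functions (IMFs),
3. **per-IMF features**: energy, morphological areas, fuzzy approximate
   entropy and autoregressive (AR) coefficients,
4. **a feed-forward neural network trained by backpropagation (FFBPNN)**,
   written from first principles,
5. **evaluation** by stratified held-out classification and a confusion
   matrix.

Because real motor-imagery recordings are large external downloads, the
package ships a seeded synthetic trial generator that emulates the
class-dependent band oscillations the method is designed to detect; every
stage of the pipeline is tested against it.

## Empirical mode decomposition and its mode-mixing problem

EMD decomposes a signal $x(n)$ into a small set of AM–FM components (IMFs)
by *sifting*: local maxima and minima are interpolated by natural cubic
splines, and the mean of the two envelopes is subtracted until the result
has an approximately zero local mean. Each extracted IMF is subtracted from
the running residue and the process repeats, so

$$x(n) = \sum_k \mathrm{IMF}_k(n) + r(n)$$

holds *exactly* (telescoping), for any stopping parameters — the package
asserts reconstruction to $10^{-10}$ relative error on every fixture.

Numerical choices, all exposed as arguments:

* **Envelope splines**: natural cubic splines; the two extrema nearest each
  signal end are mirrored about the end before fitting, the least-artifact
  common boundary treatment. Spline overshoot means the upper envelope is
  not pointwise above the lower one, and no such assertion is made.
* **Stopping**: the Cauchy criterion
  $SD = \sum (h_{prev} - h_{new})^2 / \sum h_{prev}^2 < 0.2$, capped at 100
  sifts — the classic defaults.
* **Termination**: decomposition stops when the residue has fewer than two
  maxima or two minima, or after `max_imfs` (default 10) IMFs.
* **Plateaus** count as a single extremum at their midpoint (floor index).

EMD's known failure mode is *mode mixing*: when a fast oscillation is
intermittent (present only in bursts), the first IMF alternates between the
fast scale inside bursts and the slow scale outside them, destroying the
physical interpretability of both.

## The masking signal

MEMD mitigates mode mixing with a data-driven sinusoidal mask. From the
Hilbert analytic signal of the provisional first IMF we take per-sample
instantaneous amplitude $a(i)$ and frequency $f(i)$, and set

$$a_z = \frac{1.6}{N} \sum_{i=1}^{N} a(i), \qquad
  f_z = \frac{\sum_i a(i)\, f(i)^2}{\sum_i a(i)\, f(i)},$$

the amplitude-weighted mean instantaneous frequency — the standard
masking-frequency estimator: weighting by $a f$ concentrates the estimate
on the samples that actually carry fast oscillatory energy, so $f_z$ lands
near the burst frequency rather than the global average. The mask
$z(n) = a_z \sin(2\pi f_z n / f_s)$ is added to and subtracted from the
signal; the first IMFs $y^+$ and $y^-$ of $x + z$ and $x - z$ are extracted
by plain sifting and averaged:

$$y(n) = \tfrac{1}{2}\left(y^+(n) + y^-(n)\right).$$

The mask keeps the fast scale continuously "occupied", so the slow content
cannot leak into IMF1 during burst gaps; averaging the $\pm$ runs cancels
the mask itself ($z$ and $-z$ are equal and opposite). Two package
invariants pin this down: with $a_z = 0$ MEMD is *bit-identical* to plain
EMD, and the spectrum of $y$ carries no peak at $f_z$ beyond the input's
own content.

Design choices where the construction is genuinely open:

* **Mask waveform**: a zero-phase sine; the phase is an argument
  (`phase = pi/2` gives a cosine mask).
* **The 1.6 amplitude coefficient** is treated as a fixed constant
  (`coef` argument); the package does not try to optimize it.
* **Recursion**: the mask is re-estimated at every level from the current
  residue's own first IMF (`remask_each_level = FALSE` restricts masking to
  the first level, the minimal variant).
* **Only the first IMFs** of the $\pm$ decompositions are averaged at each
  level; deeper IMFs come from the recursion, not from pairing whole IMF
  sets, which would misalign modes.
* **Degenerate traces**: an all-zero amplitude trace yields $a_z = 0$ and
  the decomposition degrades gracefully to plain EMD; a mask frequency at
  or above Nyquist is clamped to $0.45\, f_s$ with a warning.

Instantaneous frequency is the unwrapped-phase central difference scaled to
Hz; negative values (which occur only at low-amplitude samples) are clamped
to zero, and exactly zero-amplitude samples report zero frequency, so the
amplitude-weighted sums above never hit 0/0. Tolerance checks in the tests
evaluate the *interior* 80% of samples, excluding boundary Gibbs effects.

## Feature families

For each channel, the first $K = 3$ IMFs (configurable) are featurized;
channels whose decomposition fails are zero-filled with a warning, and
absent IMFs zero-pad their slots, so the feature layout is identical across
trials. Per IMF $h$:

* **Energy** $E = \sum_n h(n)^2$.
* **Morphological areas**: `aa` $= \max |h|$ (the literal definition used
  here; `aa_as_area = TRUE` switches to $\sum |h|$ for users who want a
  genuine area), `pa` $= \sum \frac{1}{2}(h + |h|)$,
  `na` $= \sum \frac{1}{2}(h - |h|)$, `tt` $=$ `pa` $+$ `na` and
  `taa` $=$ `pa` $+ |$`na`$|$ — algebraically $\sum h$ and $\sum |h|$,
  asserted exactly in the tests.
* **Fuzzy approximate entropy** with embedding length $m = 2$, gradient
  exponent $n = 2$ and tolerance $r = 0.2\,\mathrm{SD}(h)$: windows of
  length $m$ are mean-centered; the Chebyshev distance $d_{ij}$ between
  windows enters an exponential membership $D_{ij} = e^{-d_{ij}^n / r}$;
  $\phi_i^m$ is the mean membership over $j \ne i$,
  $\Phi^m = \overline{\ln \phi_i^m}$, and
  $\mathrm{FAP} = \Phi^m - \Phi^{m+1}$. A constant signal gives exactly 0.
  The implementation is vectorized but verified against an explicit
  double-loop oracle to $10^{-12}$; self-matches are excluded by zeroing
  the membership diagonal rather than subtracting 1 from the row sum,
  which would cancel catastrophically when off-diagonal memberships are
  tiny.
* **AR coefficients** of order $p = 7$ (the standard order for EEG) in the
  convention $X(t) = \sum_{i=1}^{p} a(i) X(t-i) + e(t)$, estimated by
  Burg's method via `stats::ar.burg()` — stable on short EEG segments and
  recovered to $\pm 0.03$ on simulated AR(2) processes at $n = 20\,000$ in
  the acceptance tests.

Features are computed **per IMF** rather than on the raw channel (a
`method = "raw"` mode exists) because the decomposition is what isolates
the band-limited rhythms the features are meant to describe.

## The classifier

The network is a fully connected feed-forward net (default one hidden
layer of 10 `tansig` units) with the textbook recursions

$$a^{k+1} = f^{k+1}(W^{k+1} a^k + b^{k+1}),$$
$$s^L = -2\,\dot F^L(x^L)(t - a^L), \qquad
  s^k = \dot F^k(x^k)\,(W^{k+1})^{\mathsf T} s^{k+1},$$
$$W^k \leftarrow W^k - \alpha\, s^k (a^{k-1})^{\mathsf T}, \qquad
  b^k \leftarrow b^k - \alpha\, s^k.$$

Training is full-batch: each epoch applies the *mean* of the per-sample
steepest-descent steps, which keeps the effective step size independent of
the sample count and makes training deterministic under the weight-init
seed (an `"online"` per-sample mode is available). The epoch MSE — mean
over samples and output units of the squared error, consistent with the
$-2$ factor in $s^L$ — is checked against `error_goal` *before* the
update, so a returned `final_mse` always describes the returned weights.
Non-finite MSE raises a divergence error naming the epoch. The
backpropagated gradient is verified against central finite differences to
$10^{-5}$ (norm-relative) across architectures and all transfer-function
combinations.

Targets are one-hot in $\{-1, +1\}$ to match the `tansig` output range;
classification takes the argmax output unit, ties to the lowest index.

## The pipeline and its evaluation protocol

`run_pipeline()` chains normalize → decompose → featurize → split → train →
classify. Two choices deserve emphasis:

* **Stratified 70/30 split**, seeded; per-class proportions are preserved
  within one trial. All randomness flows from the single `seed` in
  `pipeline_config()`, from which the split and weight-init seeds are
  derived, so a report is exactly reproducible.
* **Feature standardization** (z-score using training-set statistics,
  applied to both splits) sits between feature extraction and training, on
  by default. Raw energies span orders of magnitude across IMFs and plain
  steepest descent cannot train on such inputs; the statistics are computed
  on the training split only, so no test information leaks. Set
  `scale_features = FALSE` to disable.

## What the synthetic generator does and does not emulate

`gen_mi_trials()` builds each trial as class-specific mu (~10 Hz) and beta
(~22 Hz) tones — random phases, 5% amplitude jitter, ±0.5 Hz frequency
jitter — over AR(1) background noise (coefficient 0.9, innovation SD 0.3),
generated through the AR recursion with a 10×-order burn-in. The default
class effect assigns each class a distinct high/low (2.0/0.5) amplitude
combination across the two bands, a strong, cleanly separable contrast;
`mu_amp = beta_amp = 1` for all classes gives an exact null. Defaults are
4 classes × 25 trials, 3 channels, 2 s at 250 Hz — small enough that the
full pipeline runs in well under a minute, large enough that held-out
evaluation is meaningful. Intermittent rectangular-gated bursts (with
10-sample raised-cosine edges, avoiding spline-envelope ringing unrelated
to mode mixing) reproduce the intermittency that provokes mode mixing, and
every generated component keeps its ground-truth trace attached for oracle
scoring.

The generator deliberately does **not** model volume conduction, electrode
geometry, EOG/EMG artifacts, nonstationary band-power drift or 1/f spectra.
Passing tests therefore demonstrate that the pipeline recovers
band-amplitude class structure under realistic noise and intermittency —
not that it attains any particular accuracy on real recordings.

```{r pipeline, eval = FALSE}
trials <- gen_mi_trials(seed = 42)
report <- run_pipeline(trials, pipeline_config(seed = 11))
report
autoplot(report$confusion)
```

## Known limitations

* Sifting is $O(\text{sifts} \times n \log n)$ per IMF; minute-long
  high-rate recordings decompose slowly in pure R.
* The Hilbert instantaneous frequency is reliable only for near-monocomponent
  inputs — which IMFs are by construction, but a failed decomposition
  propagates into a poorly placed mask (mitigated by the zero-mask
  fallback).
* Steepest descent with a fixed learning rate has no convergence guarantee;
  the XOR fixture documents that the error after 500 epochs is below the
  first epoch's, not that it decreases monotonically.
* The masking construction assumes a single dominant fast scale per level;
  multi-mask ensembles are out of scope.
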