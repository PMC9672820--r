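# memdbci

Masking empirical mode decomposition and a from-scratch backpropagation
neural network for motor-imagery EEG classification.

## What it is for

Motor imagery — imagining a hand or foot movement — modulates the power of
the sensorimotor mu (~8–12 Hz) and beta (~18–26 Hz) EEG rhythms, and a
brain–computer interface (BCI) decodes the imagined movement from those
band-power changes. `memdbci` implements a complete decoding pipeline for
researchers who want an inspectable, fully tested reference implementation
rather than a black box:

* **min–max normalization** of each channel into [−1, +1]:
  `z_i = (y_max − y_min)(x_i − x_min)/(x_max − x_min) + y_min`;
* **empirical mode decomposition (EMD)**: cubic-spline envelope sifting
  into intrinsic mode functions (IMFs), with exact reconstruction
  `x = Σ IMF_k + residue`;
* **masking EMD (MEMD)**, the core method: from the Hilbert trace of the
  provisional first IMF it builds a sinusoidal mask with amplitude
  `a_z = 1.6 · mean(a(i))` and frequency
  `f_z = Σ a·f² / Σ a·f` (the amplitude-weighted mean instantaneous
  frequency), decomposes `x + z` and `x − z`, and averages the two first
  IMFs: `y = (y⁺ + y⁻)/2`. The mask keeps the fast scale occupied, so
  intermittent bursts no longer mix scales within one IMF, and the
  averaging cancels the mask exactly;
* **per-IMF features**: energy, morphological areas, fuzzy approximate
  entropy, and order-7 Burg autoregressive coefficients;
* **a feed-forward backpropagation network (FFBPNN)** with the textbook
  sensitivity recursions (`s^L = −2 Ḟ(x^L)(t − a)`,
  `s^k = Ḟ(x^k) Wᵀ s^{k+1}`, `W ← W − α s aᵀ`), verified against finite
  differences;
* **evaluation**: seeded stratified split, confusion matrix, accuracy and
  error rate.

A seeded synthetic trial generator (`gen_mi_trials()`) emulates
class-dependent mu/beta oscillations over autoregressive noise so the whole
pipeline is testable without any external recordings.

## Worked example

Mode-mixing rescue on an intermittency fixture — a continuous 2 Hz tone
with 25 Hz bursts (25% duty):

```r
library(memdbci)

x <- gen_signal(list(comp_tone(1, 2), comp_burst(0.4, 25, 0.25)),
                n = 2000, fs = 250, seed = 6)
burst  <- signal_components(x)[, 2]          # ground-truth burst trace
plain  <- emd_decompose(as.numeric(x),  fs = 250, max_imfs = 1)
masked <- memd_decompose(as.numeric(x), fs = 250, max_imfs = 1)
cor(plain$imfs[, 1],  burst)   # 0.220  <- mode-mixed IMF1
cor(masked$imfs[, 1], burst)   # 0.966  <- masked IMF1 isolates the bursts
masked$masks[[1]]              # a_z = 0.86, f_z = 19.07 Hz
```

Plain EMD's first IMF correlates with the true burst component at only
0.22 because it alternates between the 25 Hz bursts and the 2 Hz tone;
the estimated mask (0.86 amplitude, 19 Hz — between the two scales, near
the burst band) lifts that to 0.97.

End-to-end classification on synthetic 4-class trials:

```r
trials <- gen_mi_trials(seed = 42)   # 4 classes x 25 trials, 3 channels, 2 s @ 250 Hz
report <- run_pipeline(trials, pipeline_config(seed = 11))
report
#> <pipeline_report>
#>   method: memd | normalization: trial | IMFs/channel: 3
#>   train/test: 72 / 28 | epochs: 148 | final MSE: 0.009959
#>   held-out accuracy: 1 | error rate: 0
```

The 28 held-out trials are classified perfectly because the default class
effect is a strong high/low (2.0/0.5) band-amplitude contrast; with
identical class effects the same pipeline stays at chance (~0.25), which
the test suite checks with a binomial confidence interval. `glance()`,
`tidy()` and `autoplot()` work on reports, fitted networks, confusion
matrices and decompositions.

A thin command-line wrapper over these functions is installed at
`inst/scripts/memdbci` with subcommands `simulate`, `decompose`, `extract`,
`train` and `evaluate` (delimited text trials in, JSON reports out).

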