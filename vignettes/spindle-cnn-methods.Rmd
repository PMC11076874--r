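---
title: "Methods: sleep spindle classification with a 1D CNN and transfer learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep spindle classification with a 1D CNN and transfer learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sleep spindles are bursts of 11–16 Hz (sigma-band) EEG activity lasting
roughly 0.5–2 s, the hallmark grapheme of NREM stage-2 sleep. Annotating
them by hand across a full night of polysomnography is expensive, and their
morphology shifts across populations: in insomnia patients spindles tend to
be shorter, with a different amplitude distribution and a smaller
sigma-band energy footprint. `spindlecnn` implements a supervised
classifier for pre-segmented 3 s windows — spindle vs. non-spindle — and a
transfer-learning protocol for adapting a classifier trained on one cohort
to a domain-shifted cohort.

Clinical spindle datasets are rarely public, so the package ships a
synthetic polysomnography generator that reproduces the *structure* of such
data (sigma-band bursts on 1/f background, annotation tables, two cohort
regimes). All training and evaluation code runs identically on real
recordings read from EDF or CSV.

## Pipeline and model

1. **Preprocessing** (`preprocess_recording()`): polyphase downsampling to
   100 Hz, a zero-phase Hamming-window FIR band-pass of 0.3–30 Hz, then
   per-channel z-scoring over the whole recording.
2. **Windowing** (`build_window_set()`): one positive window per annotated
   spindle, 3 s centred on the event midpoint; an equal number of 3 s
   negatives sampled from unannotated stretches of the same subject and
   channel, so classes are balanced per (subject, channel).
3. **Classifier** (`spindle_cnn()`): a 1D CNN of five blocks
   (convolution, stride 1, "same" padding → batch normalization → ReLU),
   average pooling of size 2 after blocks 2 and 4, then a fully-connected
   head (hidden ReLU layer of width 64, 2-unit softmax output). Default
   channels are (16, 16, 32, 32, 64) with kernels (7, 7, 5, 5, 3), so a
   300-sample window reaches the head at 75 positions and the temporal
   downsampling factor is exactly 4.
4. **Training**: softmax cross-entropy with an AdamW optimizer (decoupled
   weight decay 0.01 on convolution and dense weights only). The learning
   rate at 0-based epoch $e$ is $\mathrm{lr}_0 \times 0.75^{\lfloor e/3
   \rfloor}$; defaults are 100 epochs, batch size 128, $\mathrm{lr}_0 =
   0.1$.
5. **Evaluation** (`cross_validate()`): subject-grouped five-fold
   cross-validation reporting accuracy, recall, precision, F1 (all from the
   confusion counts at the 0.5/argmax threshold) and AUC (Mann–Whitney rank
   statistic on the spindle-class probability, ties counted ½), as per-fold
   rows plus mean (standard deviation).
6. **Transfer** (`transfer_model()` / `finetune()`): either all five conv
   blocks (`"all_conv"`) or the first four (`"first_four"`) are copied —
   including batch-norm scale/shift *and running statistics* — into a fresh
   model; the rest is re-initialized. With `freeze_transferred = TRUE`
   (default) the copied blocks receive no gradient updates and their
   batch-norm statistics are not adapted, so they stay bitwise identical
   through fine-tuning.

The network, its backpropagation and the AdamW optimizer are implemented in
the package (the minibatch forward/backward pass is compiled C++ using
im2col + BLAS matrix multiplication); training is deterministic given the
seed and data.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `target_fs_hz` | 100 | Hz | downsampling rate; all window geometry assumes it |
| `band_hz` | (0.3, 30) | Hz | band-pass edges (−6 dB points of the design) |
| `transition_bw_hz` | (0.3, 5) | Hz | FIR transition widths; see below |
| `window_s` | 3 | s | window length: spindle midpoint ± 1.5 s |
| `guard_s` | 0.5 | s | exclusion margin around events for negatives |
| `epochs`, `batch_size` | 100, 128 | — | literature defaults |
| `lr0`, decay | 0.1, ×0.75 / 3 epochs | — | literature default; see below |
| `weight_decay` | 0.01 | — | AdamW decoupled decay (unstated upstream; standard value) |

**FIR design.** The band-pass is built as the difference of two
Hamming-windowed-sinc low-pass filters, one per edge, each with length
$\lceil 3.3 / (\Delta f / f_s) \rceil$ (forced odd) from its own transition
width $\Delta f$ — the classic Hamming design rule. The −6 dB points sit at
the edges. The low-side transition defaults to 0.3 Hz. For the high side,
the common rule of 25 % of the edge frequency (7.5 Hz at 30 Hz) lets the
transition roll-off intrude into the analysis band: the measured response is
about −1.07 dB at 28 Hz, violating the package's own passband contract of
±1 dB over 1–28 Hz. The default is therefore capped at 5 Hz
(−0.24 dB at 28 Hz, stopband ≥ 40 dB by 35 Hz, filter length still set by
the 0.3 Hz low side: 1101 taps at 100 Hz). Filtering is applied forward
with the linear-phase group delay compensated by trimming, so event
midpoints keep their alignment; samples beyond the record ends are treated
as zero.

**Resampling** is polyphase FIR interpolation at the rational rate ratio
(25/256 for 1024→100 Hz) with a Hamming-windowed anti-alias filter at the
output Nyquist and exact group-delay compensation; a resampled 5 Hz tone
correlates ≥ 0.999 with its closed form on the new grid. Only the outputs
actually needed are computed (one subfilter dot product per output sample).

**z-score scope.** Whether normalization should happen per recording or per
extracted window is genuinely open; the package normalizes each channel
over the whole recording at preprocessing time (the default), which keeps
relative within-recording amplitude structure intact, and offers
`zscore_scope = "per_window"` as an option applied at window building.

**Learning rate.** $\mathrm{lr}_0 = 0.1$ with AdamW is aggressive; it is
kept as the schedule's default for fidelity, the trainer aborts with a
diagnostic if the loss becomes non-finite, and 0.001–0.003 is the
documented safe range. All bundled experiments train with
$\mathrm{lr}_0 = 0.003$.

**Fold grouping.** "Cross-subject training and testing" is interpreted as
subject-grouped folds: the subject set is partitioned, so no subject
contributes windows to both sides of a fold. Window-level folds
(`grouping = "by_window"`) are available for comparison.

## What the generator emulates — and what it does not

`simulate_recording()` produces per-channel $1/f^\beta$ background noise
(FFT magnitude shaping of white Gaussian noise, $\beta = 1$, RMS 10 µV by
default) plus Poisson-placed spindle events (default 3 per minute, minimum
gap 2 s, placement by rejection): each event is a sinusoid with frequency
uniform in the regime's range, Hann envelope, peak amplitude and duration
uniform in the regime's ranges. Two regimes are bundled:

* **normal** — 11–16 Hz, 0.8–1.5 s, peak 20–30 µV, symmetric about zero;
* **insomnia** — 11–16 Hz, 0.4–0.8 s, peak 25–50 µV, plus an
  envelope-scaled baseline offset drawn from 0–10 µV that skews the
  waveform toward the −10..+40 µV asymmetry reported clinically.

Rates, SNR and inter-event statistics are *not* published for the clinical
cohorts this emulates; the defaults are field-plausible stand-ins, exposed
in `generator_config()`. Channels are generated independently (no C3/C4
correlation), and there are no artifacts (EMG, eye movements, mains hum),
no K-complexes, no sleep staging, and no non-stationarity across the night.
Consequently the synthetic task is *easier* than real spindle detection:
passing tests demonstrate that the pipeline's mechanics (geometry, balance,
schedules, freezing, metrics) are correct and that the model can learn a
separable sigma-band discrimination — they do not predict clinical
accuracy.

## Bundled experiment sizes

The test suite and the acceptance script run three experiments, sized to
finish on one CPU in minutes; sizes are fixed design choices, recorded in
each result's provenance:

* **Normal-cohort CV** — 10 subjects × 2000 s at 1024 Hz, 2 channels,
  ≈ 4,000 balanced windows; subject-grouped 5-fold CV at 6 epochs.
* **Insomnia-cohort CV** — 6 subjects × 600 s, same protocol.
* **Transfer** — source: 6 normal subjects × 600 s at default noise;
  target: 6 insomnia subjects × 600 s with background RMS raised to 35 µV.
  At default noise the source model already classifies the target cohort
  almost perfectly, leaving no headroom for adaptation to show; the raised
  background emulates the clinically described smaller sigma-band energy
  footprint of insomnia spindles and yields a measurable domain gap. The
  source model trains 4 epochs; each transfer mode fine-tunes 6 epochs per
  fold.

## Numerical choices and degenerate inputs

* Batch-norm uses $\varepsilon = 10^{-5}$ and momentum 0.1 with unbiased
  running variance; a constant (zero-variance) input window stays finite.
* Softmax is computed with max-subtraction; training loss clamps
  probabilities at $10^{-12}$ before the log.
* Convolution weights use He-style initialization
  ($\sigma = \sqrt{2/\mathrm{fan_in}}$); batch-norm starts at scale 1,
  shift 0; biases at 0.
* Positive windows whose span would cross a recording boundary are dropped
  (and counted in a warning), never padded — padding would fabricate
  signal.
* Negatives are drawn without replacement and may not overlap each other
  nor come within `guard_s` of any event; an infeasible request errors with
  the approximate feasible maximum.
* A zero-variance channel is an error naming the channel (z-scoring is
  undefined); recall is an error when no positive labels are present; F1 is
  defined as 0 when precision + recall = 0; AUC uses midranks, which is
  exactly the ties-count-½ convention.
* EDF output quantizes to 16 bits over ±200 µV (≈ 0.006 µV per step);
  the reader inverts the published linear mapping, so the round trip is the
  identity up to that quantization.

## Known limitations

* The published architecture omits channel counts, kernel sizes and dense
  widths; the defaults here are chosen for CPU-scale training and are not
  claimed to equal any particular clinical configuration (all are
  config-exposed and recorded in model provenance).
* Whole-night inference with sliding windows is out of scope: the
  classifier operates on pre-segmented 3 s windows.
* EDF support covers continuous single-rate recordings; EDF+ embedded
  annotations are not parsed (annotations travel as CSV).
* The synthetic generator's independence and stationarity assumptions are
  listed above; none of the bundled results should be read as clinical
  performance estimates.
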