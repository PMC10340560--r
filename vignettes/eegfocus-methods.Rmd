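---
title: "Methods: seizure detection and focus lateralization in eegfocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seizure detection and focus lateralization in eegfocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfocus)
```

## The problem

Temporal lobe epilepsy (TLE) is the most common focal epilepsy. Two questions
dominate its presurgical EEG work-up: *when* is the patient seizing (ictal vs
interictal periods), and *which hemisphere* hosts the epileptic focus.
`eegfocus` implements a two-stage decision-support pipeline for scalp EEG on
the standard longitudinal bipolar 10-20 montage (18 derivations, of which 16
form 8 left/right symmetric pairs):

1. **Ictal epoch detection.** Recordings are filtered, resampled, cut into
   4096-sample epochs, and each epoch is summarized by one energy value per
   channel in a chosen wavelet subband. A small LSTM classifier labels each
   epoch ictal or interictal from this 16-value feature vector.
2. **Focus lateralization.** Over the detected ictal samples, each symmetric
   channel pair votes left or right through an energy asymmetry score
   $A = \sum_n x_\mathrm{left}[n]^2 \,/\, \sum_n x_\mathrm{right}[n]^2$;
   votes are summed per recording and recordings are majority-voted per
   patient.

The stages are deliberately asymmetric in sophistication: detection is a
learning problem (rhythmic discharges take many shapes), while
lateralization exploits a single physiological premise — seizure activity
raises signal energy on the focus side — with transparent, auditable voting.

## Preprocessing

* **Low-pass** Butterworth, cutoff 64 Hz, order 6, applied forward-backward
  (`signal::filtfilt`), so the effective order is 12 and the phase response
  is zero (waveform morphology is what neurologists read; zero-phase
  filtering preserves it). Order 6 is chosen so that the zero-phase chain
  attenuates 100 Hz content of a 500 Hz recording by more than 40 dB; an
  order-4 design reaches only ~37 dB there.
* **Notch** at 50 Hz: the standard constant-bandwidth biquad (RBJ cookbook)
  with a 2 Hz -3 dB width, also zero-phase. Power-line interference is the
  one narrowband artifact we always expect in hospital recordings.
* **Resampling** to the 256 Hz analysis rate by polyphase rational
  resampling (`signal::resample`, 64/125 for 500 Hz input). The 64 Hz
  low-pass doubles as the anti-alias filter. The analysis rate is what ties
  the dyadic subband tree to the named EEG bands (next section).
* **Epoching**: consecutive non-overlapping 4096-sample windows (16 s at
  256 Hz); the trailing partial window is discarded. An epoch is labeled
  ictal when at least half of its samples fall inside ictal annotations —
  annotations label intervals, not epochs, and majority occupancy is the
  least surprising conversion. The threshold is configurable
  (`epoch_label_overlap_threshold`).

## The subband tree and its arithmetic

Features come from a dyadic discrete wavelet decomposition with the
4th-order Daubechies wavelet (db4) and **periodization** boundary handling.
Periodization makes the transform exactly orthogonal, so summed squared
coefficients equal summed squared samples (Parseval); band energies are
then computed on coefficients directly, never on reconstructed signals —
the two agree for an orthonormal wavelet, and coefficients are cheaper.

One arithmetic subtlety deserves a paragraph, because getting it wrong
silently destroys the features. At a 256 Hz rate the first detail level of
a dyadic tree spans 64-128 Hz, while the named EEG subbands of this
pipeline (D1 = 32-64 Hz down to D9 = 0.125-0.25 Hz, A9 = 0-0.125 Hz)
describe a 128 Hz bandwidth. `dwt_tree()` therefore performs one initial
split that isolates the 64-128 Hz residual (`HF` — essentially empty after
the 64 Hz low-pass) and then runs the nine named levels below it, so every
named band physically means what its label says. The classical bands map
onto the tree as Alpha = D3, Theta = D4, and Delta = D5..D9 + A9 (0-4 Hz).

Beta (16-24 Hz) and gamma (24-32 Hz) come from one further single-level
split of D2 (16-32 Hz). Wavelet-packet frequency ordering *reverses* on a
detail branch: D2 is spectrally inverted, so the low-pass child of the
split holds the upper half (gamma) and the high-pass child the lower half
(beta). The package assigns the children accordingly and the test suite
pins the assignment with sine probes at 20 and 28 Hz.

## The classifier

Each epoch contributes a 16-value feature vector (beta-band energy per
lateral channel, by default). Because band power is approximately
log-normal and raw energies span orders of magnitude, the network input is
the per-channel **z-score of log-energies**, with statistics taken from the
training split only.

The network is deliberately small: feature input (16) → LSTM (128 hidden
units) → fully connected (2) → softmax, trained with cross-entropy,
mini-batches of 150, Adam at learning rate 0.001, at most 100 passes, and
the global gradient norm clipped at 2. Each epoch is presented as a
length-1 sequence by default — the model is then a gated nonlinear
classifier on the feature vector; `seq_len > 1` feeds runs of consecutive
epochs for users who want temporal context. The implementation (forward
pass, backpropagation through time, Adam, clipping) is plain R matrix
code; its gradients are verified against finite differences in the test
suite. Model selection keeps the parameters of the best validation-accuracy
pass (ties to the earliest).

Data handling follows three rules:

* **Split fractions 0.70/0.15/0.15**, stratified by label and seeded. The
  familiar train/validation/test epoch counts this mirrors (7452/1596/1596
  of 10,644) are 70/15/15 of the total.
* **Balancing after splitting, training split only.** Ictal epochs are
  typically outnumbered ~1:12 by background; without balancing the
  classifier can reach high accuracy by calling everything interictal.
  Each ictal training row is duplicated
  $k = \max(1, \mathrm{round}(n_\mathrm{inter}/n_\mathrm{ictal}))$
  times, bringing the ratio into [1/2, 2]. Balancing before splitting
  would leak duplicates into validation and test, so it never happens.
* **Metrics** are the confusion-matrix trio with ictal as the positive
  class: accuracy, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).

## Lateralization

For each of the 8 symmetric pairs, per-channel energies are pooled (summed)
over all ictal epochs of a recording and the asymmetry score of the pooled
energies is taken. Pooling reconciles the two natural readings of the
score — per-epoch or per-recording — and weighs epochs by their energy; a
`per_epoch` mode (vote each epoch, average) is available for comparison.
The score uses the preprocessed broadband signal, not a subband: the
premise is a broadband energy increase on the focus side.

Tie-breaks are resolved toward the right, in three places, because the
decision rule is "left if strictly greater, otherwise right":

* a pair with $A = 1$ exactly votes $-1$ (a measure-zero event on real data),
* a recording with vote sum 0 is called right,
* a patient with equally many left and right recordings is called right.

A degenerate pair (zero right-side energy, e.g. a flat channel) is excluded
from the vote rather than allowed to contribute an infinite score.
Lateralization metrics treat **left** as the positive class, so sensitivity
is the left-focus detection rate.

## The synthetic cohort generator

No public dataset carries expert ictal intervals *and* focus-side labels on
this montage, so the package ships a generator that emulates the relevant
statistical structure and makes every stage testable:

* **Background**: per-channel $1/f^\alpha$ noise ($\alpha = 1$, RMS
  20 µV) — EEG spectra are approximately power-law, which gives band
  energies realistic relative scales — plus a 50 Hz mains sinusoid (5 µV).
* **Seizures**: within annotated windows, a narrowband oscillation
  (default 16-24 Hz, the beta band; peak 50 µV) is added to the 16 lateral
  channels with a shared random frequency and per-channel random phase.
  The envelope is a Hann-tapered plateau: cosine ramps of at most 5 s lead
  into a sustained discharge. Ramps avoid a detectable hard-onset artifact;
  the plateau reflects that rhythmic ictal activity sustains its amplitude
  (a full-window Hann ramp would make boundary epochs carry the ictal
  label with almost no oscillation energy, turning label conversion noise
  into class overlap).
* **Asymmetry**: focus-side channels carry the oscillation scaled by
  $\gamma = 1.5$ (energy ratio 2.25), matching the premise the asymmetry
  score tests for. Midline channels get no oscillation.
* **Cohorts**: each patient draws a focus side once (28/76 left by
  default, a right-dominant surgical case mix) shared by all their
  recordings; per-recording seeds derive deterministically from the master
  seed, so a cohort is a pure function of its configuration.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: artifacts (EMG, eye blinks, electrode pops),
spikes and sharp waves, seizure propagation and evolution across channels
and frequencies, inter-patient amplitude variability, and non-stationary
background. Synthetic results validate the machinery, not clinical
performance.

## Numerical choices and degenerate inputs

* Periodization makes the Parseval check exact to rounding (the test suite
  demands 1e-8 relative over random epochs).
* Epoch lengths must be powers of two of at least $2^{10}$ samples (ten
  dyadic splits: one residual + nine named levels); the default 4096 gives
  16 s epochs.
* All randomness funnels through one master seed per run; sub-seeds for
  cohort generation, splitting and network initialization are derived by
  deterministic integer mixing, and reports are byte-identical across
  reruns of the same configuration (single-threaded).
* Channel matching is case-insensitive and treats `-`/`_` as equivalent,
  since EDF label conventions vary; missing montage channels are hard
  errors naming the channel.
* Recordings shorter than one epoch yield an empty epoch set with a
  warning; recordings without ictal epochs raise a lateralization error
  rather than guessing a side.

## Problem sizes in the shipped checks

The test-suite and acceptance-script runs use desk-scale synthetic cohorts
chosen to exercise every code path with comfortable statistical margins:
cohorts of 8-10 patients with 3 recordings each (24-30 recordings,
~170-210 epochs) for classifier checks across 5 seeds; 40 single
recordings at 0 dB discharge-to-background power for lateralization
recovery; and 100 random epochs for energy-conservation checks. The
configured defaults (128 hidden units, 100 passes, batch 150) are used as
is; only cohort sizes are the package's own choice.

## Known limitations

* Scalp EEG only; no referential-to-bipolar re-derivation, no source
  localization, no within-hemisphere localization.
* The LSTM sees one epoch at a time by default; long-range temporal
  context is available via `seq_len` but untuned.
* The EDF reader covers continuous 16-bit recordings with a uniform
  sampling rate; EDF+ event channels are out of scope (interval labels
  travel in a CSV sidecar).
* Lateralization assumes the energy-asymmetry premise; bilateral or
  rapidly generalizing seizures can defeat it, and the package makes no
  attempt to detect that situation beyond exposing the per-pair scores.
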