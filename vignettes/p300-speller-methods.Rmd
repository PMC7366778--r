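---
title: "Models and methods behind p300speller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind p300speller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300speller)
```

# The control problem

A matrix speller turns gaze-directed attention into discrete commands. A
6x6 grid of 36 symbols is displayed; rows and columns flash in random
order. When the row or column containing the attended symbol flashes, the
brain produces a P300 — a positive event-related potential peaking roughly
300 ms (250–500 ms) after the rare, attended stimulus. Detecting which 2
of the 12 stimuli elicited a P300 identifies the attended symbol, which
can then drive an external actuator (a robotic arm, a menu, a keyboard).

`p300speller` implements the whole decoding chain — stimulation
bookkeeping, synthetic EEG generation, preprocessing, xDAWN spatial
enhancement, three epoch detectors, character decoding, and evaluation
metrics — so each stage can be tested in isolation and end to end.

# The stimulation protocol and its closed-form timing

One *repetition* flashes all 6 rows and 6 columns once, in a fresh uniform
random permutation; `n_reps` repetitions decide one character. Flash
onsets within a repetition are `isi_s` apart (ISI = flash + gap);
consecutive repetitions are separated by `inter_rep_s` and consecutive
character trials by `inter_char_s`. Both delays count gaps *between*
units, which gives the session length

```
n_chars * (n_reps * 12 * isi + (n_reps - 1) * inter_rep)
  + (n_chars - 1) * inter_char
```

With the training parameters (ISI 150 ms, 0.5 s, 5 s, 12 repetitions) a
15-character calibration run lasts exactly 476.5 s and contains
`15 * 12 * 12 = 2160` flash epochs, of which `15 * 12 * 2 = 360` are
targets (one row and one column per repetition). The online parameters
(ISI 75 ms, 0.25 s between repetitions) give a per-decision stimulation
time of `12 * 0.9 + 11 * 0.25 = 13.55` s. Onsets are computed in exact
seconds and only then rounded to the nearest sample, so no drift
accumulates over long sessions.

The online repetition count is not independently specified anywhere in the
protocol description; we fix it at 12 because that value makes the timing
model consistent with both published transfer-rate operating points
(`itr(0.8083, 36, 13.55)` = 15.42 and `itr(0.9443, 36, 27.1)` = 10.13
bits/min).

# The synthetic session generator

No public recordings exist for this paradigm, so the package ships a
generator that produces sessions with exactly the statistical structure
the detector assumes, making every downstream stage testable:

* **Evoked response.** A Gaussian bump `amp * exp(-(t - latency)^2 / (2
  width^2))` peaking at 300 ms (width 60 ms) after each *target* flash,
  with per-event latency jitter (SD 10 ms). The bump is distributed over
  channels by a fixed unit-norm *spatial pattern*; overlapping responses
  from successive flashes add linearly, which is precisely the
  superposition assumption of the xDAWN signal model.
* **Background.** Pink (1/f) noise per channel (frequency-domain shaping
  with seeded phases; SD 2 uV), a 10 Hz alpha sinusoid with random phase
  per channel (1 uV), and white sensor noise (0.5 uV).
* **Defaults.** 64 channels at 500 Hz, P300 amplitude 5 uV. The 5 uV / 2
  uV amplitude ratio is a calibration choice — the underlying study
  reports no amplitudes or SNR for its participants — picked as a
  realistic single-trial regime in which detection is good but imperfect.
  The default spatial pattern is a smooth bump over a contiguous block of
  channels, emulating a centro-parietal topography without claiming any
  montage fidelity.

Everything is drawn from one seed, so sessions are bit-reproducible.

What the generator does *not* emulate: eye blinks and EMG artifacts,
electrode drift and impedance variation, volume-conduction physics,
non-stationarity across a session, and the attention lapses that make real
online use harder than calibration. Passing tests on synthetic sessions
therefore demonstrate the correctness of the machinery and its behavior
under the model's own assumptions — not human-subject performance.

# Preprocessing

Signals are band-passed 1–20 Hz with a causal Butterworth filter
(`signal::butter(4, ...)`, four poles per band edge), decimated by 4
(500 to 125 Hz) after a causal anti-aliasing low-pass, and cut into
stimulus-locked epochs.

Two deliberate choices:

* **Causal, not zero-phase, filtering.** The same code path must run
  online, where future samples do not exist. As a consequence the online
  simulation (`run_online_sim`) provably reproduces offline decisions.
* **Epoch length.** Epochs span the full `[0, 500)` ms after each flash —
  `floor(0.5 * 125) = 62` samples — so the canonical 250–500 ms P300
  window always lies inside the epoch. (A 250 ms feature window inside a
  500 ms epoch would also be defensible; the full window is simpler and
  loses nothing, since the spatial filter and classifier weight samples
  freely.)

Markers are 0-based sample indices, epochs half-open windows; decimation
rescales markers by floor division. Epochs that would overrun the
recording are rejected and counted, never silently shortened.

# xDAWN spatial enhancement

The preprocessed recording `X` (samples x channels) is modeled as a
target-locked evoked response `A` replicated at every target onset by a
sparse 0/1 Toeplitz design `D`, plus everything else. `A` is estimated by
least squares (`argmin ||X - D A||^2`), which is the stimulus-locked
average corrected for overlapping flashes.

Spatial filters `u` maximize the signal-to-signal-plus-noise ratio

```
SSNR(u) = (u' S1 u) / (u' Sx u),   S1 = (DA)'(DA)/n,   Sx = X'X/n
```

a generalized Rayleigh quotient, solved by Cholesky-whitening `Sx` and an
ordinary symmetric eigendecomposition. The top `k = 3` eigenvectors are
kept, compressing 64 channels to 3 enhanced components (186 features per
epoch at 62 samples). Numerical choices:

* expectations are realized as sample covariances normalized by sample
  count;
* if `Sx` is not positive definite it is ridge-regularized with a logged
  epsilon (relative to `tr(Sx)/p`), escalating by decades until the
  factorization succeeds;
* eigenvector signs are fixed (largest-magnitude coefficient positive) so
  fits are deterministic;
* the denominator uses the *total* signal covariance, taking the SSNR
  definition literally rather than subtracting the evoked part — the
  nontarget response is not separately modeled;
* filters are fitted on the training session only and frozen for
  decoding.

Tests verify the solution against a dense `eigen(solve(Sx) %*% S1)` oracle
on 4-channel toys (to 1e-8), against 1000 random unit filters, and against
the planted generator pattern (forward pattern `Sx u` cosine >= 0.95 at the
default SNR).

# The three detectors

All three consume the 186-dimensional xDAWN features and output a real
score per epoch (positive = Target).

* **Fisher LDA.** `v = S_w^{-1}(m_T - m_N)` with shrinkage
  `eps = 1e-6 * tr(S_w)/d` on the within-class scatter — 186 features
  against 1728 training epochs per fold can be ill-conditioned. Threshold
  at the midpoint of projected class means.
* **SVM.** Soft-margin dual with the cubic polynomial kernel
  `(x'y + 1)^3`, solved by sequential minimal optimization with
  maximal-violating-pair selection; stopping at KKT gap 1e-4. `C = 1`
  with class weights inversely proportional to class frequency (the
  paradigm is 1:5 Target:NoTarget); features standardized before the
  kernel for conditioning. The reference study does not state its `C`.
* **MLP.** Two tanh hidden layers (32, 16) and a logistic output, trained
  by full-batch gradient descent (rate 0.5, 500 iterations) on
  cross-entropy, gradients by backpropagation (verified against central
  finite differences to 1e-5 relative). Weights start at small seeded
  uniform values: an all-zero start leaves all hidden units with
  identical gradients forever. Layer sizes, rate and iteration count are
  calibration defaults; only the two-layer tanh architecture is fixed by
  the design.

Where an established implementation of the same classifier exists
(`MASS::lda`, `e1071::svm`) it is used in the test suite as an independent
cross-check of directions and decision values, never as the
implementation.

Training quality is reported by stratified five-fold cross-validation,
mean ± sample (n−1) standard deviation — the n−1 convention is the one
that reproduces the published cross-validation summary row exactly.

# Character decoding

Scores are summed over repetitions per stimulus; the best row (R0–R5) and
best column (C0–C5) index the grid. Summation of raw scores (rather than
thresholding-then-voting) is the standard speller aggregation and is the
package's documented choice; ties break toward the lowest index and are
logged. Epoch-level accuracy (single-flash detection) and character-level
accuracy (decoded symbols) are reported separately; the transfer rate
uses character-level accuracy with the stimulation time only — the only
reading consistent with both published rate values.

The character-to-command mapping is a pluggable dictionary; the default is
the identity (the decoded character *is* the command).

# Metrics

Confusion-matrix statistics follow the usual two-class definitions
(sensitivity TP/(TP+FN), precision TP/(TP+FP), specificity TN/(TN+FP),
F-measure 2PS/(P+S)); zero denominators raise errors rather than
returning 0. The Shannon transfer rate uses `0*log2(0) = 0` so `P` of 0
and 1 are handled, and is exactly zero at chance `P = 1/N`.

# File formats

Sessions are stored as a directory bundle: a plain-text header, a
tab-separated marker table, and the signal as little-endian 64-bit doubles
(channel-major). Double precision was chosen so that a write/read
round-trip reproduces a synthesized session bit for bit; a 32-bit store
would be smaller but lossy for double-precision data. Fitted models
(xDAWN and all three detectors) serialize to a documented key-value +
matrix text format at full precision. A minimal BrainVision importer
(.vhdr/.vmrk/.eeg; INT_16 and IEEE_FLOAT_32, multiplexed or vectorized)
maps vendor stimulus codes to the package's stimulus ids through a
user-supplied code table, since marker code conventions vary by lab.

# Problem sizes used by the test suite

The suite exercises the full study scale once — a 64-channel,
15-character training session (2160 epochs) for the spatial-filter
recovery and decoding checks — and smaller sessions (8–16 channels, 2–6
characters) for unit-level properties. The repetition-count sweep uses 20
independent 16-channel test sessions at a moderate 2 uV amplitude, where
accuracy actually varies with repetition count instead of saturating.
These sizes are the package's own balance between statistical power and a
test suite that runs in a couple of minutes.

# Known limitations

* Synthetic sessions are the only bundled data; all accuracy figures on
  them characterize the machinery under its own generative assumptions.
* The SMO solver holds the full kernel matrix in memory — fine for
  single-session training (a few thousand epochs), not for pooled
  multi-session corpora.
* The MLP is deliberately plain (no momentum, no regularization); it
  exists as a faithful comparison detector, not as a competitive deep
  model.
* The BrainVision importer covers the binary encodings above; other
  dialects raise a named error rather than guessing.
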