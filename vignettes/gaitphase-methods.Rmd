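---
title: "Methods: gait phase classification from shank IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait phase classification from shank IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A gait cycle (stride) of one leg runs from a heel strike (HS) to the next
HS of the same leg. `gaitphase` labels every sample of a walking recording
with one of four phases of a chosen *reference* leg:

* **LR** (Loading Response) — first double support, reference HS to
  contralateral toe off (TO);
* **LS** (Late Stance) — single support on the reference leg, the merged
  Mid Stance + Terminal Stance interval, contralateral TO to contralateral
  HS;
* **PSw** (Pre-Swing) — second double support, contralateral HS to
  reference TO;
* **Sw** (Swing) — reference TO to the next reference HS.

and then trains sequence classifiers to predict the phase *one step ahead*
from a short window of shank IMU signals (3-axis acceleration + 3-axis
angular velocity per shank, 12 channels), so that at deployment time no
foot-contact instrumentation is needed.

## Phase labeling rules

Events come from the binary foot-contact channels: HS at every 0→1
transition, TO at every 1→0 transition, with a configurable debounce
(`min_gap`, default 50 ms: contact or no-contact segments shorter than
this are treated as sensor bounce and merged into their neighbors before
edges are read off). A leading stance has no detectable HS and a trailing
stance no TO.

All sample indices are 0-based and all intervals half-open
`[start, end)`, which makes the four phases an exact partition of each
complete cycle: `LR = [R.HS, C.TO)`, `LS = [C.TO, C.HS)`,
`PSw = [C.HS, R.TO)`, `Sw = [R.TO, next R.HS)` for reference side R and
contralateral side C. This is the standard Perry-style four-phase
partition; it is the unique assignment of these four named phases that
partitions the cycle, and the source material for this design describes
the same structure (its transition diagram and its LR rule), even though
its prose states the LS/PSw boundaries in a self-contradictory way. The
reference side defaults to the right leg; the mirrored labeling is the
same operation with sides swapped.

Cycles at the recording boundaries that lack a complete
HS→TO→HS→TO→HS event chain stay `UNLABELED (-1)` and are later excluded
from training targets; no extrapolation is attempted. A broken chain in
the *interior* of a recording (events out of the LR→LS→PSw→Sw order)
raises a labeling error naming the offending cycle, because it indicates
corrupt contact data rather than a boundary effect.

A valid four-phase structure requires genuine double support:
`contralateral_offset + stance_fraction > 1` (so the contralateral TO
falls after the reference HS) and `contralateral_offset <
stance_fraction` (so the contralateral HS falls before the reference TO).
Healthy level walking (offset ≈ 0.5, stance ≈ 0.6) sits comfortably
inside this region; the property-based tests draw schedules from it.

## The synthetic stated world

The generator stands in for multi-subject overground walking recordings
(the real benchmark uses 35 subjects, 4-minute trials at 200 Hz, which is
not desk-scale). Its defaults are the stated world of the test suite:

| parameter | default | rationale |
|---|---|---|
| `fs` | 200 Hz | recording rate of the emulated protocol; exercises the 200→100 Hz resampling step |
| `cycle_mean` | 1.1 s | comfortable stride time in healthy adults |
| `cycle_cv` | 0.03 | healthy stride-time variability (~2–4 %) |
| `stance_fraction` | 0.60 | canonical duty cycle of level walking |
| `contralateral_offset` | 0.50 | half-cycle left/right lag |
| `start_offset` | 0.1 s | first right HS strictly after sample 0, so *every* rendered event is recoverable from the contact channel (a stance already in progress at sample 0 has no rising edge) |
| `noise_sigma` | 0.3 | moderate noise relative to bump amplitudes of 0.4–2 |
| subject amplitude / cadence sd | 0.10 / 0.03 | log-normal subject-level multipliers, so trials of one subject correlate and subject-wise generalization is a real test |

Per-cycle durations are drawn around `cycle_mean` (normal, truncated at
20 % of the mean); right-leg HS times are `start_offset` plus their
cumulative sum, each TO follows its HS by `stance_fraction` of the cycle,
and left events are right events shifted by `contralateral_offset` of the
cycle. Each IMU channel is a sum of Gaussian bumps, one per phase
occurrence (centered at the run midpoint, σ a quarter of the run length),
with a per-channel per-phase amplitude: each channel has one dominant
(2.0) and one secondary (1.0) phase over a 0.4 baseline. The bench signal
is therefore phase-discriminative but smooth, which is the point: the
suite tests the *pipeline*, not the biomechanics. Real IMU data differ in
ways the generator deliberately omits — gravity and orientation effects,
drift, impact transients, within-subject waveform changes — so a green
end-to-end test establishes that the implementation learns and evaluates
correctly, **not** that the printed full-scale accuracies are reproduced.
Amplitude values are free parameters (the emulated protocol publishes no
waveform statistics); they were fixed once, before any accuracy was
measured.

## Dataset construction

* **Resampling** 200→100 Hz: zero-phase symmetric Hamming-windowed-sinc
  FIR (cutoff `0.4 * fs_out`, 65 taps, reflection padding) on the IMU
  channels, then decimation; contact and label series are decimated by
  index selection, event indices by integer division.
* **Split** is subject-wise: all sessions of held-out subjects form the
  test set; each training subject donates one seeded-draw session to
  validation. This matches the full-scale protocol (24 train / 11 test
  subjects; 3 + 1 sessions) at whatever subject count is simulated.
* **Scaling**: per-channel zero-mean/unit-variance statistics fitted on
  the pooled training partition only (pooled rather than per-trial —
  standard practice; the source protocol does not say which) and applied
  unchanged to validation/test. Scaling happens before windowing; for a
  per-channel affine map this is identical to scaling windows and avoids
  recomputing overlapping samples.
* **Windows**: length `w = 20`, stride 1, target = label at the next step
  (`offset = +1`); a fully labeled trial of `n` samples yields exactly
  `n − w` samples. Windows whose target is unlabeled are dropped; a
  window whose *input* span touches unlabeled samples is kept (inputs
  need no labels). Windows never cross trial boundaries.
* **Balancing**: the training pool (only) is undersampled without
  replacement so each class matches the smallest class count.

## Models

All three classifiers map a `w × 12` window to four class probabilities.
Because no deep-learning framework is available in the target
environment, the architectures and their training loop are implemented on
a small reverse-mode autodiff engine over R matrices; every backward rule
is finite-difference checked in the test suite, and the layer kernels
(valid 1-D convolution, scaled dot-product attention, sinusoidal
positional encoding) are additionally verified against independent
nested-loop oracles.

* **1-D CNN**: two valid-mode temporal convolutions (shared filter count,
  defaults 32 filters, kernel 1), each followed by max pooling (size 2 —
  the pooling type/size is unspecified in the source design; max/2 is the
  common choice), then a dense ReLU layer with dropout 0.3 and the output
  layer.
* **Hybrid LSTM+GRU**: LSTM(100, sequence) → LSTM(100, sequence) →
  GRU(256, final state) → dense(128, ReLU) → dropout 0.3 → output.
* **Transformer encoder**: per-time-step linear embedding to
  `d_model = 256` plus sinusoidal positional encoding, two encoder blocks
  (single-head self-attention and a position-wise FFN of width 512, each
  in a post-norm residual arrangement, dropout 0.4 on sublayer outputs),
  mean pooling over time (the temporal pooling is unspecified; `"last"`
  is available as an option), then the output layer.

The output activation is a row-wise softmax with categorical
cross-entropy: the four phases are mutually exclusive, so the "sigmoid"
reading of the source description is kept only as a non-default option
(`output_activation = "sigmoid"`: independent per-class sigmoids with
binary cross-entropy and argmax prediction). Weight initialization is
Glorot-uniform under an explicit seed. Channel vectors are kept per time
step throughout (consistent with the convolution operating on `x_{t+i}`
vectors); nothing is flattened before the dense heads except the CNN's
pooled feature map.

## Training and evaluation

The full-scale protocol is 80 epochs, no early stopping, with per-model
settings: CNN and hybrid — Adam, batch 1024, dropout 0.3, learning rates
1e-4 and 2.2e-3; Transformer — AdamW (decoupled weight decay 0.01),
batch 128, dropout 0.4, learning rate 2.92e-5. These are the package
defaults. Validation data are used for monitoring only (the original
hyperparameter search is out of scope; its selected values are the
defaults). Reported metrics are overall accuracy plus macro-averaged
precision, recall and F1 (unweighted over the four classes; a class never
predicted has undefined precision and is excluded with a warning), and
confusion matrices are emitted both as raw counts and as row-normalized
percentages — the row-normalized diagonal mean *is* macro recall, which
is how the shipped printed matrices are checked against the shipped
headline table to two decimals.

### Desk-scale profiles

`run_synthetic_benchmark()` runs the whole pipeline at a size that fits a
single CPU in a few minutes: 12 subjects × 2 × 60 s, 8/4 subject split,
reduced widths (CNN 16 filters / dense 32; hybrid 24/24 LSTM, 32 GRU,
32 dense; Transformer d_model 32, 1 head, 2 layers, d_ff 64) and ≤ 10
epochs. Two training settings deviate from the full-scale defaults, by
design rather than tuning: the CNN uses learning rate 1e-3 for 10 epochs
and the Transformer 1e-4 — the full-scale rates (1e-4 and 2.92e-5) were
selected for a dataset with hundreds of times more gradient steps per
epoch and would leave these short runs far from convergence. The
validation loss monitor uses a fixed seeded subsample of ≤ 4096 windows
(evaluating the full ~46k-window validation set after every epoch would
triple the benchmark's cost); the final test evaluation always uses every
test window.

## Numerical choices and degenerate inputs

* Softmax and attention subtract the row maximum before exponentiation.
* Prediction ties break toward the lower class index (deterministic).
* Population (not sample) sd in the channel scaler; zero-variance
  channels are an error, not silently passed through.
* Event indices round to the nearest sample; simulated events at or past
  the trial end are dropped, so a truncated final stance keeps its HS and
  loses its TO, exactly as detection would see it.
* `n ≤ w` trials yield an empty window set with a warning; an empty
  training set, a class with zero samples, or a non-finite loss are
  errors naming the condition.
* All randomness flows through explicit integer seeds; child seeds are
  derived per stage (kept below 2^31) so stages never share streams.
  Results are bit-reproducible under single-threaded BLAS; with
  multi-threaded BLAS they are reproducible in distribution.

## Known limitations

* The generator is a statistical emulation, not a biomechanical model
  (no gravity/orientation, drift, or impact dynamics); bench accuracies
  say nothing about accuracy on real recordings.
* The full-scale printed results are checked only for internal
  consistency (macro recall vs confusion diagonals); reproducing them
  would require the external multi-gigabyte dataset and hours of
  training.
* The hyperparameter search that produced the default widths and
  learning rates is not reimplemented.
* The ingestion path for real recordings is a column-mapped CSV adapter;
  the native schema of the emulated dataset is not published in the
  source material, so the mapping must be user-supplied.
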