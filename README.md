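# gaitphase

Gait-phase classification from shank-mounted IMU time series.

`gaitphase` is for movement scientists and wearable-sensor engineers who
want to label every sample of a walking recording with one of four gait
phases of a reference leg — **LR** (Loading Response), **LS** (Late
Stance, the merged Mid + Terminal Stance single-support interval),
**PSw** (Pre-Swing) and **Sw** (Swing) — and to train sequence
classifiers that predict the phase from inertial signals alone, so that
no foot-contact instrumentation is needed at deployment time.

The package implements the full pipeline:

1. **Event detection** — heel strike (HS) at every 0→1 edge and toe off
   (TO) at every 1→0 edge of a (debounced) binary foot-contact channel.
2. **Phase labeling** — with reference side R and contralateral side C,
   half-open intervals partition each complete cycle exactly:
   `LR = [R.HS, C.TO)`, `LS = [C.TO, C.HS)`, `PSw = [C.HS, R.TO)`,
   `Sw = [R.TO, next R.HS)`.
3. **Dataset construction** — zero-phase FIR resampling 200→100 Hz,
   subject-wise train/validation/test splitting, per-channel
   standardization fitted on training data only, sliding windows of
   `w = 20` steps with the label of the *next* step as target (a fully
   labeled trial of `n` samples yields exactly `n − w` windows), and
   undersampling of the training pool to the smallest class.
4. **Models** — three architectures built on a small, gradient-checked
   reverse-mode autodiff engine (no external DL framework needed):
   a 1-D CNN (`z_t = σ(Σᵢ ⟨wᵢ, x_{t+i}⟩ + b)`, two conv/pool blocks),
   a hybrid LSTM→LSTM→GRU recurrent network, and a Transformer encoder
   (`softmax(QKᵀ/√d_k)V` self-attention, sinusoidal positional encoding,
   position-wise FFN, residual + layer norm).
5. **Evaluation** — confusion matrices (counts and row-normalized %),
   accuracy and macro-averaged precision/recall/F1.

A synthetic bilateral gait generator (periodic gait with ~60% stance
duty cycle, half-cycle left/right offset, phase-locked signal bumps,
subject-level variability, additive noise, known ground truth) makes
every stage testable without any external data. See the methods
vignette (`vignettes/gaitphase-methods.Rmd`) for the model, assumptions
and design decisions.

## Worked example

```r
library(gaitphase)

params <- gait_sim_params(n_subjects = 4, trials_per_subject = 2,
                          trial_duration = 20, seed = 42)
trials <- generate_dataset(params)
trials[[1]]
#> <gait_trial> subject S01 trial T1: 4000 samples @ 200 Hz (20.0 s)
#>   labeled: 3621/4000 samples, reference side right

phase_duration_summary(trials[[1]]$phases, fs = 200)
#>   phase n_runs    mean_s        sd_s
#> 1    LR     17 0.1064706 0.003858718
#> 2    LS     17 0.4258824 0.016320548
#> 3   PSw     17 0.1061765 0.003321056
#> 4    Sw     17 0.4264706 0.013082038
```

Mean durations ≈ 0.11 / 0.43 / 0.11 / 0.43 s are the closed-form
consequence of a 1.06 s cycle (subject cadence factor × 1.1 s) with
stance fraction 0.6 and half-cycle offset: the two double-support phases
each last 10% of the cycle, single support and swing 40% each.

```r
bundle <- build_dataset(trials, fs_out = 100, w = 20, offset = 1,
                        n_test_subjects = 1, split_seed = 1, balance_seed = 2)
bundle$train
#> <window_set> 2188 samples, w = 20, offset = +1, 12 channels
#>  LR  LS PSw  Sw
#> 547 547 547 547

model <- build_cnn(cnn_config(n_filters = 8, dense_units = 16), init_seed = 7)
fit <- train_model(model, bundle$train, bundle$val,
                   train_config(epochs = 8, learning_rate = 1e-3,
                                batch_size = 256, seed = 7))
evaluate_model(fit$model, bundle$test)
#> <eval_report> n = 3723
#>   ACC 82.46%  macro PR 78.02%  RC 87.83%  F1 80.51%
#>   confusion (row %):
#>       predicted
#> actual    LR    LS    PSw    Sw
#>    LR  93.62  0.27   0.27  5.85
#>    LS   8.81 68.86   7.53 14.79
#>    PSw  0.00  0.00 100.00  0.00
#>    Sw   5.24  0.00   5.91 88.84
```

The balanced training pool has equal class counts; the held-out subject
is evaluated on its natural class distribution. This toy run (8 epochs
on 2 188 windows) already separates the phases; the larger
`run_synthetic_benchmark()` protocol (12 subjects × 2 × 60 s, all three
architectures) reaches macro F1 above 93% on unseen subjects in a few
minutes on one CPU.

## Command line

```sh
Rscript inst/cli/gaitphase.R simulate       --config cfg.json
Rscript inst/cli/gaitphase.R label          --config cfg.json
Rscript inst/cli/gaitphase.R build-dataset  --config cfg.json
Rscript inst/cli/gaitphase.R train          --config cfg.json --model transformer
Rscript inst/cli/gaitphase.R evaluate       --config cfg.json --model transformer
Rscript inst/cli/gaitphase.R verify-paper-metrics
```

Configuration is one nested JSON file (see
`inst/extdata/default_config.json`); flags override config keys. Exit
codes: 0 success, 2 config error, 3 missing upstream dependency,
4 verification failure. `verify-paper-metrics` recomputes macro recall
from the shipped row-normalized confusion matrices of the full-scale
benchmark and checks it against the shipped headline table (93.77 /
95.06 / 94.35 for CNN / hybrid / Transformer, to two decimals).

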