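# fbcsprnn

Classification of motor-imagery EEG trials from spatial-frequency-sequential
features: a filter-bank common spatial patterns (FB-CSP) front end, a
sliding-window cropping strategy, and gated recurrent networks (GRU / LSTM)
trained by backpropagation through time.

## Who this is for

Researchers building motor-imagery brain-computer interfaces (MI-BCIs) who
want a self-contained, reproducible R implementation of the
FB-CSP-plus-recurrent-network approach — including a synthetic ERD/ERS
generator so every stage can be developed and tested without access to
recorded EEG.

## The method

Imagined movement suppresses band power of the sensorimotor mu (8–12 Hz)
and beta (18–25 Hz) rhythms contralaterally (event-related
desynchronization). The pipeline turns that into a decision in four
stages:

1. **Filter bank.** Ten zero-phase Butterworth band-pass filters divide
   8–30 Hz into 4-Hz bands overlapping by 2 Hz.
2. **CSP.** Per band, spatial filters `w` maximize the Rayleigh quotient
   `(wᵀC̄₁w)/(wᵀC̄₂w)` of trace-normalized class covariances, solved as the
   generalized eigenproblem `C̄₁w = λ(C̄₁+C̄₂)w` by whitening; the `m`
   largest- and `m` smallest-λ eigenvectors are kept (one-versus-rest for
   more than two classes). Projection `Z = WX` gives the D×T
   spatial-frequency feature series.
3. **Sliding-window cropping.** Each feature series is cut into `T − τ`
   overlapping slices of length `τ` (500 samples at `τ = 20` → 480
   slices), each labelled with the trial's class — multiplying the number
   of training samples.
4. **Recurrent classification.** A GRU or peephole-LSTM cell is unrolled
   over the `τ` slice samples (slice length = unroll depth); a softmax
   head on the final state is trained with cross-entropy, BPTT, Adam and
   dropout 0.2 for exactly 200 epochs (no early stopping). A trial's
   label is the argmax of its slices' averaged probability vectors.

An SVM on log band-power features, misclassification metrics, paired
t-tests between methods, and an autoregressive signal-prediction mode for
choosing the unroll depth round out the toolbox.

## Worked example

Simulate a two-class, three-channel motor-imagery session (ERD depth 0.6
at the C3-/C4-like channels), then run the full pipeline:

```r
library(fbcsprnn)

cfg <- pipeline_config(
  synth = synth_config(n_trials_per_class = 25L, seed = 7L),
  rnn   = rnn_config(cell = "gru", tau = 20L, hidden = 32L,
                     max_iterations = 20L, seed = 8L),
  tau = 20L, train_stride = 24L, predict_stride = 10L, m = 1L, seed = 9L)

report <- run_pipeline(cfg, verbose = TRUE)
#> loaded 50 trials (3 channels x 1750 samples)
#> split: 24 train / 26 validation trials
#> training gru network at tau = 20 (D = 20 rows)
#> validation error 0.00%

print(report)
#> <eval_report>
#>   gru-rnn: mean error 0.00%

head(report$meta$trace[, c("epoch", "train_loss", "train_acc")], 3)
#>   epoch train_loss train_acc
#> 1     1  0.8058471 0.5229167
#> 2     2  0.7828816 0.5375000
#> 3     3  0.7372085 0.5895833
tail(report$meta$trace[, c("epoch", "train_loss", "train_acc")], 1)
#>    epoch train_loss train_acc
#> 20    20 0.04907644 0.9895833
```

The 7 s trials are epoched to the `[4, 6]` s imagery window (500 samples
at 250 Hz), the ten-band FB-CSP front end with `m = 1` yields `D = 20`
feature rows, and slice-level training converges from chance (52% slice
accuracy) to 99% within 20 epochs; averaging slice predictions classifies
every held-out trial correctly. The classical shallow baseline on the
same features agrees that this synthetic contrast is easy:

```r
ts    <- epoch_trials(simulate_trialset(cfg$synth), c(4, 6))
sets  <- fit_fbcsp(ts, default_filter_bank(250), m = 1)
feats <- fbcsp_features(ts, default_filter_bank(250), sets)
x <- t(vapply(feats, logvar_features, numeric(20)))
y <- vapply(feats, `[[`, integer(1), "label")
svm_baseline(x, y, kernel = "rbf", folds = 5)$error_rate
#> [1] 0
```

A thin command-line front end wraps the same functions
(`inst/cli/fbcsprnn.R`: `simulate`, `run`, `sweep-depth`, `baseline-svm`,
`compare`), driven by YAML configurations.

See `vignettes/motor-imagery-pipeline.Rmd` for the model details, every
tunable parameter, what the synthetic generator does and does not
emulate, and the package's numerical choices.

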