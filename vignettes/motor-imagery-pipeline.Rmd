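---
title: "Spatial-frequency-sequential classification of motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-frequency-sequential classification of motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbcsprnn)
```

## The problem

Motor-imagery brain-computer interfaces decode which movement a subject is
imagining from multi-channel EEG. The usable signal is the event-related
desynchronization/synchronization (ERD/ERS) of the sensorimotor rhythms:
imagining a left- or right-hand movement suppresses band power in the mu
(8–12 Hz) and beta (18–25 Hz) rhythms over the contralateral motor cortex.
Two obstacles make this hard: volume conduction smears every cortical
source across all electrodes, and motor-imagery datasets are small — a few
hundred labelled trials per subject at best, which starves flexible
classifiers.

`fbcsprnn` addresses both with a four-stage pipeline:

1. a **Butterworth filter bank** splits the 8–30 Hz range into ten 4-Hz
   bands overlapping by 2 Hz;
2. **common spatial patterns (CSP)** learn, per band, spatial filters that
   maximize the variance contrast between classes, undoing volume
   conduction;
3. a **sliding-window cropping strategy** cuts each projected trial into
   many short, overlapping, equally-labelled time slices, multiplying the
   number of training samples by roughly the trial length;
4. a **gated recurrent network** (GRU or LSTM; a vanilla cell is provided
   for reference) classifies each slice, and the trial-level decision
   averages the slice probability vectors.

## The model

### CSP as a generalized eigenproblem

For band-filtered trials of class $c$, each trial matrix
$X \in \mathbb{R}^{N \times T}$ is mean-centered per channel and its
covariance $XX^\top$ is normalized by its trace before averaging into the
class covariance $\bar C_c$. Trace normalization removes per-trial
amplitude differences that would otherwise dominate the average.

A spatial filter $w$ maximizes the power ratio
$\frac{w^\top \bar C_1 w}{w^\top \bar C_2 w}$, a Rayleigh quotient. We
solve the equivalent symmetric problem
$\bar C_1 w = \lambda (\bar C_1 + \bar C_2) w$ by whitening the composite
covariance: eigendecompose $\bar C_1 + \bar C_2 = E \Lambda E^\top$, set
$P = \Lambda^{-1/2} E^\top$, and eigendecompose $P \bar C_1 P^\top$. The
resulting eigenvalues lie in $[0, 1]$ (they are the fraction of composite
variance explained by class 1 along each filter, and the two class views
pair up as $\lambda_i \leftrightarrow 1 - \lambda_{N+1-i}$). The
projection keeps the eigenvectors of the $m$ largest and $m$ smallest
eigenvalues — the directions most discriminative for either class — giving
$M = 2m$ filters per band. Every filter satisfies
$w^\top(\bar C_1 + \bar C_2)w = 1$, and each row's sign is fixed so its
largest-magnitude coefficient is positive, making the output
deterministic.

With more than two classes, a one-versus-rest extension fits one filter
set per (band, class): the class covariance against the pooled covariance
of the remaining classes, weighted by their trial counts so class
imbalance does not bias the "rest" estimate.

Stacking all filter sets' projections $Z = W X$ band-major (then by class)
yields the spatial-frequency feature series, $D$ rows by $T$ samples. For
the classical shallow baseline, each row is reduced to the log of its
variance, normalized within its filter set — the standard CSP band-power
feature fed to an SVM.

### Cropping and the recurrent classifier

A feature series of length $T$ cropped with windows of length $\tau$
(stride 1) yields exactly $T - \tau$ slices, each inheriting the trial
label: a 2 s epoch at 250 Hz ($T = 500$) cropped at $\tau = 20$ gives 480
slices. Slice length and network depth are the same quantity: the
recurrent cell is unrolled once per slice sample, so choosing $\tau$ *is*
choosing the number of unrolled hidden layers. `sweep_depth()` selects
$\tau$ empirically as the depth maximizing validation accuracy (ties break
toward the smaller, cheaper depth).

The recurrent state update is $h_t = \sigma(W x_t + U h_{t-1} + b)$ for
the vanilla cell. The GRU uses update and reset gates

$$z_t = g(W_z x_t + U_z h_{t-1} + b_z), \quad
  r_t = g(W_r x_t + U_r h_{t-1} + b_r)$$
$$\tilde h_t = \tanh(W_c x_t + U_c (r_t \odot h_{t-1}) + b_c), \quad
  h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t$$

and the LSTM keeps a cell state $c_t = f_t \odot c_{t-1} + i_t \odot
\tilde g_t$ with input/forget/output gates and peephole connections: the
input and forget gates see $c_{t-1}$, the output gate sees $c_t$, each
through a per-unit weight vector. The hidden state is $h_t = o_t \odot
\sigma_{out}(c_t)$.

The classification head applies a softmax to an affine map of the final
step's hidden state; training minimizes the logarithmic cross-entropy
averaged over the mini-batch (with two classes this is exactly the binary
form, since the two probabilities sum to one). Gradients are
backpropagated through time analytically; the test suite verifies every
cell type and gate mode against central finite differences. A trial is
classified by scoring all of its slices and averaging the probability
vectors; exact ties break toward the lowest class index.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| bands | ten 4-Hz bands, 8–30 Hz, 2 Hz overlap | fixed, subject-independent division covering mu and beta |
| filter order | 4 | Butterworth, applied forward–backward (zero-phase), so slice/label alignment is preserved |
| notch | 50 Hz, Q = 30 | second-order IIR; mains interference |
| broadband band-pass | 0.1–100 Hz | high-pass/low-pass cascade: keeps the 0.1 Hz edge numerically well conditioned |
| `m` | 1 | filters per extreme; 1 suits 3-channel montages, 2 suits 22-channel caps |
| shrinkage `gamma` | 1e-6 | covariance regularization toward the scaled identity; guards short epochs |
| `omega` | 0 | causal moving-average smoothing window, in samples; 0 disables |
| `tau` | 20 (or swept) | slice length = unroll depth, in samples (80 ms at 250 Hz) |
| hidden width `H` | 32 | free capacity parameter of the recurrent state |
| `init_sigma` | 0.2 | weights drawn i.i.d. N(0, 0.2); biases zero |
| dropout | 0.2 | on non-recurrent connections (inputs, head input), training only |
| iterations | 200 | epochs over the slices; training never stops early |
| optimizer | Adam, lr 1e-3, betas 0.9/0.999, eps 1e-8 | conventional defaults |
| batch size | 64 slices | one "iteration" = one epoch over all training slices |
| gate activation | sigmoid (default) or ReLU | see below |

Two gate-activation modes are provided. `paper_relu` uses ReLU gates with
a tanh cell input (and, for the LSTM, a sigmoid cell-output activation) —
the idea being that unbounded gates resist vanishing error flow.
`conventional_sigmoid` (the default) uses standard bounded sigmoid gates:
ReLU gates make the GRU interpolation coefficients unbounded and can
diverge on long unrolls, so the bounded form is the safer default. Both
modes are exercised by the gradient checks.

## The synthetic generator

`simulate_trialset()` emulates the class-dependent band-power modulation
that motor imagery produces, at 250 Hz. Each source location carries mu
and beta rhythms built by band-pass filtering white noise — realistic
non-sinusoidal rhythms whose bandwidth avoids ringing artifacts that pure
sinusoids would create in the analysis filter bank. Per trial, the
(source, rhythm) pairs listed for the trial's class are attenuated by
$1 - d$ (ERD depth $d$) during the imagery interval; 1/f background noise
(white noise shaped to a $-1$ spectral power slope) is added per channel,
and sources are mixed to channels by a configurable matrix.

The default configuration is a two-class, three-channel montage (C3-like,
Cz-like, C4-like): class 1 suppresses both rhythms at channel 1, class 2
at channel 3, with depth 0.6, rhythm standard deviation 1, noise standard
deviation 0.5, and 100 trials per class. The trial timeline follows the
standard cue paradigm — 7 s trials, cue at 2 s, imagery through 6 s — so
epoching at `[4, 6]` s captures modulated signal. Band power at the
modulated channel then differs between classes by a factor of about
$(1-d)^2 = 0.16$, which the test suite verifies with a periodogram
band-power oracle.

What the generator does *not* emulate: eye and muscle artifacts,
electrode drift and other nonstationarities, realistic head-model mixing,
inter-subject variability, and ERS (power increase; only suppression is
modelled). Tests passing on this generator therefore demonstrate that the
pipeline recovers class-dependent band-power structure under controlled
conditions, not that it attains any particular accuracy on recorded EEG.

## Numerical and design choices

* **Smoothing.** The causal moving average over `omega + 1` samples
  shrinks its divisor at the left edge so constants are fixed points and
  the onset is not attenuated; `omega = 0` is the identity. A historical
  variant that divides the same sum by `omega` is available behind
  `literal = TRUE` for comparison; it is dimensionally inconsistent
  (it rescales constants and is undefined at `omega = 0`) and is never
  the default.
* **Slice count.** Cropping offsets run from 0 to $T - \tau - 1$, giving
  exactly $T - \tau$ slices at stride 1 (500 samples, $\tau = 20$, gives 480).
* **Epoching.** Sample indexing is 0-based and epochs are half-open
  `[start, stop)` in samples, so a 2 s window at 250 Hz is exactly 500
  samples, independent of the event onset.
* **Filtering epochs vs recordings.** Filters can run on continuous
  recordings before epoching (preferred; no epoch-edge transients) or on
  epochs directly; tests sensitive to transients exclude the first and
  last 0.25 s.
* **CSP degeneracies.** Covariances are shrunk toward the scaled identity
  (`gamma`); a composite covariance that is still singular raises an
  error rather than returning garbage. Zero-variance feature rows are
  floored at machine epsilon before the log, with a warning.
* **Loss clipping.** Probabilities are clipped to `[1e-12, 1 - 1e-12]`
  inside the cross-entropy so perfect predictions stay finite.
* **Determinism.** Initialization, shuffling, dropout, splits and the
  generator all derive from explicit seeds; identical configuration and
  seed give bit-identical models and reports.
* **Containers.** Trial sets and trained models are stored as versioned,
  schema-validated native R serialization files; reads validate the
  schema and re-check every invariant, and round-trips are bit-exact.
  GDF recordings (the format of the common motor-imagery benchmark
  datasets) are imported through a subprocess bridge to Python's MNE
  when an interpreter is available, with EOG channels dropped by default
  since the analysis never uses them.
* **Signal-prediction mode.** The same cells can be trained with a linear
  multivariate head on (window, next-sample) pairs and run
  autoregressively, feeding predictions back as inputs — useful for
  checking how much sequential structure a given unroll depth captures.

## Problem sizes used by the tests

The test suite and the acceptance script run the full pipeline at the
generator's default study conditions (100 trials per class, 50/50
stratified split) with a 30-epoch, stride-24 training schedule that a
single CPU core completes in under a minute; the convergence comparison
between GRU and LSTM uses 20 trials per class over five seeds. These
sizes are the package's own choices for its reference experiments;
accuracy at the default ERD depth saturates near 100% well before 200
epochs, so the shorter schedule changes nothing but run time.

## Known limitations

* The RNN is a single recurrent layer unrolled over time; stacked layers
  and attention are out of scope.
* Training is plain R with BLAS matrix products — fine for the tens of
  feature rows and short unrolls this method uses, not for raw-EEG-scale
  deep learning.
* No artifact rejection, re-referencing or channel interpolation; inputs
  are assumed to be clean epoched trials.
* The mutual-information band-selection step of the full FBCSP family is
  intentionally absent: the fixed ten-band division is used for all
  subjects.
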