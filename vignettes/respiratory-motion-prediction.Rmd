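---
title: "Forecasting respiratory motion for latency compensation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting respiratory motion for latency compensation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respredict)
```

## The problem

Robotic tumour-tracking radiotherapy steers the treatment beam to follow a
breathing-induced target. Between observing the external breathing surrogate
and repositioning the beam there is a system latency — about 115 ms in
robotic tracking systems, i.e. three samples at the 26 Hz surrogate rate — so
the system must act on a *forecast* of the breathing amplitude rather than its
last observed value. `respredict` implements that forecasting layer end to
end: a breathing-signal simulator, chronological data partitioning,
latency-shifted supervised-window construction, seven recurrent network
architectures with a compact training engine, a grouped hyperparameter search,
and an evaluation suite (RMSE, MAE, NRMSE, a variance-ratio F-test and
box-plot statistics). Only the amplitude predictor is modelled; the
correlation model that maps external markers to internal target position, and
any on-line re-fitting during treatment, are out of scope.

## The breathing simulator

Clinical traces are not distributable, so every stage is exercised against a
simulator whose traces have the same coarse statistical structure. The
generative model is the standard analytic respiratory surrogate: a baseline
plus an amplitude-scaled even power of a cosine,

$$ y(t) = b + d\,t + A_k \cos^{2n}\!\big(\pi/2 + \pi u_k(t)\big) + \varepsilon(t), $$

where $u_k(t) \in [0, 1)$ is the phase within cycle $k$, each cycle draws its
own period and amplitude ($T_k \sim N(T, \sigma_T T)$,
$A_k \sim N(A, \sigma_A A)$, truncated positive), $d$ is a linear baseline
drift and $\varepsilon$ is white Gaussian sensor noise. Phase is mapped so the
profile is zero at both cycle edges, which keeps the trace continuous when
consecutive cycles have different amplitudes, and jitter acts per cycle — not
per sample — so cycles stay smooth. With all stochastic terms zeroed the trace
equals the closed-form profile on the sample grid, which is the oracle the
tests use.

Five qualitative regimes are encoded as documented presets
(`pattern_presets()`): steady breathing, and slow/rapid crossed with
increased/shallow depth. The numbers are the package's own choices, made once:
steady 4 s / 10 mm with no jitter, drift or noise (an idealised regular
breather, also used as the noiseless smoke-test signal); slow 5 s and rapid
2.5 s cycles; deep 15 mm and shallow 5 mm excursions; 8–12% cycle jitter,
\(\pm\)0.15–0.3 mm/min drift and 0.1 mm sensor noise for the non-steady
regimes. These bracket typical thoraco-abdominal excursions. The default
cohort duration range is 1380–3600 s, matching the 23–60 min clinical
recordings, and the default sampling rate is 26 Hz throughout (overridable).

What the simulator deliberately does **not** reproduce: cardiac or other
mixed-frequency components, hysteresis and 3-D trajectories (a single scalar
channel is predicted), apnoea or cough events, and patient-specific spectral
detail. Passing tests on simulated cohorts therefore demonstrate that the
pipeline and models behave correctly and that relative orderings (e.g.
accuracy degrading with horizon) hold — not that the absolute millimetre
errors of clinical traces are reproduced.

## From signal to supervised set

Amplitudes are min–max normalized to [0, 1] before training. The normalizer
is fitted on the **training segment only** and reused for validation and
test, preventing leakage; out-of-range values in later segments are extended
affinely, not clipped, so errors denormalize faithfully back to mm. Whether to
normalize per signal or per patient is not fixed by convention; the package
normalizes per signal.

Each signal is split chronologically 35% / 5% / 60% into train / validation /
test — training earliest, which is the only causally valid layout for
forecasting. Segment lengths are `floor(frac * L)` for train and validation
with the remainder to test; on tiny inputs an empty validation segment is
returned with a warning rather than an error.

Supervised pairs are built per segment (never across a split boundary) by an
input-sliding window: pair $i$ (0-based) has input
$x_{i} \ldots x_{i+W-1}$ and target $x_{i+W+h-1} \ldots x_{i+W+h+O-2}$, where
$W$ is the input window, $O$ the output window and $h \ge 1$ the horizon in
samples. The pair count is $L - W - h - O + 2$, verified exhaustively against
enumeration. The horizon models the system latency;
`latency_to_samples(115, 26)` gives 3. The tuning table's latency values
(1, 5, 10, 15) are read as horizons in samples — the only reading consistent
with the windowing framework — and the selected value 1 (~38 ms) is kept
alongside the 115 ms bridge; both configurations are supported and neither is
asserted as "the" clinical setting. Similarly, a 30-sample input window is
reported as performing well at higher latency while the tuned table recommends
50; both remain available presets and the package does not resolve that
tension.

## The seven architectures and the training engine

Simple RNN, LSTM, GRU, their bidirectional variants and a CNN-LSTM are built
by `build_model()`. No deep-learning framework is involved: the cells,
backpropagation through time, eight optimizers (SGD, Adam, Adamax, Nesterov
Adam, Adagrad, Adadelta, RMSprop, FTRL) and four losses (MAE, MSE, Huber,
LogCosh) are implemented in the package, with the batched forward/backward
kernels in compiled code. Analytic gradients for every architecture, head and
activation were verified against central finite differences, and a slower
layerwise R implementation of the same network is kept as an independent
reference path that the compiled path is tested against.

Design choices where the architecture descriptions were open:

* Gate activations are fixed logistic sigmoids; the tunable *hidden*
  activation (11 options, Swish through Linear) applies to the cell candidate
  (and, for LSTM, the cell-state output transform) — the conventional cell
  definition. Output activations are restricted to Linear, Sigmoid, Swish and
  Softsign; Softmax is rejected for scalar regression.
* No dropout. The CNN-LSTM's feature stage is one width-3 valid convolution
  with `units_per_layer` filters followed by width-2 max-pooling. `n_layers`
  counts recurrent layers only; the conv stage is fixed and uncounted, since
  the recommended CNN-LSTM has `n_layers = 1` and counting the conv stage
  would leave no recurrent layer at all.
* Bidirectional layers run the cell over the window in both directions and
  concatenate features; the prediction head receives both directions'
  full-pass final states.
* Two multistep heads: the *vector* head emits all $O$ outputs in one dense
  projection; the *encoder–decoder* head repeats the encoder's final state as
  input to a decoder cell of the same family for $O$ steps, each step
  projected to one value — the standard recurrent sequence-to-sequence
  forecasting idiom. For $O = 1$ they differ only in parameterization.
* Weights are Glorot-uniform with an explicit seed (LSTM forget-gate biases
  start at 1), so identical `(spec, seed)` builds are bitwise identical and
  training is fully reproducible.
* Training runs exactly the configured number of epochs (no early stopping),
  shuffled minibatches, loss on the normalized scale. Weights are frozen after
  training: prediction is a pure function and never updates the model. A run
  whose loss becomes non-finite is returned with status `"diverged"` — large
  learning rates under SGD/FTRL can legitimately diverge — so hyperparameter
  sweeps record a failed trial instead of crashing.
* Metrics are always computed after denormalizing predictions and targets to
  mm, because that is the scale on which errors are clinically meaningful.

`recommended_config()` stores the per-architecture tuned configurations
(input window 50, output window 1, horizon 1, encoder–decoder head, Adam, and
per-architecture depth/width/activations/learning rate/epochs/batch/loss).

## The grouped hyperparameter search

A full factorial sweep over the 13 domains (learning-rate list deduplicated
from a printed repeat to 6 unique values; hidden and output activations kept
as separate domains even though study summaries count them as one "activation"
variant) would be astronomically large. The grouped (nonsequential-correlated)
search instead resolves small groups of correlated hyperparameters in order,
each by a full grid or a seeded uniform random sample without replacement,
carrying each group's winner forward. The named pairings are groups A
{loss, optimizer} (grid), B {optimizer, learning rate} (random) and C
{layers, units} (grid); the remaining pairings — {epochs, learning rate},
{batch, optimizer}, {latency, input window}, {hidden activation, optimizer},
{multistep, epochs}, plus singletons for output activation and output window —
are a documented default reflecting the reported interactions, and the whole
plan is overridable. The plan's full group composition is the package's own
default, not a reproduced figure.

When a hyperparameter reappears in a later group, the first winner is frozen
and the later group searches only its unresolved parameters; group B therefore
searches the learning rate alone once group A has fixed the optimizer. The
objective is the seed-averaged validation RMSE in mm (validation, not test, to
avoid leakage); diverged trials score $+\infty$; ties break to the first
configuration in domain enumeration order (the first listed parameter varies
fastest), making the whole search deterministic. Every evaluated configuration
appears in the trial ledger exactly once per seed, and an all-failed group
aborts the plan with the ledger intact. The default is 10 trials per
configuration; the total trial count is reported rather than forced to match
any external figure, since the decomposition of a global search budget across
groups is not derivable. For separable objectives whose optimum is reachable
within the groups, the grouped search provably returns the global optimum —
the property the tests verify on rigged objectives.

## Evaluation

For ground truth $Y$ and predictions $\hat{Y}$ over $N$ points (in mm):

$$ \mathrm{RMSE} = \sqrt{\tfrac1N \textstyle\sum_i (Y_i - \hat{Y}_i)^2}, \quad
   \mathrm{MAE} = \tfrac1N \textstyle\sum_i |Y_i - \hat{Y}_i|, \quad
   \mathrm{NRMSE} = \frac{\mathrm{RMSE}}{Y_{\max} - Y_{\min}}, $$

with the NRMSE denominator taken from the ground-truth extrema of the
evaluated segment, making the score scale-free across breathing amplitudes.

The statistical test accompanying the reports is described in the source
literature only loosely ("between the RMSE of the real value and the RMSE of
the predicted value"), which is not a standard construction. The package's
reading — a decision, recorded here — is the classical two-sample
variance-ratio F-test between the ground-truth and predicted series:
$F = s^2_Y / s^2_{\hat{Y}}$ with $n-1$ degrees of freedom each and a two-sided
p-value, i.e. a check that the forecast reproduces the variability of the real
signal. It matches `stats::var.test` (used in the tests as an independent
cross-check, never as the implementation) and holds its nominal 5% size under
the null by Monte-Carlo.

Box-plot statistics use inclusive linear-interpolation quartiles
(`quantile` type 7 — the convention had to be fixed, as quartiles are
convention-dependent), whiskers at the most extreme non-outlier points, and an
outlier rule of more than 2.7 sample standard deviations from the mean.
Cohort summaries are the mean ± SD of per-signal metrics; per-patient
weighting is not attempted because no patient-to-signal mapping is defined
for simulated cohorts. Relative improvement between two error levels is
$100\,(e_{\mathrm{ref}} - e)/e_{\mathrm{ref}}$.

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run at desk scale, chosen once:
a 5-minute steady trace for the noiseless forecasting smoke check (tuned GRU,
epochs reduced to 100, one-step test RMSE < 0.02 normalized, averaged over 3
seeds); a five-signal jittered cohort at 150–200 s per signal, 3 seeds and 20
epochs for the horizon-degradation ordering (h = 15 vs h = 1); five signals of
90–120 s at 30 epochs for the full seven-architecture pipeline report; and
analytic (training-free) objectives for the search-plan checks. Training for
hundreds of epochs on 23–60 min traces, as in a full study, uses the same code
paths unchanged — only the configured sizes differ.

## Known limitations

* The simulator's realism bounds what simulated cohorts can show (above);
  absolute clinical error levels require clinical traces, supplied as CSV
  files via `read_signal()`.
* The search plan's group list beyond the named A/B/C pairings is a default,
  and freezing first winners means later groups never revisit an early
  choice; a parameter whose optimum depends on a later group's winner can be
  missed — the documented trade-off of the grouped strategy.
* No Bayesian optimization, Hyperband or early stopping; trials are
  independent and schedulers are out of scope.
* No transformer/attention models, no multi-channel or 3-D targets, and no
  on-line weight updates during prediction.
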