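---
title: "Neural Granger causality with bidirectional LSTM regressors: models, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural Granger causality with bidirectional LSTM regressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilstmgc)
```

## The statistical model

Granger causality (GC) declares a directed dependency $i \rightarrow j$ when
the history (here: the context) of channel $i$ reduces the prediction error
of channel $j$ beyond what every other channel, including $j$ itself,
already provides. The package quantifies this with the classical log
error-variance ratio

$$ F_{i \rightarrow j} \;=\; \max\!\Big(0,\; \ln \frac{\mathrm{err}_{\text{restricted}}}{\mathrm{err}_{\text{full}}}\Big), $$

where both errors are *held-out* mean-squared prediction errors of a
regression of $j$'s value at position $t$ on context windows of all
channels (full) or all channels with $i$ removed (restricted). Four
regression engines stand behind one interface:

* **bi-LSTM-GC** — a stacked LSTM pair reading the window forwards and
  backwards, able to exploit both past and future samples;
* **RNN-GC** — a unidirectional LSTM on past-only windows;
* **NN-GC** — a one-hidden-layer feed-forward network on a *flattened* lag
  window (`n_channels * model_order` inputs, hidden size two thirds of
  that, rounded up), deliberately discarding temporal structure;
* **linear_gc_oracle** — ordinary-least-squares vector autoregression, the
  textbook linear statistic, used as a fast reference and cross-check.

The LSTM cell follows the standard gate recurrence (input, forget, output
gates and candidate cell, sigmoid and tanh nonlinearities); `lstm_step()`
exposes a single update in plain R, and the compiled engine reproduces it
bit-for-bit (a tested invariant).

## Window design: what the bidirectional model is allowed to see

Bidirectional windows are centred on the prediction position $t$: $k$ past
samples and $k$ future samples with the centre excluded
(`max_sequence_length` = $2k$, default 20). Two choices here are load-bearing:

* **The target's own future is masked.** If the regression may see
  $x_j(t\pm1), x_j(t\pm2), \dots$, predicting $x_j(t)$ degenerates into
  interpolation: the full and restricted models become nearly equally good
  and every error ratio collapses towards zero. With the target's future
  masked, the model still forecasts $j$ from its own past plus the
  two-sided context of the other channels, which is the bidirectional
  Granger contract.
* **Other channels' futures are kept.** This is what makes *forward*
  dependencies (a channel determined by another channel's future samples,
  as in benchmark model C) detectable at all; a past-only window provably
  cannot separate them from ordinary autoregressive structure.

### The price of acausal context: lag-reversed duals

Keeping other channels' futures has an unavoidable consequence. A single
coupling $x_i(t-\ell) \rightarrow x_j(t)$ is one statistical dependence
between two time-shifted series; an acausal regression sees it from both
ends. In the model for target $j$ it appears as "past of $i$ helps"
(the true edge); in the model for target $i$ it appears as "future of $j$
helps" — a **lag-reversed dual** that populates the matrix cell
$j \rightarrow i$. The two readings are the *same* coupling, and no
detector working from the joint distribution alone can suppress the dual
while keeping genuine forward dependencies: a backward edge read in
reverse and a forward edge have identical observational signatures. The
package therefore reports both cells when both are statistically
significant, and this vignette — rather than the detector — is the place
where that limitation is stated. On the linear benchmarks the duals of the
strong backward edges (e.g. $2\rightarrow1$, $3\rightarrow1$,
$4\rightarrow1$ in models A/B) are the expected extra detections.

## Restriction modes

`gc_config(restriction =)` controls how the restricted model is formed:

* `ablate_input_at_inference` (default): the trained full model is
  evaluated with the source channel's standardized input stream zeroed.
  This measures *reliance* — whether the trained network actually uses the
  channel — at essentially no extra cost, which is what makes ten-trial
  averaging affordable.
* `retrain_without_channel`: the engine is refitted without the source
  channel. This measures *irreplaceability*, the stricter and more
  classical Granger reading: a channel whose information is duplicated
  elsewhere (a common situation in the benchmarks, where several channels
  share one driver) scores near zero because the refitted model re-routes
  through the remaining channels. The two modes answer different
  questions, and the benchmark comparisons that contrast the bidirectional
  and unidirectional engines use the retrain mode, because the
  unidirectional engine's *inability* to see forward dependencies only
  manifests when its restricted model is allowed to re-learn.

## Edge detection and its two nulls

`detect_edges()` compares each pair's trial-averaged score against nulls
at level `alpha` (default 0.05):

* **Circular-shift surrogates.** The source channel is rotated by a random
  offset of at least the context length, destroying cross-channel coupling
  while preserving its autocorrelation, and the score is recomputed
  against the trained full model. Under no coupling the real channel is
  exchangeable with its rotations, so the permutation p-value
  $(1 + \#\{\text{surrogate} \ge \text{observed}\})/(n+1)$ is valid.
  Surrogate draws are single-trial while the observed statistic is a
  trial average, which makes the test deliberately conservative for null
  pairs.
* **Cross-trial consistency (retrain mode, ≥ 3 trials).** Each trial uses
  a fresh training seed (and a fresh realisation for simulator inputs), so
  the per-trial signed scores of a pair are independent draws carrying all
  noise sources — training stochasticity included. A one-sided t-test of
  these draws against zero asks whether the dependency is *consistently*
  positive. Under the retrain restriction null scores centre at or
  slightly below zero (a restricted model has fewer inputs to overfit), so
  the test is valid and mildly conservative. It is also selective in a
  useful way: genuine direct couplings produce stable scores across
  trials, while lag-reversed duals — which require the network to learn a
  noisy multivariate inversion — fluctuate strongly and often fail the
  consistency requirement.
* **Training-noise replicates (retrain mode, < 3 trials).** With too few
  trials for the consistency test, the engine refits `n_null_replicates`
  extra *full* models per target and trial; their log error ratios against
  the original full model estimate the training-noise scale (per target,
  shrunk towards the pooled value) and a normal tail supplies the
  p-value.

The final p-value of a pair is the maximum over the applicable nulls.

Both the raw averaged matrix and the thresholded edge set are returned;
which of the two a figure shows is a presentation choice, so the package
produces both.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `hidden_units` | 10 | LSTM units per layer; the benchmark configuration. |
| `max_sequence_length` | 20 | Total context (samples); covers the longest benchmark delay (10). |
| `depth` | 1 | Stacked layers. Deeper stacks are supported, but at a few thousand training windows a 3-layer bidirectional stack memorises the training windows and loses the weak-edge contrast on held-out data; one layer generalises measurably better here. |
| `epochs` / `patience` | 60 / 12 | Adam epoch cap with early stopping on a validation split (the latest 20% of training windows); most fits stop well before the cap. |
| `learning_rate` | 0.01 | Adam step size, halved after every 4 epochs without validation improvement (floor 1e-3); the plateau schedule keeps run-to-run variability of the fitted error low, which matters because the training-noise null scales with it. |
| `n_null_replicates` | 2 | Extra full-model refits per target and trial under the retrain restriction, feeding the training-noise null. |
| `batch_size` | 256 | Minibatch size. |
| `weight_decay` | 1e-3 | Decoupled L2 on the weight matrices. |
| `model_order` | 5 (7 for model C) | Lag window of the flattened-input and linear engines. |
| `n_trials` | 10 | Independent trials averaged into the matrix; each trial redraws the training seed, and a fresh realisation when the input is a `sim_spec()`. |
| `holdout` | 0.2 | Tail fraction for error evaluation; held-out errors avoid overfit-driven negative log ratios. |
| `alpha`, `n_permutations` | 0.05, 99 | Detection level and surrogate draws per pair. |

Channels are standardized (centered, unit variance) before training; GC
uses error ratios, so no inverse transform is needed.

## The benchmark generators

`simulate_gc_benchmark()` reproduces three ground-truthed generators:
model A (five channels, linear lagged couplings, a resonant AR(2) driver
with coefficients 0.952/−0.9025), model B (as A, but $1\rightarrow2$
becomes quadratic with a 10-sample delay), and model C (B plus two forward
channels driven by future samples of $x_1$, $x_4$, $x_5$). Study
conditions follow the printed recursions: unit-variance zero-mean Gaussian
innovations, series lengths 5000 (A/B) and 5020 (C), dependency
coefficients as printed. Choices the recursions leave open:

* **Initial conditions and burn-in.** All channels start at zero and 100
  burn-in samples are discarded, so the returned window is near-stationary
  (the AR(2) roots have modulus 0.95; transients decay well within 100
  samples).
* **Model C terminal fill.** The forward channels depend on future
  samples, so their *last* two samples have no source available; they are
  drawn standard-normal and the count is recorded. (The original
  description speaks of the *first* points; dependence on the future
  breaks at the end of a series, so the end-fill reading is implemented.)
* **Noise streams.** Read literally, model C reuses the innovations of
  $x_2$ and $x_4$ inside $y_1$ and $y_2$, which would add instantaneous
  correlations on top of the lagged couplings. The default draws
  independent streams; `noise_spec(stream_policy = "shared_as_written")`
  reproduces the literal reading. Both are tested.
* **Orientation of forward edges.** The ground-truth tables orient a
  forward dependency as source $\rightarrow$ dependent channel with a
  negative lag ($x_1 \rightarrow y_1$, lag −2): the edge belongs to the
  equation that *contains* the other channel. The dual reading
  ($y_1 \rightarrow x_1$ at a positive lag) is the same coupling; see the
  duality discussion above.

## The EEG chain

* **Band filters.** Order-10 Chebyshev type-I bandpass filters (0.5 dB
  passband ripple) for delta 0.5–3, theta 4–7, alpha 8–13, beta 13–30 and
  gamma 31–50 Hz, applied forward–backward for zero phase. The design is
  carried out in zero-pole-gain form and applied as second-order sections:
  an order-10 bandpass has 20 poles, and at EEG band edges the expanded
  transfer-function polynomial is numerically unusable (delta at 1 kHz
  places poles at radius ≈ 0.999), so polynomial-form filtering is not an
  implementation option here. The cascade's response is checked against
  the analytic Chebyshev magnitude curve in the tests. One consequence of
  zero-phase filtering deserves flagging: the forward–backward pass is
  acausal, leaking a little of each channel's future into its present, so
  directed estimates on band-filtered data can show spurious
  reverse-direction companions of genuine couplings. This is a known
  property of two-pass filtering, shared by any pipeline that filters
  before causal analysis.
* **Stationarity preprocessing.** Per channel: linear detrend, demean,
  then an augmented Dickey–Fuller unit-root test (constant-only
  regression, large-sample critical values, lag order $\lfloor (n-1)^{1/3}
  \rfloor$). Channels that fail are first-differenced once and re-tested;
  channels still failing carry a reject flag, mirroring the exclusion of
  recordings that do not meet stationarity criteria.
* **Montage.** The extended 10/20 layout with 34 electrodes in 10 regions
  ships as a packaged table; label matching is case-insensitive because
  both `Pz`/`PZ` spellings occur in practice.
* **Connectivity on filtered data.** A band-filtered series is heavily
  oversampled at the recording rate: neighbouring lags correlate above
  0.99, least squares becomes ill-conditioned, and one-step prediction
  degenerates into smooth extrapolation that buries directed information.
  Two measures keep the per-segment estimates meaningful: the linear
  engine solves its regressions by truncated SVD (relative tolerance
  1e-4; identical to OLS on well-conditioned designs), and
  `segment_connectivity()` decimates after the zero-phase bandpass
  (`decimate = "auto"` keeps the band's high edge below half the new
  Nyquist). Even so, narrowband segments carry roughly `2 x bandwidth x
  duration` effective degrees of freedom, so per-segment strengths are
  noisy for short segments — hence the 60 s default segment length of the
  cohort generator.
* **Stable dependencies.** Records are grouped by (source, target, band).
  The occurrence count is the number of (subject, segment) units where the
  edge was *detected*; the group's strengths are the **signed** log error
  ratios of all units, tested against zero with a one-sample, one-sided
  (greater) t-test. Both choices matter: floored scores are nonnegative by
  construction, so a t-test on them would reject for almost any group; and
  signed ratios of null pairs centre slightly *below* zero (the full
  model's extra inputs cost it held-out accuracy), so a two-sided test
  rejects on the wrong side for large cohorts while the one-sided test —
  which matches the directional hypothesis that a dependency *increases*
  the restricted error — stays calibrated. Both behaviours are tested
  invariants. "More than 10 occurrences" is read strictly (`> 10`). No
  multiple-testing correction is applied by default, matching the stated
  p < 0.05 + occurrence rule; a Benjamini–Hochberg option exists.
* **Synthetic cohorts.** `synthesize_eeg_cohort()` generates AR(1)
  background activity per electrode plus band-limited, lagged, linear
  couplings on planted edges, with ground truth attached. It emulates
  autocorrelated band-limited signals with known directed couplings; it
  does **not** emulate volume conduction, shared reference artifacts,
  eye-blink/muscle contamination, or nonstationary drift — so a passing
  recovery test demonstrates that the pipeline's statistics work, not that
  real scalp recordings would behave as cleanly.

## Numerical choices and degenerate inputs

Constant target channels are an error (nothing to predict); a full model
with numerically zero held-out error raises a perfect-fit condition rather
than returning an infinite ratio. Boundary positions without complete
context are dropped, not padded. Training windows are capped (default
1600, evenly subsampled) and evaluation windows capped at 256; the caps
are package defaults chosen so a full benchmark matrix fits in minutes on
one core, and they are stated here rather than hidden. All randomness
derives from one root seed through named substreams (simulate / train /
replicate / permute / cohort), so stages are independently reproducible
and a fixed seed gives bit-identical simulator output.

## Scales used by the shipped checks

The test suite and the acceptance script run the full protocol at sizes
chosen to keep a complete run on one core in the tens of minutes: the
linear-oracle benchmark at the printed length 5000 over ten seeds; the
bidirectional engine's full model-B matrix at length 2000 with five
trials; the model-C forward-dependency comparison at the printed length
5020 with four trials, estimating only the two forward-channel targets;
cohort recovery with 25 subjects × two 60 s segments at 128 Hz over ten
cohort seeds plus a null cohort. All comparison runs use the retrain
restriction (the strict classical reading) under one shared protocol.
These are the package's own choices of desk-scale problem sizes.

## Known limitations

* The lag-reversed-dual ambiguity of acausal context windows is
  fundamental, not an implementation artifact; expect dual detections for
  strong backward couplings whenever the bidirectional engine is used.
* Neural GC scores carry training noise; with few trials the
  training-noise null costs power for weak couplings. The linear oracle
  has no such noise and is the right tool for linear questions.
* Conditional GC is limited to remove-one-channel restrictions; no
  spectral GC, no transfer entropy.
* The EEG chain is exercised on synthetic cohorts only; acquisition-file
  parsing and artifact rejection are out of scope.
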