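# bilstmgc

Directed ("effective") connectivity estimation for multichannel time
series — EEG in particular — by **neural Granger causality**: the
autoregressive predictors of classical Granger causality are replaced by
LSTM sequence regressors, including a **bidirectional** variant
(bi-LSTM-GC) that reads context on both sides of the prediction position
and can therefore detect *forward* dependencies, where one channel is
driven by another channel's future samples. The package is aimed at
researchers analysing directed information flow between signal channels
(EEG electrodes, neural populations, coupled dynamical systems) who need
estimators that go beyond linear vector autoregression.

## The statistic

Channel *i* Granger-causes channel *j* when removing *i* increases the
prediction error of *j* given everything else. The package scores every
ordered pair with the classical log error-variance ratio

```
F(i -> j) = max(0, ln( err_restricted / err_full ))
```

where both errors are held-out mean-squared errors of a regression of
`x_j(t)` on context windows of all channels (full) versus all channels
without *i* (restricted). Four interchangeable engines fit the
regression:

| Engine | Context | Model |
|---|---|---|
| `bilstm_gc` | past **and** future (target's own future masked) | stacked bidirectional LSTM |
| `rnn_gc` | past only | unidirectional LSTM |
| `nn_gc` | past only, flattened | one-hidden-layer feed-forward net (hidden = ⌈2/3 · input⌉) |
| `linear_gc_oracle` | past only | ordinary-least-squares VAR |

Edges are declared against circular-shift surrogate nulls (plus a
training-noise null when restricted models are retrained); see the
methods vignette (`vignettes/neural-granger-causality.Rmd`) for the model,
its assumptions, and the design decisions.

Three ground-truthed benchmark generators ship with the package: a linear
five-channel network (model A), a nonlinear variant with a 10-sample
delayed quadratic coupling (model B), and a seven-channel variant with two
forward-dependent channels (model C). An EEG post-processing chain
(order-10 Chebyshev type-I band filters, stationarity preprocessing,
extended 10/20 montage mapping, stable-dependency extraction, region-level
flow summaries) completes the pipeline, exercised on synthetic cohorts.

## Worked example

Simulate the linear benchmark, estimate the dependency matrix with the
classical linear engine, and detect edges:

```r
library(bilstmgc)

cfg <- gc_config("linear_gc_oracle", model_order = 5, n_trials = 10,
                 restriction = "retrain_without_channel", seed = 1)
det <- detect_edges(estimate_gc(sim_spec("A", n = 5000), cfg))
tidy(det)[tidy(det)$detected, c("source_label", "target_label", "score", "p_value")]
#> # A tibble: 5 x 4
#>   source_label target_label  score p_value
#>   <chr>        <chr>         <dbl>   <dbl>
#> 1 x1           x2           0.422     0.01
#> 2 x1           x4           0.384     0.01
#> 3 x1           x3           0.148     0.01
#> 4 x5           x4           0.0761    0.01
#> 5 x4           x5           0.0605    0.01

score_detection(det, ground_truth_edges("A"))
#> # A tibble: 1 x 7
#>   n_true n_detected true_positives false_positives false_negatives recall precision
#>    <int>      <int>          <int>           <int>           <int>  <dbl>     <dbl>
#> 1      5          5              5               0               0      1         1
```

All five printed dependencies (1→2, 1→3, 1→4, 4→5, 5→4) are recovered
with no false detections: each detected pair's score is the trial-averaged
log error ratio and `p_value` its circular-shift permutation p-value. The
neural engines run through the same interface
(`gc_config("bilstm_gc", ...)`), and `autoplot()` on the results draws the
dependency-matrix heatmap. A command-line front end covering
simulate/filter/estimate/detect/stable-edges/summarize-regions/run lives
at `inst/cli/bilstmgc`.

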