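---
title: "Forecasting daily Health Improvement Scores from wearable streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting daily Health Improvement Scores from wearable streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hisforecast)
library(dplyr)
library(ggplot2)
```

## The problem

A Health Improvement Score (HIS) is a daily self-report, on a 1–10 Likert
scale, of how much a person feels their health has improved under a
training or physical-activity program. Modern wearables record, alongside
it, a multi-domain stream of daily measurements: physiological channels
(resting and active heart rate, heart-rate variability, SpO₂, respiration,
body temperature), activity channels (steps, intensity, distance, energy,
posture time), sleep structure (duration, phase fractions, interruptions)
and body metrics (weight, BMI). `hisforecast` predicts the next day's HIS
from the preceding week of these channels, and attributes each prediction
to the days that drove it.

The model is a sequence-to-one regressor:

* a stack of `L` LSTM layers encodes a window
  $\mathbf{X} = \{x_1, \dots, x_T\}$ of daily feature vectors through the
  recurrence $h_t = \mathrm{LSTM}(x_t, h_{t-1}, c_{t-1})$;
* temporal attention scores each top-layer state against the final state,
  $\alpha_t = \mathrm{softmax}_t\!\left(h_t^\top W_a\, h_T\right)$, and
  forms the context $c = \sum_t \alpha_t h_t$;
* a dense head produces the prediction $\hat{y} = \sigma(W c + b)$;
* training minimizes a composite loss
  $\mathcal{L} = \frac{1}{N}\sum_i (y_i - \hat{y}_i)^2 +
  \lambda\,\frac{1}{T'-1}\sum_t (\hat{y}_t - \hat{y}_{t+1})^2$, mean
  squared error plus a temporal-smoothness penalty on consecutive
  predictions.

All of this — forward pass, analytic backpropagation, Adam, DropConnect —
is implemented directly in R on batched BLAS matrix operations, so every
quantity down to individual gate activations and attention gradients is
inspectable and unit-tested against independent hand-executed oracles.

## Model assumptions and defaults

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `n_layers` | 5 | count | depth selected by the tuning grid (3–6); desk-scale examples use 1–2 |
| `hidden_size` | 128 | units | grid midpoint {64, 128, 256} |
| `dropout_rate` | 0.2 | prob. | inter-layer dropout |
| `dropconnect_rate` | 0.2 | prob. | element dropout on recurrent weight matrices, rescaled by $1/(1-p)$ |
| `lambda` | 0.1 | unitless ≥ 0 | smoothness weight; no canonical value exists, so the suite verifies *monotone smoothing in λ* rather than a fixed constant |
| `T` | 7 days | window | weekly context with daily stride is the common wearable convention; 32 days then yield 25 windows per participant |
| `H` | 1 day | horizon | one-step-ahead forecasting |
| learning rate / batch | 0.001 / 64 | — | Adam defaults from the tuning grid |
| patience | 10 epochs | — | early stopping on validation loss; best-epoch weights are restored |

Decisions the architecture leaves open, and how this package resolves
them:

* **Scalar vs. sequence output.** The head emits an `H`-step vector. With
  the default `H = 1`, the smoothness term is computed across
  time-consecutive windows of the same participant inside a batch
  (batches are assembled participant-contiguous and time-ordered to make
  this well-defined); with `H ≥ 2` it runs along each window's own
  prediction steps.
* **Output activation.** `identity` by default — standard for regression
  on normalized targets; `scaled_sigmoid` is available since targets live
  in $[0,1]$ after scaling.
* **Attention query.** The final top-layer state $h_T$, with the query
  step itself included in the softmax. There is no learned query vector.
* **$W_a$ initialization.** Identity plus small noise, so attention
  starts as plain dot-product similarity against $h_T$ and can only
  sharpen; a zero-mean random start wastes early epochs diluting recent
  information across the window.
* **LSTM initialization.** Uniform fan-in input weights, orthogonal
  recurrent blocks per gate, forget-gate bias 1 — standard practice,
  fixed per seed.
* **Cell state vs. context.** The symbol *c* conventionally denotes both
  the LSTM cell state and the attention context; they are distinct
  objects here (`encoder_state$layers[[l]]$c` vs. the context vector).

## The target scale

HIS is trained on the fixed affine scale $(y-1)/9 \in [0,1]$ and every
reported metric (MAE, RMSE, R², EVS, MBE) is computed after inverting back
to the 1–10 scale — error magnitudes on the normalized scale would be
meaningless to a practitioner. Wearable channels are min–max normalized
with extrema estimated **on the training split only** and clipped
application to validation/test; whether split-wise or global statistics
are the convention for this kind of study is genuinely ambiguous, and the
train-only choice is the one that cannot leak.

## What the synthetic cohort emulates

No public dataset accompanies this problem, so the package ships a seeded
generator whose defaults define the study conditions: 384 participants,
32 days, 21 channels, a 1–10 HIS (sex mix ≈ 207:177, mean age 37).
Its generative structure:

* **Population trajectory.** `latent_his_trajectory()` rises at 0.12
  HIS/day, dips by 0.5 around day 14 (an adaptation slump), then recovers
  at 0.12 HIS/day with exponentially saturating increments
  (`plateau_strength` 0.08/day) — initial improvement, a slight decline,
  then a resumed climb with diminishing gains. The dip is a linear
  one-day descent rather than a Gaussian bump so that two properties hold
  exactly for any positive depth: the trajectory at the dip day is below
  the previous day, and post-dip increments are strictly non-increasing.
* **Individual level.** A participant intercept (sd 0.4 HIS) plus an
  AR(1) daily "wellness" process (ρ = 0.7, sd 0.6) shared between the
  channels and the self-report (gain 0.8 HIS/unit): good days cluster,
  and the wearable channels observe them.
* **Channels.** Physiologically signed couplings (resting HR falls ~2
  bpm per latent HIS unit, HRV and steps rise, etc.) with per-channel
  Gaussian noise in natural units; sleep-phase fractions renormalized to
  sum to one; SpO₂ clipped to [85, 100].
* **Acute strain events.** With probability 0.08 per participant-day, an
  overexertion/poor-recovery day occurs: heart rate, respiration,
  temperature and sleep disruption jump on the day itself, while HIS is
  depressed with a delayed lag profile peaking 3 days later (the 48–72 h
  delayed-onset-fatigue window). These events are what make *when*
  something happened inside a window matter — the informative day is
  mid-window, not the most recent one.
* **Likert reporting.** Self-report noise sd 0.5; values are clipped to
  [1, 10] and real-valued by default (`round_his = TRUE` mimics integer
  reporting).
* **Missingness.** Uniform at random over channel cells (default 5%),
  never on HIS itself; records over the 20% exclusion threshold are
  dropped strictly (> 0.20), the rest forward-filled with head-backfill.

What it deliberately does **not** model: circadian or device noise
structure, informative missingness, demographic effects on the
trajectory (demographics are sampled but inert), floor/ceiling response
styles. Passing tests on this cohort therefore demonstrate that the
machinery learns the kind of structure such studies describe — not that
it would achieve any particular accuracy on a real cohort.

```{r cohort, fig.width = 6, fig.height = 3.5}
cohort <- generate_cohort(synthetic_config(n_participants = 48, seed = 1))
autoplot(cohort)
```

## Numerical choices

* **Gradients.** Backpropagation through the full stack (loss → head →
  attention → LSTM layers) is hand-derived; the test suite verifies every
  parameter's gradient against central finite differences (relative error
  ≤ 1e-4) in eval mode and under fixed regularization masks in train
  mode.
* **Softmax** is computed with row-max subtraction; degenerate inputs
  (non-finite states) are rejected rather than propagated.
* **Constant channels** min–max-map to 0; supplied scalers with
  `min = max` on a non-constant channel are an error.
* **Grid-search ties** break toward fewer parameters, then earlier
  enumeration order; a failed fit is recorded in the leaderboard with
  `NA` loss, never fatal.
* **Determinism.** Every stochastic step (cohort, masks, shuffles,
  splits) flows from explicit seeds through one RNG-restoring helper;
  eval-mode prediction is a pure function of (input, parameters). The
  pipeline derives per-stage sub-seeds from one root seed so stages are
  independently reproducible.
* **Early stopping** uses strict improvement (`min_delta = 0`) and
  restores best-epoch weights; validation loss includes the λ term so
  model selection optimizes the training objective.

## Desk-scale problem sizes

The shipped tests and the acceptance script run everything on reduced
problem sizes chosen to finish comfortably on a single CPU: cohorts of
16–64 participants, hidden sizes 6–16, one or two LSTM layers, and a few
dozen training epochs. These sizes were picked once as the smallest at
which each qualitative claim (signal learnability, smoothing
monotonicity, attention recovery, model ranking) is stably observable;
the full-scale defaults (384 participants, 5 × 128 network) remain the
package defaults for real use.

## Evaluation protocol

Per-participant metric distributions on held-out participants are the
comparison unit: predictions are inverted to the 1–10 scale, grouped by
participant, and each participant contributes one MAE/RMSE/R²/EVS/MBE
row — the population a comparison boxplot summarizes. The split is by
participant (70/15/15), never by window, so overlapping windows of one
person cannot straddle train and test. Error sign is `predicted −
actual`, so positive MBE is over-prediction. Baselines run under one
adapter contract: `persistence` (last observed HIS), `linear_ar`
(least-squares on the last *p* HIS values — a univariate stand-in for
classical single-series models), and `lstm_plain` (the same network with
attention ablated to $h_T$ and λ = 0). Published baseline families
(ARIMA, SARIMA, SVR, GRU, CNN-LSTM) attach through the same contract via
`predict_fn` when an implementation is available; their internals are
intentionally not re-implemented here.

Beyond-horizon forecasting rolls the model forward day by day. HIS is a
target, not an input channel, by default, so predictions do not feed
back; future covariates are supplied by recycling the participant's last
`T` observed days cyclically. Building windows with `include_his = TRUE`
adds the day's own HIS as an input channel and switches the rollout to
autoregressive-HIS mode, where each prediction becomes the next day's
`his_lag` input. This is the weakest link for long horizons — recycled
covariates freeze the participant's state — and both per-participant and
cohort-mean views of the trajectory are exposed because which of the two
a trend figure should show is itself ambiguous.

## Known limitations

* Training is single-threaded pure R; the full 384 × 32 cohort with the
  5 × 128 default network trains in minutes-to-hours, not seconds. The
  implementation favours transparency and testability over speed.
* The smoothness term couples windows only within a batch; across batch
  boundaries consecutive windows of one participant are not penalized
  (batches are participant-contiguous, so the effect is one missing pair
  per boundary).
* Whether attention + smoothness beats an ablated LSTM is, at desk
  scale, a small-margin stochastic outcome — the package asserts the
  direction over seeds, not a magnitude.
* HIS elicitation cadence is assumed daily; periodic (e.g., weekly)
  self-reports would change the windowing and are not modelled.
```
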