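---
title: "Learned Kalman filtering for 3D trajectory tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned Kalman filtering for 3D trajectory tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A detector watching an animal from an aerial camera produces one noisy 3D
position per video frame. The noise level varies with range, lighting and
pose; frames drop out under occlusion; occasional detections are wildly
wrong. A temporal regularizer turns this jittery stream into a smooth,
accurate track. Classical Kalman filters do this well *if* the modeler
specifies a motion model and fixed noise covariances in advance — exactly
what is hard for wild animals that stand, walk and sprint within one
recording.

This package implements a learned Kalman filter: three recurrent (LSTM)
modules predict, per frame, the state transition and the diagonal process
and measurement noise covariances, and a standard Kalman filter fuses
prediction and measurement. The filter equations stay intact; what is
learned is what to put into them.

## Model

State-space model with identity observation:

$$y_t = f(y_{t-1}) + w_t, \quad w_t \sim N(0, Q_t), \qquad
  z_t = y_t + v_t, \quad v_t \sim N(0, R_t).$$

Per frame the filter runs the extended-Kalman-filter recursions

$$\hat y'_t = f(\hat y_{t-1}), \qquad
  \hat P'_t = F \hat P_{t-1} F^\top + \hat Q_t,$$
$$K_t = \hat P'_t(\hat P'_t + \hat R_t)^{-1}, \qquad
  \hat y_t = \hat y'_t + K_t(z_t - \hat y'_t), \qquad
  \hat P_t = (I - K_t)\hat P'_t,$$

where $F$ is the Jacobian of the learned transition $f$ at
$\hat y_{t-1}$, assembled analytically layer by layer
(`jacobian_of_f()`), and $\hat Q_t, \hat R_t$ are the outputs of the two
covariance modules, constrained diagonal and positive by exponentiating
the raw network outputs. On frames with no measurement the prediction
becomes the estimate and the belief covariance grows by $\hat Q_t$.

### Architecture

* **Transition module** (`f`): stacked LSTM layers followed by a fully
  connected stack with ReLU on all but the last layer. Reference size:
  3 × 1024 recurrent units with FC 1024/1024/out
  (`lstmkf_profile("reference")`); the desk profile used throughout the
  tests and benchmark is 3 × 64 with FC 64/64/out.
* **Covariance modules** (`Q`, `R`): single-layer LSTMs (reference 256,
  desk 32) with a linear head of width $d$.
* Dropout (retention 0.7) follows each LSTM layer during training, in
  inverted form so evaluation is deterministic.

### Design choices the reference formulation leaves open

* **Transition parameterization.** `f` is realized as a residual map
  $f(y) = y + g(y)$ with the final layer of $g$ zero-initialized, so an
  untrained model is already an identity-transition Kalman filter with
  covariances $q_0, r_0$ — a sensible filter rather than a degenerate
  one. `residual_f = FALSE` gives the bare network output.
* **Input encoding.** By default the recurrent modules receive
  translation-invariant signals: the transition module sees the previous
  state increment $\hat y_{t-1} - \hat y_{t-2}$, the process-covariance
  module the predicted increment $\hat y'_t - \hat y_{t-1}$, and the
  measurement-covariance module the innovation $z_t - \hat y'_t$. These
  are bounded, metrically meaningful quantities; absolute world
  coordinates (tens of meters) saturate gate nonlinearities and tie the
  model to where a track happens to lie in space, which at desk scale
  (small hidden sizes, three training sequences) prevents
  generalization. `input_mode = "absolute"` feeds the raw vectors
  instead. A fixed `input_scale` places the signals in the active range
  of the gates.
* **Covariance positivity** uses `exp` of the raw output (clamped to
  `[1e-8, 1e8]`): it covers many decades of noise scale symmetrically in
  log-space and makes "zero network output" correspond to unit
  covariance. The initial biases are set to `log(q0)`, `log(r0)`.
* **Innovation-adaptive measurement covariance** (`r_adaptive`, default
  on). The measurement module's exponentiated output does not set
  $\hat R_t$ absolutely; it multiplies a running exponential average of
  the squared innovation held in the filter state (memory `r_ema_rho`,
  default 0.98, roughly 50 frames), in the spirit of classical
  innovation-based adaptive filtering. The network therefore learns a
  log-residual correction to a moment-matched baseline instead of the
  absolute noise scale — a much easier target, and the untrained filter
  already adapts to noise segments. The multiplicative correction is
  initialized at `r_gamma0 = 0.1`, the fraction of innovation energy
  attributed a priori to measurement noise; it must start well below 1
  because part of the innovation is prediction error, and attributing
  all of it to the sensor makes the filter distrust measurements,
  lag, and destabilize. The average uses the *previous* frames'
  innovations, so a frame's own innovation never feeds its own gain
  directly.
* **Direct output connections.** Each module head carries a direct
  input-to-output connection (the modified-output formulation): a skip
  matrix on the current input, and — for the transition module — a
  zero-initialized joint weight matrix over a ring buffer of the last
  `f_lag_window = 8` module inputs. With the relative encoding those
  lagged inputs are past state increments, so these weights can express
  a finite-impulse-response velocity smoother; this is what lets a
  position-only (d = 3) state track fast motion the way a
  constant-velocity filter's explicit velocity state does, and in
  training it is the single largest contributor to beating that
  baseline. Lagged inputs live in the filter state and therefore do not
  enter the transition Jacobian; the lag-0 skip does.
* **Loss.** The training loss is the two-stream mean
  $\frac1T\sum_t (\lVert y_t - \hat y_t\rVert + \lambda\lVert y_t -
  \hat y'_t\rVert)$; the $\lambda$-term feeds gradient directly to the
  transition module, which otherwise learns poorly through the
  gain-weighted posterior term alone. $\lambda$ defaults to 1. A
  `squared_loss` switch uses squared norms, which weights frames
  proportionally to their error and matches the mean-squared-error
  optimality of the Kalman filter.
* **Modified LSTM output.** The output-connection variant
  $Y_t = V C_t + \sum_n W_n X_n$ sums over *all* past inputs as
  written, which implies unboundedly many matrices; `modified_output()`
  realizes it with a fixed ring of lag-indexed, shared matrices
  (default window 8), preserving the direct input-to-output shortcut
  that counteracts overfitting while keeping the parameter count
  bounded.

## Differentiation through the filter

Training requires the gradient of the loss with respect to every weight
*through* the Kalman update — including the covariance propagation,
whose Jacobian $F$ itself depends on the weights. No automatic
differentiation library is available to the package, so it carries a
minimal reverse-mode tape (`ad_tape()`, `ad_backward()`) over dense
matrices: some thirty primitives (matrix product, inverse, gate
nonlinearities, row scaling, slicing, norms) each record a local
backward rule. The Jacobian chain is expressed in the same primitives,
so reverse mode differentiates through it exactly; the engine is
validated against central finite differences down to `1e-7` relative
error on composite graphs, and end-to-end on a small filter (state
dimension 2, hidden 8, 5 frames) to `1e-3` relative.

ReLU derivative kinks make finite differences disagree at points where a
pre-activation is within the step size of zero; the gradient checks use
models with generic (non-microscopic) pre-activations.

## Optimizer

Training uses the infinity-norm variant of Adam: the second-moment
accumulator generalizes from the $L^2$ to the $L^p$ norm, and the stable
$p \to \infty$ limit is the recursion $v_t = \max(\beta_2 v_{t-1},
|g_t|)$ with closed form $v_t = \max_i \beta_2^{\,t-i}|g_i|$ — both
implemented and cross-checked to `1e-12`, with the finite-$p$ variant
(`update_v_p()`) verified to approach the limit at $p = 256$ and to
overflow (with a clear error) at large $p$. The first moment keeps
Adam's bias-corrected momentum; the infinity-norm accumulator needs no
bias correction. Defaults: $\alpha = 2\times10^{-5}$ (reference
schedule), $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-8}$.

## Training protocol

Truncated backpropagation through time: sequences are consumed in
windows (reference 100 steps; the desk benchmark uses 25), recurrent and
belief state values carry across windows, gradients stop at the
boundary, and one optimizer step is taken per window with global
gradient-norm clipping at 10. The learning rate decays by 0.95 per epoch
from the second epoch. "Epoch" means one pass over the training
sequences.

Equal-length sequences can be trained as one batch
(`lstmkf_loss_grad_batch()`): network states carry one column per
sequence and the filter covariances form a block-diagonal system, so the
per-frame arithmetic is shared across the batch. Under the squared loss
the batched gradient is *exactly* the mean of the per-sequence gradients
(asserted to 1e-9 in the tests); per-column gap frames are realized by
zeroing the innovation and making that column's measurement
uninformative, and dropout masks are shared across the batch. The desk
benchmark trains its three sequences as one batch of three with the
squared loss, selecting the epoch with the best validation loss; the
plain-LSTM baseline trains in lockstep batches of 2 at its reference
settings (16 hidden units, learning rate 5e-4, 10-step windows, 120
epochs — scaled down in the desk benchmark).

## 3D localization geometry

The detector's bounding box is contracted about its center by a factor
$\theta$ (default 0.5; the contraction discards background pixels at the
box edges), valid depth readings whose pixel centers fall inside the
contracted half-open rectangle are averaged to a range $S$, and the box
center is back-projected through the intrinsics:
$X_C = K^{-1}(S\,[u, v, 1]^\top)$. The camera-frame point is carried to
the world frame by the fixed camera-to-body transform and the observer
pose, $X_W = T_{BW} T_{CB} X_C$. Pixel convention: origin top-left,
$u$ rightward, $v$ downward; rotations may be supplied as matrices or
scalar-first quaternions (normalized on ingest). A patch with no valid
depth raises an error at the API level; the tracking layer represents
such frames as missing measurements and coasts.

## Synthetic benchmark

The generator stands in for aerial field footage and emulates what the
method assumes: smooth second-order kinematics under discrete motion
regimes (standing ≤ 0.005 m/s, walking 0.5–1.5 m/s, running 4–9 m/s,
with regime-specific turn rates), piecewise-constant measurement noise
(default segments cycling σ = 0.05, 0.3, 0.1, 0.6, 0.2, 0.45 m every
10 s), 1% outlier frames at 6× noise, and 2% dropout frames. Sequences
default to 60 s at 30 Hz; motion is integrated at a fixed internal
240 Hz so the same seed yields pathwise-consistent trajectories across
frame rates. Six sequences are split 3/2/1 into train/test/validation.
Every generator is a pure function of (parameters, seed).

What it does *not* emulate: detector-specific error structure
(systematic box offsets, confusion between animals), range-dependent
noise, terrain, or multi-animal interactions. Passing benchmarks here
show that the filter learns the assumed statistical structure, not that
it handles every pathology of real footage.

The comparison harness scores raw measurements, constant-velocity and
constant-acceleration Kalman filters (standard kinematic
discretizations; fixed parameters declared in the benchmark config, not
fitted), an exponential moving average, the plain-LSTM regressor, and
the learned filter, reporting translation RMSE per motion regime and
overall — the qualitative ordering of interest being learned filter <
classical KF < raw ≪ plain LSTM, the last because a direct
measurement-to-state regressor trained on three sequences has no
filtering structure to fall back on.

Problem sizes in the test-suite: the full benchmark trains the desk
profile for 20 epochs on three 1801-frame sequences batched together
(learning rate 1e-2, 25-step windows); oracle and property checks use
sequences of 25–100 frames and models of hidden size 8.

## Numerical choices

* Posterior covariances are symmetrized, $(P + P^\top)/2$, after each
  update; the innovation matrix is inverted only when its reciprocal
  condition number exceeds `1e-14`.
* The Euclidean norm in the loss is smoothed as
  $\sqrt{\lVert e\rVert^2 + 10^{-12}}$ so it is differentiable at zero
  error.
* Baseline filters initialize the observed block from the first
  measurement with prior variance `diag(R)` and `1e4` on unobserved
  blocks; the learned filter starts at `P = p0 I`.
* Checkpoints store tensors as raw little-endian doubles, so save →
  load → filter is bit-identical.

## Known limitations

* The desk-scale training budget (minutes, one CPU) supports the 64/32
  profile; the 1024/256 reference profile is provided for fidelity but
  is not practical to train in pure R.
* Covariance modules predict diagonals only (as specified); correlated
  noise is out of scope.
* The measurement-covariance module advances its recurrent state only on
  frames with a measurement.
* Single-animal tracking; data association is out of scope.
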