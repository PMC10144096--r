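# lstmkf — learned Kalman filtering for 3D trajectory tracking

Aerial wildlife monitoring produces one noisy 3D position per video frame:
a detector finds the animal in the image, stereo depth places it in the
world, and the resulting track jitters with range- and pose-dependent
noise, drops out under occlusion, and occasionally jumps to a wrong
detection. Classical Kalman filters clean such tracks only if the motion
model and the noise covariances are specified in advance — hard for an
animal that stands, walks and sprints within one recording.

`lstmkf` implements a **learned Kalman filter** for this problem: three
recurrent (LSTM) modules predict, per frame, the state transition `f`, the
process noise covariance `Q̂ₜ` and the measurement noise covariance `R̂ₜ`
(both diagonal, positive), and a standard Kalman filter fuses prediction
and measurement:

```
ŷ'ₜ = f(ŷₜ₋₁)              P̂'ₜ = F P̂ₜ₋₁ Fᵀ + Q̂ₜ      (F = ∂f/∂y)
Kₜ  = P̂'ₜ (P̂'ₜ + R̂ₜ)⁻¹    ŷₜ  = ŷ'ₜ + Kₜ(zₜ − ŷ'ₜ)   P̂ₜ = (I − Kₜ) P̂'ₜ
```

The filter is differentiable end-to-end through a built-in reverse-mode
autodiff tape (including the transition Jacobian used in the covariance
propagation), trains with truncated backpropagation through time under an
infinity-norm Adam variant (`vₜ = max(β₂ vₜ₋₁, |gₜ|)`), and is benchmarked
against constant-velocity / constant-acceleration Kalman filters, an
exponential moving average, and a plain LSTM regressor on a synthetic
trajectory benchmark with motion regimes and piecewise-constant
(heteroscedastic) measurement noise. The package also implements the
bounding-box + depth localization geometry (ROI contraction, depth
averaging, pinhole back-projection, camera→body→world transforms).

Who it is for: anyone turning per-frame 3D detections into smooth tracks —
in particular when the measurement noise level varies over time, which is
exactly where a filter with a *learned, per-frame* `R̂ₜ` beats any fixed-R
filter.

## Worked example

Simulate a walking animal with two noise regimes, filter with an untrained
model (an identity-transition Kalman filter) and inspect the output:

```r
library(lstmkf)

sched <- data.frame(regime = "walking", duration = 20)
truth <- simulate_trajectory(sched, dt = 1/30, seed = 42)
meas  <- simulate_measurements(truth,
          noise_model(sigma_segments = c(0.1, 0.4), segment_len = 10,
                      outlier_prob = 0, dropout_prob = 0.02), seed = 43)

set.seed(1)
model <- lstmkf_init(lstmkf_config(d = 3, q0 = 5e-3, r0 = 0.12, p0 = 0.1))
out <- lstmkf_filter(model, meas$z)

rmse(truth$pos, out$est)$overall     # filtered error (m)
rmse(truth$pos[!meas$dropout, ], meas$z[!meas$dropout, ])$overall  # raw error
```

which prints (exact values for these seeds)

```
[1] 0.1549261   # filtered
[1] 0.2806041   # raw measurements
```

— the untrained filter (an identity-transition, innovation-adaptive
Kalman filter) already roughly halves the raw measurement error on this
sequence; training adapts `f`, `Q̂` and `R̂` to the data (see below).

The full comparison — train the learned filter and the plain-LSTM
baseline, score every method on the held-out test sequences — is one
call:

```r
run <- benchmark_comparison(seed = 1)
run$table    # translation RMSE (m) per motion regime and overall
run$rho      # Spearman correlation of learned R̂ with the true noise
```

A command-line interface with `simulate`, `train`, `track`, `evaluate`,
`compare` and `localize` subcommands is installed at
`system.file("cli", "lstmkf.R", package = "lstmkf")`.

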