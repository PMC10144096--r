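Package: lstmkf
Title: Learned LSTM-Kalman Filtering for 3D Trajectory Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Temporal regularization of noisy 3D pose tracks with a learned
    Kalman filter: three recurrent (LSTM) modules predict the state transition
    and per-timestep diagonal process and measurement noise covariances, and a
    Kalman filter fuses them frame by frame. The filter is differentiable
    end-to-end via a built-in reverse-mode automatic differentiation tape, and
    is trained with truncated backpropagation through time using an
    infinity-norm variant of the Adam optimizer. Includes the bounding-box plus
    depth back-projection geometry used to localize a tracked animal in the
    world frame from an aerial camera, classical constant-velocity and
    constant-acceleration Kalman baselines, an exponential-moving-average
    smoother, and a synthetic trajectory benchmark with motion regimes,
    heteroscedastic measurement noise, outliers and dropout frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
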