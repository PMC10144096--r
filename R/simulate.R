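#' @title Synthetic trajectory benchmark
#'
#' @description
#' Generates smooth animal-like 3D trajectories under discrete motion
#' regimes (standing, walking, running), corrupts them with
#' heteroscedastic Gaussian measurement noise, outlier frames and
#' measurement dropouts, and scores temporal regularizers with RMSE and
#' MAE. The generator is the desk-scale stand-in for aerial field
#' footage: every sequence is a pure function of its parameters and seed.
#'
#' Motion is integrated at a fixed internal resolution (240 Hz) and
#' sampled at the frame interval, so the same seed yields pathwise
#' consistent trajectories across frame rates.
#'
#' @name synthetic-benchmark
NULL

.regimes <- list(
  standing = list(speed = c(0, 0.005), turn_rate = 1.0, accel_tau = 2),
  walking  = list(speed = c(0.5, 1.5),  turn_rate = 0.6, accel_tau = 3),
  running  = list(speed = c(4, 9),      turn_rate = 0.25, accel_tau = 4)
)

#' Motion regime definition
#'
#' @param name One of `"standing"`, `"walking"`, `"running"`. Speed
#'   ranges (m/s): standing 0--0.005, walking 0.5--1.5, running 4--9;
#'   turn-rate standard deviations (rad/s): 1.0, 0.6, 0.25.
#' @return A list with `name`, `speed` (range, m/s), `turn_rate` (rad/s)
#'   and `accel_tau` (speed relaxation time, s).
#' @export
motion_regime <- function(name = c("standing", "walking", "running")) {
  name <- match.arg(name)
  c(list(name = name), .regimes[[name]])
}

#' Simulate a ground-truth trajectory
#'
#' Second-order kinematics on the horizontal plane with a slowly varying
#' height: the heading performs a random walk at the regime's turn rate
#' and the speed mean-reverts (Ornstein-Uhlenbeck style) to a target
#' drawn from the regime's speed range. The process is integrated at a
#' fixed 240 Hz internal resolution and sampled every `dt`, which must be
#' a multiple of the internal step.
#'
#' @param regime_schedule Data frame with columns `regime` (name) and
#'   `duration` (seconds); regimes are visited in order.
#' @param dt Frame interval in seconds (default 1/30).
#' @param seed Integer seed; the trajectory is a pure function of
#'   (schedule, dt, seed).
#' @param x0 Starting position (length 3, meters).
#' @return A list of class `sim_trajectory`: `t` (times), `pos` (T x 3),
#'   `vel` (T x 3), `regime` (factor per frame), `dt`, `seed`.
#' @export
simulate_trajectory <- function(regime_schedule, dt = 1 / 30, seed = 1,
                                x0 = c(0, 0, 0)) {
  if (dt <= 0) stop_lstmkf("dt must be positive", "lstmkf_invalid_parameter")
  base_hz <- 240
  h <- 1 / base_hz
  k <- round(dt * base_hz)
  if (abs(k - dt * base_hz) > 1e-9 || k < 1)
    stop_lstmkf("dt must be a multiple of the internal 1/240 s step",
                "lstmkf_invalid_parameter")
  rs <- as.data.frame(regime_schedule)
  stopifnot(all(c("regime", "duration") %in% names(rs)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- round(rs$duration * base_hz)
  n_sub <- sum(counts)
  regime_sub <- rep(as.character(rs$regime), times = counts)
  pos <- matrix(NA_real_, n_sub + 1, 3)
  vel <- matrix(NA_real_, n_sub + 1, 3)
  pos[1, ] <- x0
  psi <- stats::runif(1, 0, 2 * pi)
  spd <- 0
  z_off <- 0
  target <- NA_real_
  cur <- ""
  vel[1, ] <- c(cos(psi), sin(psi), 0) * spd
  for (i in seq_len(n_sub)) {
    rg <- .regimes[[regime_sub[i]]]
    if (regime_sub[i] != cur) {
      cur <- regime_sub[i]
      target <- stats::runif(1, rg$speed[1], rg$speed[2])
    }
    psi <- psi + stats::rnorm(1, 0, rg$turn_rate * sqrt(h))
    spd <- spd + (target - spd) * h / rg$accel_tau +
      stats::rnorm(1, 0, 0.05 * sqrt(h) * max(target, 0.01))
    spd <- max(spd, 0)
    z_off <- z_off * (1 - h / 10) + stats::rnorm(1, 0, 0.02 * sqrt(h))
    v <- c(cos(psi) * spd, sin(psi) * spd, 0)
    pos[i + 1, ] <- pos[i, ] + v * h
    pos[i + 1, 3] <- x0[3] + z_off
    vel[i + 1, ] <- v
  }
  idx <- seq(1, n_sub + 1, by = k)
  structure(list(t = (idx - 1) * h, pos = pos[idx, , drop = FALSE],
                 vel = vel[idx, , drop = FALSE],
                 regime = factor(regime_sub[pmin(idx, n_sub)],
                                 levels = names(.regimes)),
                 dt = dt, seed = seed),
            class = "sim_trajectory")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Measurement noise model
#'
#' Piecewise-constant measurement noise with occasional outliers and
#' dropout frames. `sigma_segments` are cycled over equal-length segments
#' of `segment_len` seconds across the sequence.
#'
#' @param sigma_segments Positive per-segment measurement standard
#'   deviations in meters.
#' @param segment_len Segment length in seconds.
#' @param outlier_prob Per-frame probability of an outlier.
#' @param outlier_scale Multiplier on the noise draw for outlier frames.
#' @param dropout_prob Per-frame probability of a missing measurement.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma_segments = c(0.05, 0.3, 0.1, 0.6, 0.2, 0.45),
                        segment_len = 10,
                        outlier_prob = 0.01, outlier_scale = 6,
                        dropout_prob = 0.02) {
  if (any(sigma_segments <= 0))
    stop_lstmkf("sigmas must be positive", "lstmkf_invalid_parameter")
  if (any(c(outlier_prob, dropout_prob) < 0) ||
      any(c(outlier_prob, dropout_prob) >= 1))
    stop_lstmkf("probabilities must lie in [0, 1)", "lstmkf_invalid_parameter")
  structure(list(sigma_segments = sigma_segments, segment_len = segment_len,
                 outlier_prob = outlier_prob, outlier_scale = outlier_scale,
                 dropout_prob = dropout_prob),
            class = "noise_model")
}

#' Simulate measurements of a trajectory
#'
#' `z_t = y_t + e_t` with `e_t ~ N(0, sigma_t^2 I)`; outlier frames scale
#' the noise draw by `outlier_scale`, dropout frames become `NA` rows.
#' The first frame is never dropped so filters can initialize.
#'
#' @param truth A `sim_trajectory` (or a list with `t` and `pos`).
#' @param noise A [noise_model()].
#' @param seed Integer seed; measurements are a pure function of
#'   (truth, noise, seed).
#' @return A list of class `sim_measurements`: `z` (T x 3 with `NA`
#'   rows), `sigma` (true per-frame sd), `segment` (segment index per
#'   frame), `outlier` (logical), `seed`.
#' @export
simulate_measurements <- function(truth, noise = noise_model(), seed = 1) {
  stopifnot(inherits(noise, "noise_model"))
  pos <- as.matrix(truth$pos)
  Tlen <- nrow(pos)
  seg <- pmin(floor(truth$t / noise$segment_len) %%
                length(noise$sigma_segments) + 1,
              length(noise$sigma_segments))
  sigma <- noise$sigma_segments[seg]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eps <- matrix(stats::rnorm(Tlen * 3), Tlen, 3) * sigma
  outlier <- stats::runif(Tlen) < noise$outlier_prob
  eps[outlier, ] <- eps[outlier, ] * noise$outlier_scale
  z <- pos + eps
  drop <- stats::runif(Tlen) < noise$dropout_prob
  drop[1] <- FALSE
  z[drop, ] <- NA_real_
  structure(list(z = z, sigma = sigma, segment = seg, outlier = outlier,
                 dropout = drop, seed = seed),
            class = "sim_measurements")
}

#' Simulate a detection stream (bounding boxes + depth patches)
#'
#' Projects the true trajectory into a hovering observer's camera,
#' producing per-frame bounding boxes, depth patches with invalid-pixel
#' holes, the camera intrinsics and the observer pose -- an end-to-end
#' exercise for [localize()]. Frames with the target behind the camera
#' are marked missing.
#'
#' @param truth A `sim_trajectory`.
#' @param K A [camera_intrinsics()].
#' @param observer An [observer_pose()] (held fixed over the sequence).
#' @param seed Integer seed.
#' @param jitter Pixel standard deviation added to box centers.
#' @param depth_noise Relative depth noise standard deviation.
#' @param hole_prob Probability that a depth pixel is invalid.
#' @param target_size Physical target extent in meters (sets box size).
#' @param patch_px Depth patch edge length in pixels.
#' @return A list of class `sim_detections`: per-frame `frames` list with
#'   `box`, `patch`, `missing`; plus `K` and `observer`.
#' @export
simulate_detection_stream <- function(truth, K, observer, seed = 1,
                                      jitter = 0, depth_noise = 0,
                                      hole_prob = 0, target_size = 1,
                                      patch_px = 8) {
  stopifnot(inherits(K, "camera_intrinsics"),
            inherits(observer, "observer_pose"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  M_wc <- invert_rigid(structure(unclass(body_to_world(observer)) %*%
                                   unclass(camera_to_body()),
                                 class = "rigid_transform"))
  pos <- as.matrix(truth$pos)
  frames <- vector("list", nrow(pos))
  for (t in seq_len(nrow(pos))) {
    xc <- apply_rigid(M_wc, pos[t, ])
    if (xc[3] <= 0.1) {
      frames[[t]] <- list(missing = TRUE)
      next
    }
    uv <- K$K %*% xc
    u <- uv[1] / uv[3]; v <- uv[2] / uv[3]
    fpx <- mean(c(K$K[1, 1], K$K[2, 2]))
    wpx <- max(fpx * target_size / xc[3], 2)
    box <- bbox2d(u + stats::rnorm(1, 0, jitter),
                  v + stats::rnorm(1, 0, jitter), wpx, wpx)
    vals <- matrix(xc[3] * (1 + stats::rnorm(patch_px^2, 0, depth_noise)),
                   patch_px, patch_px)
    valid <- matrix(stats::runif(patch_px^2) >= hole_prob, patch_px, patch_px)
    patch <- depth_patch(vals, valid,
                         origin = c(box$cx - patch_px / 2,
                                    box$cy - patch_px / 2))
    frames[[t]] <- list(missing = FALSE, box = box, patch = patch)
  }
  structure(list(frames = frames, K = K, observer = observer, seed = seed),
            class = "sim_detections")
}

#' Root-mean-square error between truth and estimate
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`, reported per axis and pooled over
#' all axes.
#'
#' @param y_true_seq,y_hat_seq Equal-shape numeric matrices (or vectors).
#' @return List with `per_axis` and `overall`.
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
rmse <- function(y_true_seq, y_hat_seq) {
  yt <- as.matrix(y_true_seq); yh <- as.matrix(y_hat_seq)
  if (!all(dim(yt) == dim(yh)) || nrow(yt) < 1)
    stop_lstmkf("sequences must have equal, non-zero shape",
                "lstmkf_dimension_error")
  e2 <- (yt - yh)^2
  list(per_axis = sqrt(colMeans(e2)), overall = sqrt(mean(e2)))
}

#' Mean absolute error between truth and estimate
#'
#' @inheritParams rmse
#' @return List with `per_axis` and `overall`.
#' @export
#' @examples
#' mae(c(0, 0), c(3, 4))  # 3.5
mae <- function(y_true_seq, y_hat_seq) {
  yt <- as.matrix(y_true_seq); yh <- as.matrix(y_hat_seq)
  if (!all(dim(yt) == dim(yh)) || nrow(yt) < 1)
    stop_lstmkf("sequences must have equal, non-zero shape",
                "lstmkf_dimension_error")
  ae <- abs(yt - yh)
  list(per_axis = colMeans(ae), overall = mean(ae))
}

#' Default benchmark regime schedule
#'
#' Each sequence cycles standing, walking and running in a seeded random
#' order with dwell times summing to `duration`.
#'
#' @param duration Total duration in seconds.
#' @param seed Integer seed.
#' @return Data frame with `regime` and `duration` columns.
#' @export
benchmark_schedule <- function(duration = 60, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  blocks <- sample(rep(names(.regimes), 2))
  d <- as.numeric(stats::rmultinom(1, duration, rep(1, 6))) / 1
  d <- pmax(d, 4)
  d <- d / sum(d) * duration
  data.frame(regime = blocks, duration = d)
}

#' Build the default synthetic benchmark dataset
#'
#' Six sequences (60 s at 30 Hz by default), each cycling the three
#' motion regimes with the heteroscedastic noise model, split 3/2/1 into
#' train/test/validation in sequence order.
#'
#' @param n_seq Number of sequences (default 6).
#' @param duration Sequence duration in seconds.
#' @param dt Frame interval.
#' @param noise A [noise_model()].
#' @param seed Master seed; per-sequence seeds are derived from it.
#' @return A list of class `benchmark_data`: `sequences` (each with `z`,
#'   `y` = true positions, `truth`, `meas`), and `split` (list of index
#'   vectors `train`, `test`, `validation`).
#' @export
make_benchmark <- function(n_seq = 6, duration = 60, dt = 1 / 30,
                           noise = noise_model(), seed = 20260927) {
  seqs <- lapply(seq_len(n_seq), function(i) {
    s <- seed + 1000L * i
    tr <- simulate_trajectory(benchmark_schedule(duration, s), dt = dt,
                              seed = s,
                              x0 = c((i - 1) * 5, (i %% 3) * 5, 0))
    ms <- simulate_measurements(tr, noise, seed = s + 1L)
    list(z = ms$z, y = tr$pos, truth = tr, meas = ms)
  })
  n_train <- round(n_seq * 3 / 6)
  n_test <- round(n_seq * 2 / 6)
  split <- list(train = seq_len(n_train),
                test = seq.int(n_train + 1, n_train + n_test),
                validation = seq.int(n_train + n_test + 1, n_seq))
  structure(list(sequences = seqs, split = split, dt = dt, seed = seed,
                 noise = noise), class = "benchmark_data")
}

#' Compare temporal regularizers on a benchmark
#'
#' Scores each method's position estimates on the test split: columns are
#' the mean translation RMSE per motion regime (over frames with that
#' regime label) plus the overall mean. Methods: raw measurements
#' (gap frames carried forward), constant-velocity and
#' constant-acceleration Kalman filters, exponential moving average, the
#' plain LSTM baseline and the learned filter.
#'
#' @param bench A [make_benchmark()] dataset.
#' @param model A trained `lstmkf_model`, or `NULL` to skip that row.
#' @param std_lstm A trained `std_lstm_model`, or `NULL` to skip.
#' @param kf_q,kf_r Process intensity and measurement variance for the
#'   classical filters (defaults declared in the benchmark config, not
#'   fitted).
#' @param ema_alpha Smoothing weight of the EMA row.
#' @param units `"m"` or `"mm"` for reporting.
#' @return A data frame (one row per method) of class `method_comparison`.
#' @export
compare_methods <- function(bench, model = NULL, std_lstm = NULL,
                            kf_q = 0.5, kf_r = 0.1, ema_alpha = 0.3,
                            units = c("m", "mm")) {
  stopifnot(inherits(bench, "benchmark_data"))
  units <- match.arg(units)
  test <- bench$sequences[bench$split$test]
  dt <- bench$dt
  methods <- list(
    raw = function(sq) {
      z <- sq$z
      for (t in seq_len(nrow(z))[-1]) if (anyNA(z[t, ])) z[t, ] <- z[t - 1, ]
      z
    },
    kalman_vel = function(sq)
      run_filter(constant_velocity_model(3, dt, kf_q, kf_r), sq$z)$pos,
    kalman_acc = function(sq)
      run_filter(constant_acceleration_model(3, dt, kf_q, kf_r), sq$z)$pos,
    ema = function(sq) ema_smoother(sq$z, ema_alpha),
    std_lstm = if (is.null(std_lstm)) NULL else function(sq)
      std_lstm_predict(std_lstm, sq$z),
    lstm_kf = if (is.null(model)) NULL else function(sq)
      lstmkf_filter(model, sq$z)$est
  )
  methods <- methods[!vapply(methods, is.null, TRUE)]
  regs <- names(.regimes)
  rows <- lapply(names(methods), function(mn) {
    per_reg <- stats::setNames(numeric(length(regs)), regs)
    cnt <- stats::setNames(numeric(length(regs)), regs)
    tot <- 0; n_tot <- 0
    for (sq in test) {
      est <- methods[[mn]](sq)
      e2 <- rowSums((est - sq$y)^2)
      lab <- as.character(sq$truth$regime)
      for (rg in regs) {
        sel <- lab == rg
        per_reg[rg] <- per_reg[rg] + sum(e2[sel])
        cnt[rg] <- cnt[rg] + sum(sel)
      }
      tot <- tot + sum(e2); n_tot <- n_tot + length(e2)
    }
    scale <- if (units == "mm") 1000 else 1
    data.frame(method = mn,
               standing = sqrt(per_reg["standing"] / cnt["standing"]) * scale,
               walking = sqrt(per_reg["walking"] / cnt["walking"]) * scale,
               running = sqrt(per_reg["running"] / cnt["running"]) * scale,
               mean = sqrt(tot / n_tot) * scale,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("method_comparison", "data.frame")
  attr(out, "units") <- units
  out
}

#' Rank correlation between learned measurement noise and the truth
#'
#' Runs the learned filter over the test split and correlates the mean
#' predicted measurement variance per noise segment with the true
#' per-segment variance (Spearman rank correlation, pooled over
#' sequences). A filter that has learned to read the noise level off the
#' measurement stream scores near 1.
#'
#' @param model A trained `lstmkf_model`.
#' @param bench A [make_benchmark()] dataset.
#' @param split Which split to evaluate (default `"test"`).
#' @return List with `rho` and the per-segment table `segments`.
#' @export
noise_recovery_rho <- function(model, bench, split = "test") {
  seqs <- bench$sequences[bench$split[[split]]]
  rows <- list()
  for (si in seq_along(seqs)) {
    sq <- seqs[[si]]
    out <- lstmkf_filter(model, sq$z)
    rbar <- rowMeans(out$R_diag)
    seg <- sq$meas$segment
    for (g in unique(seg)) {
      sel <- seg == g & !is.na(rbar)
      sel[1] <- FALSE
      if (sum(sel) < 2) next
      rows[[length(rows) + 1]] <- data.frame(
        seq = si, segment = g,
        r_hat = mean(rbar[sel]),
        sigma2_true = mean(sq$meas$sigma[sel]^2))
    }
  }
  tab <- do.call(rbind, rows)
  rho <- stats::cor(tab$r_hat, tab$sigma2_true, method = "spearman")
  list(rho = rho, segments = tab)
}
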