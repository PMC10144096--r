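test_that("trajectory generator is a pure function of its seed", {
  sched <- data.frame(regime = c("walking", "running"), duration = c(5, 5))
  a <- simulate_trajectory(sched, dt = 1 / 30, seed = 7)
  b <- simulate_trajectory(sched, dt = 1 / 30, seed = 7)
  expect_identical(a$pos, b$pos)
  c <- simulate_trajectory(sched, dt = 1 / 30, seed = 8)
  expect_false(identical(a$pos, c$pos))
  expect_equal(nrow(a$pos), 10 * 30 + 1)
})

test_that("standing animals barely move; running ones cover ground", {
  for (seed in 1:5) {
    st <- simulate_trajectory(data.frame(regime = "standing", duration = 60),
                              seed = seed)
    disp <- max(sqrt(rowSums((st$pos - st$pos[rep(1, nrow(st$pos)), ])^2)))
    expect_lt(disp, 0.5)
    rn <- simulate_trajectory(data.frame(regime = "running", duration = 60),
                              seed = seed)
    disp_r <- sqrt(sum((rn$pos[nrow(rn$pos), ] - rn$pos[1, ])^2))
    path_r <- sum(sqrt(rowSums(diff(rn$pos)^2)))
    expect_gt(path_r, 60)  # at least 1 m/s average path speed
  }
})

test_that("halving the frame interval refines the same underlying path", {
  sched <- data.frame(regime = "walking", duration = 10)
  coarse <- simulate_trajectory(sched, dt = 1 / 30, seed = 11)
  fine <- simulate_trajectory(sched, dt = 1 / 60, seed = 11)
  # common timestamps coincide exactly: same internal 240 Hz path
  expect_equal(fine$pos[seq(1, nrow(fine$pos), by = 2), ][seq_len(nrow(coarse$pos)), ],
               coarse$pos, tolerance = 1e-12)
})

test_that("measurement noise matches its schedule empirically", {
  sched <- data.frame(regime = "standing", duration = 40)
  tr <- simulate_trajectory(sched, dt = 1 / 240 * 2, seed = 12)  # 120 Hz
  nm <- noise_model(sigma_segments = c(0.1, 0.5), segment_len = 20,
                    outlier_prob = 0, dropout_prob = 0)
  ms <- simulate_measurements(tr, nm, seed = 13)
  resid <- ms$z - tr$pos
  s1 <- sd(resid[ms$segment == 1, ])
  s2 <- sd(resid[ms$segment == 2, ])
  expect_lt(abs(s1 - 0.1) / 0.1, 0.05)
  expect_lt(abs(s2 - 0.5) / 0.5, 0.05)
  # noiseless limit reproduces the truth
  nm0 <- noise_model(sigma_segments = 1e-12, outlier_prob = 0,
                     dropout_prob = 0)
  ms0 <- simulate_measurements(tr, nm0, seed = 14)
  expect_equal(ms0$z, tr$pos, tolerance = 1e-9)
  # replay determinism
  expect_identical(simulate_measurements(tr, nm, seed = 13)$z, ms$z)
})

test_that("dropout marks frames missing but never the first frame", {
  tr <- simulate_trajectory(data.frame(regime = "walking", duration = 5),
                            seed = 15)
  nm <- noise_model(dropout_prob = 0.999, outlier_prob = 0)
  ms <- simulate_measurements(tr, nm, seed = 16)
  expect_false(anyNA(ms$z[1, ]))
  expect_true(all(is.na(ms$z[-1, 1])))
})

test_that("detection stream with zero jitter is exactly invertible by localize", {
  tr <- simulate_trajectory(data.frame(regime = "walking", duration = 3),
                            seed = 17, x0 = c(20, 0, 0))
  K <- camera_intrinsics(matrix(c(400, 0, 320, 0, 400, 240, 0, 0, 1),
                                3, 3, byrow = TRUE))
  # camera looks along +x (body forward) from the origin
  obs <- observer_pose(o = c(0, 0, 0))
  det <- simulate_detection_stream(tr, K, obs, seed = 18)
  errs <- vapply(seq_along(det$frames), function(t) {
    fr <- det$frames[[t]]
    if (fr$missing) return(NA_real_)
    xw <- localize(fr$box, fr$patch, K, obs, theta = 0.5)
    sqrt(sum((xw - tr$pos[t, ])^2))
  }, 0)
  expect_true(any(!is.na(errs)))
  expect_lt(max(errs, na.rm = TRUE), 1e-6)
})

test_that("invalid-pixel holes leave constant-depth recovery unchanged", {
  tr <- simulate_trajectory(data.frame(regime = "standing", duration = 1),
                            seed = 19, x0 = c(15, 2, -1))
  K <- camera_intrinsics(diag(c(350, 350, 1)))
  obs <- observer_pose(o = c(0, 0, 0))
  det0 <- simulate_detection_stream(tr, K, obs, seed = 20, hole_prob = 0)
  det5 <- simulate_detection_stream(tr, K, obs, seed = 20, hole_prob = 0.5)
  for (t in c(1, 10, 20)) {
    a <- localize(det0$frames[[t]]$box, det0$frames[[t]]$patch, K, obs)
    b <- localize(det5$frames[[t]]$box, det5$frames[[t]]$patch, K, obs)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("targets behind the camera are flagged missing", {
  tr <- simulate_trajectory(data.frame(regime = "standing", duration = 1),
                            seed = 21, x0 = c(-10, 0, 0))
  K <- camera_intrinsics(diag(c(350, 350, 1)))
  obs <- observer_pose(o = c(0, 0, 0))  # camera looks along +x
  det <- simulate_detection_stream(tr, K, obs, seed = 22)
  expect_true(all(vapply(det$frames, function(f) f$missing, TRUE)))
})

test_that("error metrics match hand-computed values and their inequality", {
  expect_equal(rmse(c(0, 0), c(3, 4))$overall, sqrt(12.5))
  expect_equal(mae(c(0, 0), c(3, 4))$overall, 3.5)
  expect_equal(rmse(1:5, 1:5)$overall, 0)
  expect_equal(mae(1:5, 1:5)$overall, 0)
  set.seed(23)
  for (i in 1:100) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    expect_gte(rmse(a, b)$overall, mae(a, b)$overall)
    expect_gte(min(rmse(a, b)$per_axis - mae(a, b)$per_axis), 0)
  }
  expect_error(rmse(1:4, 1:5), class = "lstmkf_dimension_error")
})

test_that("benchmark splits 6 sequences 3/2/1 and replays from its seed", {
  b <- make_benchmark(n_seq = 6, duration = 4, noise = noise_model(
    sigma_segments = c(0.1, 0.3), segment_len = 2))
  expect_length(b$sequences, 6)
  expect_equal(lengths(b$split[c("train", "test", "validation")]),
               c(train = 3, test = 2, validation = 1))
  expect_equal(sort(unname(unlist(b$split))), 1:6)
  b2 <- make_benchmark(n_seq = 6, duration = 4, noise = noise_model(
    sigma_segments = c(0.1, 0.3), segment_len = 2))
  expect_identical(b$sequences[[4]]$z, b2$sequences[[4]]$z)
  # every sequence visits all three regimes
  for (sq in b$sequences)
    expect_setequal(as.character(unique(sq$truth$regime)),
                    c("standing", "walking", "running"))
})

test_that("method comparison scores noiseless data at (near) zero", {
  b <- make_benchmark(n_seq = 6, duration = 4,
                      noise = noise_model(sigma_segments = 1e-9,
                                          outlier_prob = 0, dropout_prob = 0))
  cmp <- compare_methods(b, kf_q = 5, kf_r = 1e-6)
  expect_s3_class(cmp, "method_comparison")
  raw <- cmp$mean[cmp$method == "raw"]
  expect_lt(raw, 1e-8)
  expect_lt(cmp$mean[cmp$method == "kalman_vel"], 0.05)
  # mm reporting scales by 1000
  cmp_mm <- compare_methods(b, kf_q = 5, kf_r = 1e-6, units = "mm")
  expect_equal(cmp_mm$mean, cmp$mean * 1000)
  # learned rows refused without trained models: rows simply absent
  expect_false("lstm_kf" %in% cmp$method)
})

test_that("matched-model data ranks the Kalman row at or below raw", {
  wins <- 0
  for (seed in 1:50) {
    set.seed(seed)
    Tlen <- 120; dt <- 1 / 30
    # constant-velocity truth with matched process noise
    q <- 0.3; r <- 0.2
    v <- matrix(0, Tlen, 3); p <- matrix(0, Tlen, 3)
    for (t in 2:Tlen) {
      v[t, ] <- v[t - 1, ] + rnorm(3, 0, sqrt(q * dt))
      p[t, ] <- p[t - 1, ] + v[t - 1, ] * dt
    }
    z <- p + matrix(rnorm(Tlen * 3, 0, sqrt(r)), Tlen, 3)
    est <- run_filter(constant_velocity_model(3, dt, q, r), z)$pos
    if (rmse(p, est)$overall <= rmse(p, z)$overall) wins <- wins + 1
  }
  expect_gte(wins, 48)
})
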