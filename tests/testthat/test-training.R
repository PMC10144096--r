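# tiny dataset shared by the training tests
tiny_dataset <- function(n_seq = 2, Tlen = 60, d = 3, seed = 61) {
  set.seed(seed)
  lapply(seq_len(n_seq), function(i) {
    sched <- data.frame(regime = "walking", duration = Tlen / 30)
    tr <- simulate_trajectory(sched, dt = 1 / 30, seed = seed + i)
    nm <- noise_model(sigma_segments = c(0.1, 0.4), segment_len = 1,
                      outlier_prob = 0, dropout_prob = 0)
    ms <- simulate_measurements(tr, nm, seed = seed + 100 + i)
    list(z = ms$z, y = tr$pos)
  })
}

tiny_lstmkf <- function(seed = 62) {
  set.seed(seed)
  lstmkf_init(lstmkf_config(d = 3, f_hidden = c(8, 8, 8), f_fc = c(8, 8),
                            q_hidden = 8, r_hidden = 8, q0 = 5e-3, r0 = 0.05,
                            p0 = 0.1))
}

test_that("learning-rate schedule decays geometrically from the second epoch", {
  cfg <- train_config(lr0 = 2e-5, decay = 0.95)
  expect_equal(lr_schedule(1, cfg), 2e-5)
  expect_equal(lr_schedule(2, cfg), 1.9e-5)
  expect_equal(lr_schedule(3, cfg), 2e-5 * 0.95^2)
  cfg1 <- train_config(lr0 = 1e-3, decay = 1)
  expect_equal(lr_schedule(50, cfg1), 1e-3)
})

test_that("a window spanning the whole sequence reproduces full-BPTT gradients", {
  m <- tiny_lstmkf()
  set.seed(63)
  z <- matrix(rnorm(24, 0, 0.3), 8, 3)
  y <- matrix(rnorm(24, 0, 0.3), 8, 3)
  full <- lstmkf_loss_grad(m, z, y, training = FALSE)
  again <- lstmkf_loss_grad(m, z, y, training = FALSE)
  for (nm in names(full$grads)) {
    expect_equal(full$grads[[nm]], again$grads[[nm]], tolerance = 1e-12)
  }
  # split windows carry state values identical to the uninterrupted pass
  part1 <- lstmkf_loss_grad(m, z[1:4, ], y[1:4, ], training = FALSE)
  part2 <- lstmkf_loss_grad(m, z[5:8, ], y[5:8, ], st = part1$st,
                            training = FALSE)
  expect_equal(part2$st$y, full$st$y, tolerance = 1e-12)
  expect_equal(part2$st$P, full$st$P, tolerance = 1e-12)
  # and the split losses average (frame-weighted) to the full loss
  expect_equal((part1$loss * part1$n_frames + part2$loss * part2$n_frames) / 7,
               full$loss, tolerance = 1e-12)
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  ds <- tiny_dataset()
  cfg <- train_config(lr0 = 2e-3, tbptt_window = 20, epochs = 3, seed = 64)
  m1 <- tbptt_train(tiny_lstmkf(), ds, cfg)
  h1 <- attr(m1, "loss_history")
  expect_true(all(is.finite(h1)))
  expect_lt(h1[3], h1[1])
  m2 <- tbptt_train(tiny_lstmkf(), ds, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(h1, attr(m2, "loss_history"))
})

test_that("early stopping returns the best validation parameters", {
  ds <- tiny_dataset()
  val <- tiny_dataset(n_seq = 1, seed = 99)
  cfg <- train_config(lr0 = 2e-3, tbptt_window = 20, epochs = 3, seed = 65,
                      patience = 2)
  m <- tbptt_train(tiny_lstmkf(), ds, cfg, val_dataset = val)
  vh <- attr(m, "val_history")
  expect_true(length(vh) >= 1 && all(is.finite(vh)))
})

test_that("baseline defaults mirror the reference setup and training runs", {
  cfg <- std_lstm_config()
  expect_equal(cfg$tbptt_window, 10)
  expect_equal(cfg$batch_size, 2)
  expect_equal(cfg$lr0, 5e-4)
  expect_equal(cfg$epochs, 120)
  expect_equal(cfg$hidden, 16)
  ds <- tiny_dataset()
  cfg_small <- std_lstm_config(epochs = 5, seed = 66)
  m <- train_std_lstm_baseline(ds, cfg_small)
  expect_true(all(is.finite(m$loss_history)))
  pred <- std_lstm_predict(m, ds[[1]]$z)
  expect_true(all(is.finite(pred)))
  expect_equal(dim(pred), dim(ds[[1]]$z))
})

test_that("plain LSTM trained on scarce data is worse than raw measurements", {
  ds <- tiny_dataset(n_seq = 2, Tlen = 90, seed = 67)
  m <- train_std_lstm_baseline(ds, std_lstm_config(epochs = 5, seed = 68))
  # dissimilar motion: a running sequence far from the training tracks
  tr <- simulate_trajectory(data.frame(regime = "running", duration = 3),
                            seed = 69, x0 = c(50, -30, 0))
  ms <- simulate_measurements(tr, noise_model(sigma_segments = 0.2,
                                              outlier_prob = 0,
                                              dropout_prob = 0), seed = 70)
  pred <- std_lstm_predict(m, ms$z)
  expect_gt(rmse(tr$pos, pred)$overall, rmse(tr$pos, ms$z)$overall)
})

test_that("batched window gradients equal the mean of per-sequence gradients", {
  set.seed(72)
  cfg <- lstmkf_config(d = 3, f_hidden = c(8, 8, 8), f_fc = c(8, 8),
                       q_hidden = 8, r_hidden = 8, p0 = 0.1,
                       squared_loss = TRUE)
  m <- lstmkf_init(cfg)
  for (nm in names(m$params))
    m$params[[nm]][] <- m$params[[nm]][] + rnorm(length(m$params[[nm]]), 0, 0.05)
  B <- 3; Tn <- 12
  zs <- lapply(1:B, function(b) matrix(rnorm(Tn * 3, 0, 0.4), Tn, 3))
  ys <- lapply(1:B, function(b) matrix(rnorm(Tn * 3, 0, 0.4), Tn, 3))
  zs[[2]][5, ] <- NA  # gap in one column only
  bat <- lstmkf_loss_grad_batch(m, zs, ys)
  seqs <- lapply(1:B, function(b) lstmkf_loss_grad(m, zs[[b]], ys[[b]]))
  expect_equal(bat$loss, mean(vapply(seqs, `[[`, 0, "loss")),
               tolerance = 1e-9)
  for (nm in names(m$params)) {
    gb <- bat$grads[[nm]]
    if (is.null(gb)) gb <- 0 * m$params[[nm]]
    gs <- Reduce(`+`, lapply(seqs, function(s)
      if (is.null(s$grads[[nm]])) 0 * m$params[[nm]] else s$grads[[nm]])) / B
    expect_lt(max(abs(gb - gs)), 1e-9)
  }
  # squared-loss requirement is enforced
  m2 <- m; m2$cfg$squared_loss <- FALSE
  expect_error(lstmkf_loss_grad_batch(m2, zs, ys),
               class = "lstmkf_invalid_parameter")
})

test_that("checkpoints round-trip bit-for-bit and training resumes identically", {
  ds <- tiny_dataset()
  cfg <- train_config(lr0 = 2e-3, tbptt_window = 20, epochs = 2, seed = 71)
  m <- tbptt_train(tiny_lstmkf(), ds, cfg)
  path <- file.path(tempdir(), "ckpt_test")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_equal(m2$cfg, m$cfg)
  # filtering with the restored model is bit-identical
  out1 <- lstmkf_filter(m, ds[[1]]$z)
  out2 <- lstmkf_filter(m2, ds[[1]]$z)
  expect_identical(out1$est, out2$est)
})
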