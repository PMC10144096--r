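test_that("prediction step propagates mean and covariance", {
  b <- kf_predict(belief(1, matrix(1)), diag(1), Q = matrix(0.5))
  expect_equal(b$y, 1)
  expect_equal(b$P, matrix(1.5))
  b2 <- kf_predict(belief(3, matrix(1)), matrix(2), Q = matrix(0))
  expect_equal(b2$y, 6)
  expect_equal(b2$P, matrix(4))
  b3 <- kf_predict(belief(c(1, 2), diag(2) * 0.3), diag(2), Q = diag(2) * 0)
  expect_equal(b3$P, diag(2) * 0.3)
  expect_error(kf_predict(belief(1, matrix(1)), diag(2), Q = matrix(0)),
               class = "lstmkf_dimension_error")
})

test_that("measurement update interpolates mean by the gain", {
  b <- kf_update(belief(0, matrix(1)), 2, matrix(1))
  expect_equal(attr(b, "gain"), matrix(0.5))
  expect_equal(b$y, 1)
  expect_equal(b$P, matrix(0.5))
  # perfect-measurement limit
  b2 <- kf_update(belief(5, matrix(1)), 2, matrix(1e-12))
  expect_equal(b2$y, 2, tolerance = 1e-9)
  # uninformative-measurement limit
  b3 <- kf_update(belief(5, matrix(1)), 0, matrix(1e12))
  expect_equal(b3$y, 5, tolerance = 1e-9)
  expect_equal(b3$P, matrix(1), tolerance = 1e-9)
})

test_that("kinematic models have the standard discretization", {
  cv <- constant_velocity_model(1, dt = 1, q = 0.1, r = 0.1)
  expect_equal(cv$A, matrix(c(1, 0, 1, 1), 2, 2))
  cv2 <- constant_velocity_model(1, dt = 0.5, q = 0.1, r = 0.1)
  expect_equal(cv2$A[1, ], c(1, 0.5))
  ca <- constant_acceleration_model(1, dt = 1, q = 0.1, r = 0.1)
  expect_equal(ca$A[1, ], c(1, 1, 0.5))
  expect_error(constant_acceleration_model(1, dt = 0), class = "lstmkf_invalid_parameter")
  # noiseless straight line: constant-velocity filter converges to the truth
  t_seq <- 0:60
  z <- matrix(2 + 3 * t_seq, ncol = 1)
  out <- run_filter(constant_velocity_model(1, dt = 1, q = 0, r = 1e-4), z)
  expect_lt(abs(out$pos[61] - z[61]), 1e-3)
  # on zero-acceleration data the CA filter agrees with CV within noise
  set.seed(8)
  zn <- z + rnorm(61, 0, 0.5)
  pv <- run_filter(constant_velocity_model(1, 1, 0.01, 0.25), zn)$pos
  pa <- run_filter(constant_acceleration_model(1, 1, 0.01, 0.25), zn)$pos
  expect_lt(sqrt(mean((pv - pa)^2)), 0.5)
})

test_that("EMA smoother obeys its recursion and fixed points", {
  expect_equal(ema_smoother(matrix(c(0, 2)), 0.5), matrix(c(0, 1)))
  z <- matrix(rnorm(20), 10, 2)
  expect_equal(ema_smoother(z, 1), z)
  zc <- matrix(3, 7, 1)
  expect_equal(ema_smoother(zc, 0.3), zc)
  expect_error(ema_smoother(z, 0), class = "lstmkf_invalid_parameter")
  expect_error(ema_smoother(z, 1.5), class = "lstmkf_invalid_parameter")
})

test_that("run_filter extrapolates through gaps and handles degenerate input", {
  # all-gap after the first frame: straight-line extrapolation at the
  # initial (zero) velocity estimate keeps the position constant
  z <- matrix(NA_real_, 10, 1)
  z[1, ] <- 4
  out <- run_filter(constant_velocity_model(1, 1, 0.1, 0.1), z)
  expect_equal(out$pos[, 1], rep(4, 10))
  # with a second measurement the velocity is picked up and extrapolated
  z2 <- matrix(NA_real_, 10, 1)
  z2[1, ] <- 0; z2[2, ] <- 1
  out2 <- run_filter(constant_velocity_model(1, 1, 0, 1e-8), z2)
  expect_equal(diff(out2$pos[5:10, 1]), rep(1, 5), tolerance = 1e-3)
  one <- run_filter(constant_velocity_model(1, 1, 0.1, 0.1),
                    matrix(2, 1, 1))
  expect_equal(one$pos[1, 1], 2)
  expect_error(run_filter(constant_velocity_model(1), matrix(0, 0, 1)),
               class = "lstmkf_invalid_parameter")
})

test_that("scalar filter matches a dense grid-based Bayes filter", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- 1; q <- runif(1, 0.05, 0.3); r <- runif(1, 0.1, 0.5)
    Tlen <- 25
    y <- numeric(Tlen); y[1] <- rnorm(1, 0, 0.5)
    for (t in 2:Tlen) y[t] <- a * y[t - 1] + rnorm(1, 0, sqrt(q))
    z <- y + rnorm(Tlen, 0, sqrt(r))
    z[sample(3:Tlen, 3)] <- NA
    # package filter with identity transition
    b <- belief(z[1], matrix(r))
    means <- numeric(Tlen); means[1] <- z[1]
    for (t in 2:Tlen) {
      b <- kf_predict(b, matrix(a), Q = matrix(q))
      if (!is.na(z[t])) b <- kf_update(b, z[t], matrix(r))
      means[t] <- b$y
    }
    ref <- grid_bayes_filter(z, a, q, r, y0 = z[1], p0 = r)
    expect_lt(max(abs(means - ref)), 1e-6)
  }
})

test_that("gain-form filter matches the information-form recursion", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    model <- constant_velocity_model(2, dt = 0.2, q = 0.2, r = 0.3)
    # identity-observation comparison on the full state: simulate and filter
    d <- 2
    A <- diag(d); Q <- diag(runif(d, 0.05, 0.3)); R <- diag(runif(d, 0.1, 0.4))
    Tlen <- 60
    z <- matrix(rnorm(Tlen * d), Tlen, d)
    z[sample(2:Tlen, 5), ] <- NA
    b <- belief(z[1, ], diag(0.5, d))
    means <- matrix(NA_real_, Tlen, d); means[1, ] <- z[1, ]
    for (t in 2:Tlen) {
      b <- kf_predict(b, A, Q = Q)
      if (!anyNA(z[t, ])) b <- kf_update(b, z[t, ], R)
      means[t, ] <- b$y
    }
    ref <- info_filter(z, A, Q, R, y0 = z[1, ], P0 = diag(0.5, d))
    expect_lt(max(abs(means - ref)), 1e-9)
  }
})

test_that("posterior covariance stays symmetric PSD and never grows in update", {
  set.seed(9)
  for (i in 1:2000) {
    d <- sample(2:4, 1)
    L <- matrix(rnorm(d * d), d)
    P <- crossprod(L) + diag(1e-6, d)
    Lr <- matrix(rnorm(d * d), d)
    R <- crossprod(Lr) + diag(1e-6, d)
    b <- kf_update(belief(rnorm(d), P), rnorm(d), R)
    expect_lt(max(abs(b$P - t(b$P))), 1e-9)
    expect_gt(min(eigen(b$P, symmetric = TRUE, only.values = TRUE)$values),
              -1e-9)
    expect_lte(sum(diag(b$P)), sum(diag(P)) + 1e-12)
  }
})

test_that("matched-model filtering beats raw measurements over replicates", {
  wins <- 0
  for (seed in 1:50) {
    set.seed(seed)
    q <- 0.05; r <- 0.4; Tlen <- 80
    y <- cumsum(rnorm(Tlen, 0, sqrt(q)))
    z <- y + rnorm(Tlen, 0, sqrt(r))
    b <- belief(z[1], matrix(r))
    est <- numeric(Tlen); est[1] <- z[1]
    for (t in 2:Tlen) {
      b <- kf_predict(b, matrix(1), Q = matrix(q))
      b <- kf_update(b, z[t], matrix(r))
      est[t] <- b$y
    }
    if (rmse(y, est)$overall < rmse(y, z)$overall) wins <- wins + 1
  }
  expect_gte(wins, 45)
})
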