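# small model used across several blocks
tiny_model <- function(seed = 41, d = 2, jitter = 0.05) {
  set.seed(seed)
  cfg <- lstmkf_config(d = d, f_hidden = c(8, 8, 8), f_fc = c(8, 8),
                       q_hidden = 8, r_hidden = 8, p0 = 0.5)
  m <- lstmkf_init(cfg)
  if (jitter > 0) {
    for (nm in names(m$params))
      m$params[[nm]][] <- m$params[[nm]][] +
        rnorm(length(m$params[[nm]]), 0, jitter)
  }
  m
}

test_that("transition prediction reduces to zero network and identity bypass", {
  set.seed(40)
  cfg <- lstmkf_config(d = 3, f_hidden = c(4, 4, 4), f_fc = c(4, 4),
                       residual_f = FALSE)
  m <- lstmkf_init(cfg)
  for (nm in grep("^f\\.", names(m$params), value = TRUE))
    m$params[[nm]][] <- 0
  out <- predict_state(m, c(1, -2, 3))
  expect_equal(out$y_prime, c(0, 0, 0))
  # identity bypass
  mb <- m
  mb$cfg$f_bypass <- TRUE
  expect_equal(predict_state(mb, c(1, -2, 3))$y_prime, c(1, -2, 3))
  expect_equal(jacobian_of_f(mb, c(1, -2, 3)), diag(3))
  # zero network without residual: constant function, zero Jacobian
  expect_equal(jacobian_of_f(m, c(1, -2, 3)), matrix(0, 3, 3))
  expect_error(predict_state(m, c(1, NA, 3)), class = "lstmkf_invalid_parameter")
})

test_that("transition prediction equals independent layer-by-layer evaluation", {
  m <- tiny_model(seed = 42, d = 2)
  cfg <- m$cfg
  y0 <- c(0.7, -1.1)
  y_ref <- c(0.2, -0.3)
  out <- predict_state(m, y0, y_ref = y_ref)
  # naive re-evaluation (relative encoding: input is the scaled increment)
  x <- (y0 - y_ref) * cfg$input_scale
  h <- x
  states <- lapply(cfg$f_hidden, function(n) list(h = rep(0, n), C = rep(0, n)))
  p <- m$params
  for (l in 1:3) {
    w <- list(W_f = p[[paste0("f.l", l, ".W_f")]],
              W_i = p[[paste0("f.l", l, ".W_i")]],
              W_c = p[[paste0("f.l", l, ".W_c")]],
              W_o = p[[paste0("f.l", l, ".W_o")]],
              b_f = p[[paste0("f.l", l, ".b_f")]],
              b_i = p[[paste0("f.l", l, ".b_i")]],
              b_c = p[[paste0("f.l", l, ".b_c")]],
              b_o = p[[paste0("f.l", l, ".b_o")]])
    r <- naive_lstm_step(h, states[[l]]$h, states[[l]]$C, w)
    h <- r$h
  }
  a1 <- pmax(p[["f.fc1.W"]] %*% h + p[["f.fc1.b"]], 0)
  a2 <- pmax(p[["f.fc2.W"]] %*% a1 + p[["f.fc2.b"]], 0)
  g <- p[["f.fc3.W"]] %*% a2 + p[["f.fc3.b"]] + p[["f.skip.W"]] %*% x
  expect_equal(out$y_prime, y0 + as.vector(g), tolerance = 1e-10)
})

test_that("transition Jacobian matches central finite differences", {
  m <- tiny_model(seed = 43, d = 3)
  y0 <- c(0.5, -0.2, 1.4)
  y_ref <- c(0.1, 0.1, 1.0)   # fixed reference so FD moves the input
  Fj <- jacobian_of_f(m, y0, y_ref = y_ref)
  h <- 1e-5
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    fp <- predict_state(m, y0 + e, y_ref = y_ref)$y_prime
    fm <- predict_state(m, y0 - e, y_ref = y_ref)$y_prime
    fd <- (fp - fm) / (2 * h)
    expect_equal(Fj[, j], fd, tolerance = 1e-4)
  }
})

test_that("covariance heads emit strictly positive diagonals via exp", {
  set.seed(44)
  cfg <- lstmkf_config(d = 2, q_hidden = 4, r_hidden = 4, q0 = 1, r0 = 1,
                       r_adaptive = FALSE)
  m <- lstmkf_init(cfg)
  # zero network: exp(0) = 1 on the diagonal
  expect_equal(predict_Q(m, c(0.3, -0.5))$Q_diag, c(1, 1))
  expect_equal(predict_R(m, c(0.3, -0.5))$R_diag, c(1, 1))
  # adaptive transform: the head emits the multiplicative correction,
  # which starts at the configured innovation-energy fraction
  set.seed(44)
  ma <- lstmkf_init(lstmkf_config(d = 2, q_hidden = 4, r_hidden = 4,
                                  r_gamma0 = 0.1))
  expect_equal(predict_R(ma, c(0.3, -0.5))$R_diag, c(0.1, 0.1))
  # raw output (ln 2, ln 3) is forced to diag(2, 3)
  m2 <- m
  m2$params[["q.fc.b"]] <- matrix(log(c(2, 3)), 2, 1)
  expect_equal(predict_Q(m2, c(0, 0))$Q_diag, c(2, 3))
  # positivity across random parameters and inputs
  for (i in 1:200) {
    m3 <- m
    for (nm in grep("^(q|r)\\.", names(m3$params), value = TRUE))
      m3$params[[nm]][] <- rnorm(length(m3$params[[nm]]), 0, 2)
    expect_gt(min(predict_Q(m3, rnorm(2, 0, 10))$Q_diag), 0)
    expect_gt(min(predict_R(m3, rnorm(2, 0, 10))$R_diag), 0)
  }
})

test_that("bypassed filter with frozen covariances equals the classical KF", {
  set.seed(45)
  d <- 3; q <- 0.02; r <- 0.3
  cfg <- lstmkf_config(d = d, f_bypass = TRUE, fixed_Q = rep(q, d),
                       fixed_R = rep(r, d), p0 = r)
  m <- lstmkf_init(cfg)
  z <- matrix(cumsum(rnorm(100 * d, 0, 0.2)), 100, d)
  z[c(30, 31, 70), ] <- NA
  out <- lstmkf_filter(m, z)
  ident <- structure(list(A = diag(d), H = diag(d), Q = diag(q, d),
                          R = diag(r, d), pos_idx = 1:d, state_dim = d),
                     class = "lg_model")
  ref <- run_filter(ident, z)
  expect_lt(max(abs(out$est - ref$pos)), 1e-6)
})

test_that("tiny measurement noise pins the estimate to the measurement", {
  set.seed(46)
  d <- 2
  cfg <- lstmkf_config(d = d, f_bypass = TRUE, fixed_Q = rep(0.1, d),
                       fixed_R = rep(1e-10, d))
  m <- lstmkf_init(cfg)
  z <- matrix(rnorm(40), 20, 2)
  out <- lstmkf_filter(m, z)
  expect_lt(max(abs(out$est[-1, ] - z[-1, ])), 1e-6)
})

test_that("gap frames grow the belief covariance by the process noise", {
  m <- tiny_model(seed = 47, d = 2)
  st <- lstmkf_state0(m, c(0, 0))
  prev_tr <- sum(diag(st$P))
  for (t in 1:5) {
    out <- lstmkf_step(m, st, NULL)
    st <- out$st
    expect_gte(sum(diag(st$P)), prev_tr - 1e-12)
    prev_tr <- sum(diag(st$P))
    expect_null(out$R_diag)
  }
})

test_that("sequence loss follows the two-stream mean-norm formula", {
  yt <- matrix(c(1, 2), 1, 2)
  expect_equal(sequence_loss(yt, yt, yt, lambda = 0.7), 0)
  # T=1, ||y - yhat|| = 1, ||y - y'|| = 2, lambda = 0.5 -> 2.0
  yh <- matrix(c(0, 2), 1, 2)
  yp <- matrix(c(1, 4), 1, 2)
  expect_equal(sequence_loss(yt, yh, yp, lambda = 0.5), 2.0)
  # lambda = 0 removes the prediction term
  expect_equal(sequence_loss(yt, yh, yp, lambda = 0), 1.0)
  expect_error(sequence_loss(yt, yh, matrix(0, 2, 2)),
               class = "lstmkf_dimension_error")
  # non-negative; zero iff both streams exact
  set.seed(48)
  a <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(12), 4, 3)
  expect_gt(sequence_loss(a, b, a), 0)
  expect_gt(sequence_loss(a, a, b), 0)
})

test_that("filter loss gradient matches finite differences end to end", {
  m <- tiny_model(seed = 49, d = 2, jitter = 0.1)
  set.seed(50)
  z <- matrix(rnorm(10, 0, 0.5), 5, 2)
  y <- matrix(rnorm(10, 0, 0.5), 5, 2)
  res <- lstmkf_loss_grad(m, z, y)
  h <- 1e-5
  checked <- 0
  for (nm in names(m$params)) {
    g <- res$grads[[nm]]
    if (is.null(g)) next
    i <- which.max(abs(g))
    if (abs(g[i]) < 1e-7) next
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
    mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - h
    fd <- (lstmkf_loss_grad(mp, z, y)$loss -
             lstmkf_loss_grad(mn, z, y)$loss) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-3)
    checked <- checked + 1
  }
  # every module contributed gradient-bearing parameters
  expect_gte(checked, 20)
})

test_that("Q and R diagonals stay positive over random models and inputs", {
  set.seed(51)
  for (i in 1:100) {
    m <- tiny_model(seed = 500 + i, d = 2, jitter = 0.5)
    out <- lstmkf_filter(m, matrix(rnorm(20, 0, 5), 10, 2))
    expect_gt(min(out$Q_diag[-1, ]), 0)
    expect_gt(min(out$R_diag[-1, ]), 0)
  }
})
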