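#' @title Classical Kalman filtering and smoothing baselines
#'
#' @description
#' The linear-Gaussian predict/update recursions together with
#' constant-velocity and constant-acceleration motion models and an
#' exponential-moving-average smoother. These are the classical temporal
#' regularizers the learned filter is compared against, and the update
#' equations are the numeric core that the learned filter re-uses with
#' per-timestep predicted covariances.
#'
#' @name kalman-baselines
NULL

#' Filter belief: state mean and covariance
#'
#' @param y Numeric state mean (length d).
#' @param P d x d state covariance; must be symmetric (to 1e-9).
#' @return An object of class `belief`.
#' @export
belief <- function(y, P) {
  y <- as.numeric(y)
  P <- as.matrix(P)
  d <- length(y)
  if (!identical(dim(P), c(d, d)))
    stop_lstmkf("P must be d x d for a length-d mean", "lstmkf_dimension_error")
  if (max(abs(P - t(P))) > 1e-9)
    stop_lstmkf("P must be symmetric", "lstmkf_invalid_parameter")
  structure(list(y = y, P = P), class = "belief")
}

#' Kalman prediction step
#'
#' Propagates the belief through a (possibly nonlinear) transition:
#' `y' = f(y)`, `P' = F P F' + Q` with `F` the Jacobian of `f`.
#'
#' @param b A [belief()].
#' @param f Transition: a d x d matrix (linear case) or a function of the
#'   state vector.
#' @param F_jac Jacobian of `f` at `b$y`; may be omitted when `f` is a
#'   matrix (then `F = f`).
#' @param Q Process noise covariance (d x d, positive semidefinite).
#' @return The predicted `belief`.
#' @export
#' @examples
#' kf_predict(belief(3, matrix(1)), matrix(2), Q = matrix(0))
kf_predict <- function(b, f, F_jac = NULL, Q) {
  stopifnot(inherits(b, "belief"))
  d <- length(b$y)
  if (is.matrix(f)) {
    if (!identical(dim(f), c(d, d)))
      stop_lstmkf("transition matrix must be d x d", "lstmkf_dimension_error")
    if (is.null(F_jac)) F_jac <- f
    ynew <- as.numeric(f %*% b$y)
  } else {
    if (is.null(F_jac))
      stop_lstmkf("a Jacobian is required for a functional transition",
                  "lstmkf_invalid_parameter")
    ynew <- as.numeric(f(b$y))
  }
  Q <- as.matrix(Q)
  if (!identical(dim(Q), c(d, d)) || !identical(dim(as.matrix(F_jac)), c(d, d)))
    stop_lstmkf("F and Q must be d x d", "lstmkf_dimension_error")
  P <- F_jac %*% b$P %*% t(F_jac) + Q
  belief(ynew, (P + t(P)) / 2)
}

#' Kalman measurement update
#'
#' With identity observation (the default), the gain is
#' `K = P' (P' + R)^{-1}`, the mean `y = y' + K (z - y')` and the
#' covariance `P = (I - K) P'`. A measurement matrix `H` restricted to a
#' subset of the state (as in the position-only baselines) is supported.
#' The posterior covariance is symmetrized after the update.
#'
#' @param b_pred Predicted [belief()].
#' @param z Measurement vector.
#' @param R Measurement noise covariance.
#' @param H Observation matrix; `NULL` means identity.
#' @return The posterior `belief`, with the gain attached as
#'   `attr(, "gain")`.
#' @export
#' @examples
#' kf_update(belief(0, matrix(1)), 2, matrix(1))
kf_update <- function(b_pred, z, R, H = NULL) {
  stopifnot(inherits(b_pred, "belief"))
  d <- length(b_pred$y)
  z <- as.numeric(z)
  R <- as.matrix(R)
  if (is.null(H)) H <- diag(d)
  H <- as.matrix(H)
  m <- length(z)
  if (!identical(dim(H), c(m, d)) || !identical(dim(R), c(m, m)))
    stop_lstmkf("incompatible measurement dimensions", "lstmkf_dimension_error")
  S <- H %*% b_pred$P %*% t(H) + R
  if (rcond(S) < 1e-14)
    stop_lstmkf("innovation covariance is numerically singular",
                "lstmkf_linalg_error")
  K <- b_pred$P %*% t(H) %*% solve(S)
  ynew <- b_pred$y + as.numeric(K %*% (z - H %*% b_pred$y))
  P <- (diag(d) - K %*% H) %*% b_pred$P
  out <- belief(ynew, (P + t(P)) / 2)
  attr(out, "gain") <- K
  out
}

block_diag <- function(...) {
  mats <- list(...)
  n <- vapply(mats, nrow, 1L)
  out <- matrix(0, sum(n), sum(n))
  at <- 0L
  for (m in mats) {
    idx <- at + seq_len(nrow(m))
    out[idx, idx] <- m
    at <- at + nrow(m)
  }
  out
}

#' Constant-velocity linear-Gaussian model
#'
#' State is `[position; velocity]` per spatial axis; the position advances
#' by `dt * velocity` each frame. Process noise follows the standard
#' continuous white-noise-acceleration discretization with intensity `q`;
#' the measurement observes position only with isotropic variance `r`.
#'
#' @param space_dim Number of spatial axes (default 3).
#' @param dt Frame interval in seconds; must be positive.
#' @param q Process noise intensity (m^2/s^3); non-negative.
#' @param r Measurement noise variance (m^2); non-negative.
#' @return A list of class `lg_model` with elements `A`, `H`, `Q`, `R`,
#'   `pos_idx` (rows of the state holding position) and `state_dim`.
#' @export
constant_velocity_model <- function(space_dim = 3, dt = 1, q = 0.1, r = 0.1) {
  if (dt <= 0) stop_lstmkf("dt must be positive", "lstmkf_invalid_parameter")
  if (q < 0 || r < 0) stop_lstmkf("q, r must be non-negative",
                                  "lstmkf_invalid_parameter")
  I <- diag(space_dim)
  A <- rbind(cbind(I, dt * I), cbind(0 * I, I))
  Qa <- rbind(cbind(dt^3 / 3 * I, dt^2 / 2 * I),
              cbind(dt^2 / 2 * I, dt * I)) * q
  H <- cbind(I, 0 * I)
  structure(list(A = A, H = H, Q = Qa, R = r * I,
                 pos_idx = seq_len(space_dim), state_dim = 2 * space_dim,
                 name = "constant_velocity"),
            class = "lg_model")
}

#' Constant-acceleration linear-Gaussian model
#'
#' State is `[position; velocity; acceleration]` per axis with the usual
#' second-order kinematic discretization; process noise is a discrete
#' Wiener acceleration model of intensity `q`.
#'
#' @inheritParams constant_velocity_model
#' @return A list of class `lg_model`; see [constant_velocity_model()].
#' @export
constant_acceleration_model <- function(space_dim = 3, dt = 1, q = 0.1,
                                        r = 0.1) {
  if (dt <= 0) stop_lstmkf("dt must be positive", "lstmkf_invalid_parameter")
  if (q < 0 || r < 0) stop_lstmkf("q, r must be non-negative",
                                  "lstmkf_invalid_parameter")
  I <- diag(space_dim)
  Z <- 0 * I
  A <- rbind(cbind(I, dt * I, dt^2 / 2 * I),
             cbind(Z, I, dt * I),
             cbind(Z, Z, I))
  g <- c(dt^2 / 2, dt, 1)
  Qa <- kronecker(outer(g, g), I) * q
  H <- cbind(I, Z, Z)
  structure(list(A = A, H = H, Q = Qa, R = r * I,
                 pos_idx = seq_len(space_dim), state_dim = 3 * space_dim,
                 name = "constant_acceleration"),
            class = "lg_model")
}

#' Exponential-moving-average smoother
#'
#' `yhat_t = alpha * z_t + (1 - alpha) * yhat_{t-1}`, initialized at the
#' first measurement. Gap frames (rows of `NA`) carry the previous
#' smoothed value forward.
#'
#' @param z_seq Numeric matrix (T x d) of measurements; `NA` rows are gaps.
#' @param alpha Smoothing weight in (0, 1].
#' @return A T x d matrix of smoothed values.
#' @export
#' @examples
#' ema_smoother(matrix(c(0, 2)), 0.5)
ema_smoother <- function(z_seq, alpha) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop_lstmkf("alpha must lie in (0, 1]", "lstmkf_invalid_parameter")
  z <- as.matrix(z_seq)
  out <- z
  prev <- NULL
  for (t in seq_len(nrow(z))) {
    if (anyNA(z[t, ])) {
      if (!is.null(prev)) out[t, ] <- prev
    } else {
      prev <- if (is.null(prev)) z[t, ] else alpha * z[t, ] + (1 - alpha) * prev
      out[t, ] <- prev
    }
  }
  out
}

#' Run a linear-Gaussian Kalman filter over a measurement sequence
#'
#' Initializes the observed (position) block of the state from the first
#' measurement, with zero derivatives and a large prior variance on the
#' unobserved blocks, then alternates prediction with measurement updates.
#' Gap frames (`NA` rows) run prediction only, so the filter coasts on its
#' motion model through occlusions.
#'
#' @param model An `lg_model` from [constant_velocity_model()] or
#'   [constant_acceleration_model()].
#' @param z_seq T x d matrix of measurements (`NA` rows = gaps); the first
#'   frame must be present.
#' @param P0_unobserved Prior variance for unobserved state blocks.
#' @return A list with `means` (T x state_dim), `pos` (T x d filtered
#'   positions), and `cov_diag` (T x state_dim).
#' @export
run_filter <- function(model, z_seq, P0_unobserved = 1e4) {
  stopifnot(inherits(model, "lg_model"))
  z <- as.matrix(z_seq)
  Tlen <- nrow(z)
  if (Tlen < 1) stop_lstmkf("empty measurement sequence", "lstmkf_invalid_parameter")
  if (anyNA(z[1, ]))
    stop_lstmkf("first frame must contain a measurement",
                "lstmkf_invalid_parameter")
  d <- model$state_dim
  m <- length(model$pos_idx)
  if (ncol(z) != m)
    stop_lstmkf("measurement width does not match the model",
                "lstmkf_dimension_error")
  y0 <- numeric(d)
  y0[model$pos_idx] <- z[1, ]
  P0 <- diag(P0_unobserved, d)
  diag(P0)[model$pos_idx] <- diag(model$R)
  b <- belief(y0, P0)
  means <- matrix(NA_real_, Tlen, d)
  cov_diag <- matrix(NA_real_, Tlen, d)
  means[1, ] <- b$y
  cov_diag[1, ] <- diag(b$P)
  for (t in seq_len(Tlen)[-1]) {
    b <- kf_predict(b, model$A, Q = model$Q)
    if (!anyNA(z[t, ])) b <- kf_update(b, z[t, ], model$R, model$H)
    means[t, ] <- b$y
    cov_diag[t, ] <- diag(b$P)
  }
  list(means = means, pos = means[, model$pos_idx, drop = FALSE],
       cov_diag = cov_diag)
}
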