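#' @title The learned LSTM-Kalman filter
#'
#' @description
#' The composite temporal regularizer: a recurrent module `f` predicts the
#' state transition, two further recurrent modules predict per-timestep
#' diagonal process (`Qhat_t`) and measurement (`Rhat_t`) noise
#' covariances, and a Kalman filter fuses prediction and measurement each
#' frame. Covariance propagation uses the Jacobian of the learned
#' transition (extended-Kalman-filter style); the whole per-frame
#' computation is expressed in autodiff primitives so the filter is
#' differentiable end-to-end and can be trained by backpropagation through
#' the filter equations.
#'
#' @name lstm-kf
NULL

#' Configuration of the learned filter
#'
#' @param d State dimension (3 for a translation track).
#' @param f_hidden Integer vector of hidden sizes for the stacked
#'   transition LSTM (reference architecture: three layers of 1024).
#' @param f_fc Hidden sizes of the fully connected stack after the
#'   transition LSTM (reference: 1024, 1024); the final linear layer maps
#'   to `d` and is appended automatically. ReLU on all FC activations
#'   except the last.
#' @param q_hidden,r_hidden Hidden size of the single-layer covariance
#'   LSTMs (reference: 256).
#' @param keep_prob Dropout retention probability after each LSTM layer
#'   during training (reference: 0.7).
#' @param lambda Weight of the prediction-stream term in the training
#'   loss.
#' @param residual_f If `TRUE` the transition is `f(y) = y + g(y)` with
#'   `g` the network output, so a freshly initialized model starts as an
#'   identity-transition filter. The Jacobian accounts for it.
#' @param input_mode Input encoding for the three recurrent modules.
#'   `"relative"` (default) feeds translation-invariant signals: the
#'   transition module sees the previous state increment
#'   `yhat_{t-1} - yhat_{t-2}`, the process-covariance module the
#'   predicted increment `y'_t - yhat_{t-1}`, and the
#'   measurement-covariance module the innovation `z_t - y'_t`.
#'   `"absolute"` feeds the raw state / measurement vectors.
#' @param f_bypass If `TRUE`, force `f` to the identity (reduction mode
#'   used to check the filter against the classical KF).
#' @param fixed_Q,fixed_R Optional length-`d` positive vectors freezing
#'   the predicted covariance diagonals (reduction mode); `NULL` = learn.
#' @param input_scale Fixed multiplier applied to network inputs so meter
#'   -scale coordinates land in the active range of the gate
#'   nonlinearities.
#' @param q0,r0 Initial covariance diagonals: the final covariance layers
#'   start at zero weights with biases `log(q0)`, `log(r0)`.
#' @param p0 Initial belief variance.
#' @param r_adaptive If `TRUE` (default), the measurement-covariance
#'   transform is innovation-moment scaled: the module's exponentiated
#'   raw output multiplies a running exponential average of the squared
#'   innovation held in the filter state, so the untrained filter is
#'   already an innovation-based adaptive filter and the network learns
#'   a log-residual correction. `FALSE` uses the plain `exp` transform.
#' @param r_ema_rho Memory of the squared-innovation average (per frame).
#' @param r_gamma0 Initial multiplicative correction in adaptive mode:
#'   the fraction of innovation energy attributed to measurement noise
#'   before training. Must be well below 1, since part of the innovation
#'   is prediction error; values near 1 make the untrained filter
#'   over-trust its prediction and lag.
#' @param f_lag_window Number of lagged module inputs wired directly to
#'   the transition output (the multi-lag direct connections of the
#'   modified output formulation, realized as a ring buffer in the
#'   filter state). Lag 0 is the skip matrix itself; lags 1 and beyond
#'   get a joint zero-initialized weight matrix. With the relative input
#'   encoding the lagged inputs are past state increments, so these
#'   weights can express a finite-impulse-response velocity smoother.
#' @param f_skip_init Initial value of the transition skip diagonal: `a`
#'   gives the damped velocity extrapolation `y' = y + a (y - y_prev)`
#'   at initialization (a constant-velocity prior); 0 starts from the
#'   identity transition.
#' @param output_skip Add a direct input-to-output connection (the
#'   modified output formulation: zero-initialized weights from the
#'   module input to the module output) on each of the three module
#'   heads. For the transition module this lets the filter express a
#'   damped velocity extrapolation directly; for the covariance modules
#'   an immediate response to the innovation magnitude.
#' @param squared_loss Use squared Euclidean norms in the loss instead of
#'   unsquared.
#' @param cov_range Clamp for predicted covariance diagonals.
#' @return A list of class `lstmkf_config`.
#' @export
lstmkf_config <- function(d = 3,
                          f_hidden = c(64, 64, 64),
                          f_fc = c(64, 64),
                          q_hidden = 32,
                          r_hidden = 32,
                          keep_prob = 0.7,
                          lambda = 1.0,
                          residual_f = TRUE,
                          f_bypass = FALSE,
                          fixed_Q = NULL,
                          fixed_R = NULL,
                          input_mode = c("relative", "absolute"),
                          input_scale = NULL,
                          output_skip = TRUE,
                          r_adaptive = TRUE,
                          r_ema_rho = 0.98,
                          r_gamma0 = 0.1,
                          f_skip_init = 0,
                          f_lag_window = 8,
                          q0 = 1e-2, r0 = 1e-1, p0 = 1.0,
                          squared_loss = FALSE,
                          cov_range = c(1e-8, 1e8)) {
  input_mode <- match.arg(input_mode)
  if (is.null(input_scale))
    input_scale <- if (input_mode == "relative") 1 else 0.05
  stopifnot(d >= 1, all(f_hidden >= 1), all(f_fc >= 1),
            q_hidden >= 1, r_hidden >= 1,
            keep_prob > 0, keep_prob <= 1, lambda >= 0,
            q0 > 0, r0 > 0, p0 > 0)
  structure(list(d = d, f_hidden = f_hidden, f_fc = f_fc,
                 q_hidden = q_hidden, r_hidden = r_hidden,
                 keep_prob = keep_prob, lambda = lambda,
                 residual_f = residual_f, f_bypass = f_bypass,
                 fixed_Q = fixed_Q, fixed_R = fixed_R,
                 input_mode = input_mode, input_scale = input_scale,
                 output_skip = output_skip,
                 r_adaptive = r_adaptive, r_ema_rho = r_ema_rho,
                 r_gamma0 = r_gamma0,
                 f_skip_init = f_skip_init, f_lag_window = f_lag_window,
                 q0 = q0, r0 = r0, p0 = p0,
                 squared_loss = squared_loss, cov_range = cov_range),
            class = "lstmkf_config")
}

#' Named architecture profiles
#'
#' `"reference"` is the full published architecture this package follows
#' (transition LSTM 3 x 1024 with FC 1024/1024/out, covariance LSTMs of
#' 256); `"desk"` is the scaled-down profile used throughout the
#' package's tests and benchmark (3 x 64 with FC 64/64/out, covariance
#' LSTMs of 32).
#'
#' @param name `"reference"` or `"desk"`.
#' @param d State dimension.
#' @param ... Overrides passed to [lstmkf_config()].
#' @return An `lstmkf_config`.
#' @export
lstmkf_profile <- function(name = c("desk", "reference"), d = 3, ...) {
  name <- match.arg(name)
  if (name == "reference") {
    lstmkf_config(d = d, f_hidden = c(1024, 1024, 1024),
                  f_fc = c(1024, 1024), q_hidden = 256, r_hidden = 256, ...)
  } else {
    lstmkf_config(d = d, ...)
  }
}

.fc_init <- function(n_out, n_in, zero = FALSE) {
  r <- 1 / sqrt(n_in)
  W <- if (zero) matrix(0, n_out, n_in)
       else matrix(stats::runif(n_out * n_in, -r, r), n_out)
  list(W = W, b = matrix(0, n_out, 1))
}

.flatten_lstm <- function(prefix, w) {
  out <- list()
  for (nm in c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o"))
    out[[paste(prefix, nm, sep = ".")]] <- w[[nm]]
  out
}

#' Initialize a learned-filter model
#'
#' Parameters are drawn from the current RNG (seed with [set.seed()] for
#' reproducibility). The final transition FC layer and the covariance
#' output layers start at zero weights, so the initial model is an
#' identity-transition Kalman filter with constant covariances `q0`, `r0`
#' -- a sensible filter before any training.
#'
#' @param cfg An [lstmkf_config()].
#' @return A list of class `lstmkf_model` with `cfg` and a flat named
#'   parameter list `params`.
#' @export
lstmkf_init <- function(cfg = lstmkf_config()) {
  stopifnot(inherits(cfg, "lstmkf_config"))
  d <- cfg$d
  params <- list()
  n_in <- d
  for (l in seq_along(cfg$f_hidden)) {
    params <- c(params, .flatten_lstm(paste0("f.l", l),
                                      lstm_weights(n_in, cfg$f_hidden[l])))
    n_in <- cfg$f_hidden[l]
  }
  sizes <- c(utils::tail(cfg$f_hidden, 1), cfg$f_fc, d)
  for (j in seq_along(sizes)[-1]) {
    fc <- .fc_init(sizes[j], sizes[j - 1], zero = (j == length(sizes)))
    params[[paste0("f.fc", j - 1, ".W")]] <- fc$W
    params[[paste0("f.fc", j - 1, ".b")]] <- fc$b
  }
  params <- c(params, .flatten_lstm("q.l1", lstm_weights(d, cfg$q_hidden)))
  params[["q.fc.W"]] <- matrix(0, d, cfg$q_hidden)
  params[["q.fc.b"]] <- matrix(log(cfg$q0), d, 1)
  params <- c(params, .flatten_lstm("r.l1", lstm_weights(d, cfg$r_hidden)))
  params[["r.fc.W"]] <- matrix(0, d, cfg$r_hidden)
  # adaptive transform: the head is a multiplicative log-correction to the
  # innovation-moment baseline, so it starts at exp(0) = 1
  params[["r.fc.b"]] <- matrix(if (isTRUE(cfg$r_adaptive)) log(cfg$r_gamma0)
                               else log(cfg$r0), d, 1)
  if (isTRUE(cfg$output_skip)) {
    params[["f.skip.W"]] <- diag(cfg$f_skip_init / cfg$input_scale, d)
    params[["q.skip.W"]] <- matrix(0, d, d)
    params[["r.skip.W"]] <- matrix(0, d, d)
    if (cfg$f_lag_window > 1)
      params[["f.lag.W"]] <- matrix(0, d, d * (cfg$f_lag_window - 1))
  }
  structure(list(cfg = cfg, params = params), class = "lstmkf_model")
}

# regroup a flat (possibly tape-variable) parameter list into module views
.lstmkf_modules <- function(params, cfg) {
  gates <- c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o")
  lay <- function(prefix, n_in, n_h) {
    w <- lapply(gates, function(nm) params[[paste(prefix, nm, sep = ".")]])
    names(w) <- gates
    w$n_in <- n_in; w$n_h <- n_h
    w
  }
  f_layers <- list()
  n_in <- cfg$d
  for (l in seq_along(cfg$f_hidden)) {
    f_layers[[l]] <- lay(paste0("f.l", l), n_in, cfg$f_hidden[l])
    n_in <- cfg$f_hidden[l]
  }
  n_fc <- length(cfg$f_fc) + 1
  f_fc <- lapply(seq_len(n_fc), function(j)
    list(W = params[[paste0("f.fc", j, ".W")]],
         b = params[[paste0("f.fc", j, ".b")]]))
  list(f_layers = f_layers, f_fc = f_fc,
       q = lay("q.l1", cfg$d, cfg$q_hidden),
       q_fc = list(W = params[["q.fc.W"]], b = params[["q.fc.b"]]),
       r = lay("r.l1", cfg$d, cfg$r_hidden),
       r_fc = list(W = params[["r.fc.W"]], b = params[["r.fc.b"]]),
       f_skip = params[["f.skip.W"]],
       f_lag = params[["f.lag.W"]],
       q_skip = params[["q.skip.W"]],
       r_skip = params[["r.skip.W"]])
}

#' Fresh filter state initialized at the first measurement
#'
#' @param model An [lstmkf_init()] model.
#' @param z1 First-frame measurement (length d).
#' @return A list of class `lstmkf_state`: zeroed recurrent states and the
#'   belief `y = z1`, `P = p0 * I`.
#' @export
lstmkf_state0 <- function(model, z1) {
  cfg <- model$cfg
  z1 <- as.numeric(z1)
  if (length(z1) != cfg$d || anyNA(z1))
    stop_lstmkf("first measurement must be a complete length-d vector",
                "lstmkf_invalid_parameter")
  structure(list(
    f_states = lapply(cfg$f_hidden, lstm_state0),
    q_state = lstm_state0(cfg$q_hidden),
    r_state = lstm_state0(cfg$r_hidden),
    y = matrix(z1, ncol = 1),
    y_pp = matrix(z1, ncol = 1),   # posterior one step further back
    r_ema = matrix(cfg$r0, cfg$d, 1),  # running squared-innovation average
    x_hist = matrix(0, cfg$d * max(cfg$f_lag_window - 1, 0), 1),
    P = diag(cfg$p0, cfg$d)), class = "lstmkf_state")
}

# transition network forward + Jacobian chain; st entries may be advars.
# y_pp (the posterior one step further back) is the reference point of the
# relative input encoding and is held fixed in the Jacobian.
# y_prev / y_pp may carry B columns (a batch of sequences); F_jac is then
# returned as B horizontal d x d blocks (d x B*d)
.f_forward <- function(mods, cfg, f_states, y_prev, y_pp, training,
                       x_hist = NULL) {
  d <- cfg$d
  B <- ncol(ad_value(y_prev))
  Irep <- do.call(cbind, rep(list(diag(d)), B))
  if (cfg$f_bypass) {
    return(list(y_prime = y_prev, F_jac = Irep, f_states = f_states,
                x_hist = x_hist))
  }
  x <- if (cfg$input_mode == "relative")
    ad_scale(ad_sub(y_prev, y_pp), cfg$input_scale)
  else ad_scale(y_prev, cfg$input_scale)
  M <- Irep * cfg$input_scale       # d(input)/d(y_prev), blockwise
  rs <- if (B == 1) function(v, m) ad_rowscale(v, m)
        else function(v, m) ad_rowscale_bcols(v, m, d)
  inp <- x
  for (l in seq_along(mods$f_layers)) {
    w <- mods$f_layers[[l]]
    stp <- lstm_step(inp, f_states[[l]], w)
    f_states[[l]] <- stp$state
    M <- lstm_jvp(w, stp$internals, M)
    inp <- stp$h
    if (training && cfg$keep_prob < 1) {
      # one mask per layer, shared across the batch columns
      mask <- matrix((stats::runif(w$n_h) < cfg$keep_prob) / cfg$keep_prob,
                     ncol = 1)
      inp <- ad_rowscale(mask, inp)
      M <- ad_rowscale(mask, M)
    }
  }
  n_fc <- length(mods$f_fc)
  for (j in seq_len(n_fc)) {
    fc <- mods$f_fc[[j]]
    pre <- ad_addcol(ad_matmul(fc$W, inp), fc$b)
    M <- ad_matmul(fc$W, M)
    if (j < n_fc) {
      inp <- ad_relu(pre)
      M <- rs(ad_step(pre), M)
    } else {
      inp <- pre
    }
  }
  if (!is.null(mods$f_skip)) {
    # direct input-to-output connection (modified output): g += W_skip x
    inp <- ad_add(inp, ad_matmul(mods$f_skip, x))
    M <- ad_add(M, ad_matmul(ad_scale(mods$f_skip, cfg$input_scale), Irep))
    if (!is.null(mods$f_lag) && !is.null(x_hist)) {
      # lagged direct connections (ring buffer of past module inputs);
      # lags are state, so they do not enter the Jacobian
      inp <- ad_add(inp, ad_matmul(mods$f_lag, x_hist))
      keep <- seq_len(nrow(ad_value(x_hist)) - d)
      x_hist <- ad_rbind2(x, ad_rows(x_hist, keep))
    }
  }
  if (cfg$residual_f) {
    y_prime <- ad_add(y_prev, inp)
    F_jac <- ad_add(Irep, M)
  } else {
    y_prime <- inp
    F_jac <- M
  }
  list(y_prime = y_prime, F_jac = F_jac, f_states = f_states,
       x_hist = x_hist)
}

# single-layer covariance head: diag entries exp(clamped raw output);
# x_raw is the (already encoded) input signal. In relative mode the
# magnitude of the signal is what carries variance information, so the
# module sees |x|; the optional skip matrix connects it directly to the
# raw output (modified output formulation).
.cov_forward <- function(w, fc, cfg, state, x_raw, training, skip = NULL) {
  if (cfg$input_mode == "relative") x_raw <- ad_abs(x_raw)
  x <- ad_scale(x_raw, cfg$input_scale)
  stp <- lstm_step(x, state, w)
  h <- stp$h
  if (training && cfg$keep_prob < 1) {
    mask <- matrix((stats::runif(w$n_h) < cfg$keep_prob) / cfg$keep_prob,
                   ncol = 1)
    h <- ad_rowscale(mask, h)
  }
  raw <- ad_addcol(ad_matmul(fc$W, h), fc$b)
  # saturating direct connection: bounds the covariance response to large
  # innovations, so an adaptive initialization cannot run away
  if (!is.null(skip)) raw <- ad_add(raw, ad_matmul(skip, ad_tanh(x)))
  diagv <- ad_exp(ad_clamp(raw, log(cfg$cov_range[1]), log(cfg$cov_range[2])))
  list(diag = diagv, state = stp$state)
}

# one full filter step; z is a d-vector or NULL (gap frame)
.lstmkf_step_core <- function(mods, cfg, st, z, training = FALSE) {
  d <- cfg$d
  ff <- .f_forward(mods, cfg, st$f_states, st$y, st$y_pp, training,
                   x_hist = st$x_hist)
  st$f_states <- ff$f_states
  st$x_hist <- ff$x_hist
  y_prime <- ff$y_prime
  Fj <- ff$F_jac
  if (!is.null(cfg$fixed_Q)) {
    Qd <- matrix(cfg$fixed_Q, ncol = 1)
    Qm <- diag(cfg$fixed_Q, d)
  } else {
    q_in <- if (cfg$input_mode == "relative") ad_sub(y_prime, st$y)
            else y_prime
    qq <- .cov_forward(mods$q, mods$q_fc, cfg, st$q_state, q_in, training,
                       skip = mods$q_skip)
    st$q_state <- qq$state
    Qd <- qq$diag
    Qm <- ad_diagm(Qd)
  }
  st$y_pp <- st$y
  P_pred <- ad_add(ad_matmul(ad_matmul(Fj, st$P), ad_t(Fj)), Qm)
  if (is.null(z)) {
    st$y <- y_prime
    st$P <- P_pred
    return(list(st = st, y_hat = y_prime, y_prime = y_prime,
                Q_diag = Qd, R_diag = NULL))
  }
  zc <- matrix(as.numeric(z), ncol = 1)
  if (!is.null(cfg$fixed_R)) {
    Rd <- matrix(cfg$fixed_R, ncol = 1)
    Rm <- diag(cfg$fixed_R, d)
  } else {
    e_in <- ad_sub(zc, y_prime)
    r_in <- if (cfg$input_mode == "relative") e_in else zc
    rr <- .cov_forward(mods$r, mods$r_fc, cfg, st$r_state, r_in, training,
                       skip = mods$r_skip)
    st$r_state <- rr$state
    Rd <- rr$diag
    if (isTRUE(cfg$r_adaptive)) {
      # modulate the running squared-innovation average (pre-update, so
      # the current innovation does not feed its own gain directly)
      Rd <- ad_mul(Rd, st$r_ema)
      st$r_ema <- ad_add(ad_scale(st$r_ema, cfg$r_ema_rho),
                         ad_scale(ad_mul(e_in, e_in), 1 - cfg$r_ema_rho))
    }
    Rm <- ad_diagm(Rd)
  }
  S <- ad_add(P_pred, Rm)
  K <- ad_matmul(P_pred, ad_inv(S))
  y_new <- ad_add(y_prime, ad_matmul(K, ad_sub(zc, y_prime)))
  P_new <- ad_matmul(ad_sub(diag(d), K), P_pred)
  P_new <- ad_scale(ad_add(P_new, ad_t(P_new)), 0.5)
  st$y <- y_new
  st$P <- P_new
  list(st = st, y_hat = y_new, y_prime = y_prime, Q_diag = Qd, R_diag = Rd)
}

#' Advance the learned filter by one frame
#'
#' Runs the transition module and its Jacobian, predicts the process
#' covariance, propagates the belief, and -- if a measurement is present
#' -- predicts the measurement covariance and applies the Kalman update.
#' On a gap frame the prediction becomes the estimate and the belief
#' covariance grows by `Qhat_t`.
#'
#' @param model An `lstmkf_model`.
#' @param st An `lstmkf_state` from [lstmkf_state0()] or a previous step.
#' @param z Measurement (length d) or `NULL` / all-`NA` for a gap frame.
#' @return List with `st` (new state), `y_hat` (posterior mean), `y_prime`
#'   (prior mean), `Q_diag`, `R_diag` (`NULL` on gaps).
#' @export
lstmkf_step <- function(model, st, z = NULL) {
  stopifnot(inherits(model, "lstmkf_model"), inherits(st, "lstmkf_state"))
  if (!is.null(z) && anyNA(z)) z <- NULL
  if (!is.null(z) && any(!is.finite(as.numeric(z))))
    stop_lstmkf("non-finite measurement", "lstmkf_invalid_parameter")
  mods <- .lstmkf_modules(model$params, model$cfg)
  out <- .lstmkf_step_core(mods, model$cfg, st, z, training = FALSE)
  class(out$st) <- "lstmkf_state"
  out
}

#' Transition prediction (prior mean) for one step
#'
#' Runs only the learned transition: `y'_t = f(yhat_{t-1})` through the
#' stacked LSTM and FC layers (ReLU on all but the last).
#'
#' @param model An `lstmkf_model`.
#' @param y_prev Previous posterior mean (length d).
#' @param f_states Optional recurrent states (default: zeros).
#' @param y_ref Reference state for the relative input encoding (the
#'   posterior one step further back); defaults to `y_prev` (zero
#'   increment). Ignored in absolute mode.
#' @return List with `y_prime` (length d) and advanced `f_states`.
#' @export
predict_state <- function(model, y_prev, f_states = NULL, y_ref = NULL) {
  cfg <- model$cfg
  if (any(!is.finite(as.numeric(y_prev))))
    stop_lstmkf("non-finite state input", "lstmkf_invalid_parameter")
  if (is.null(f_states)) f_states <- lapply(cfg$f_hidden, lstm_state0)
  if (is.null(y_ref)) y_ref <- y_prev
  mods <- .lstmkf_modules(model$params, cfg)
  ff <- .f_forward(mods, cfg, f_states, matrix(as.numeric(y_prev), ncol = 1),
                   matrix(as.numeric(y_ref), ncol = 1), training = FALSE)
  list(y_prime = as.numeric(ad_value(ff$y_prime)), f_states = ff$f_states)
}

#' Jacobian of the learned transition
#'
#' `F[i, j] = d f_i / d y_j` at `y_prev` (holding the recurrent state at
#' its current value), assembled analytically layer by layer.
#'
#' @inheritParams predict_state
#' @return A `d x d` matrix.
#' @export
jacobian_of_f <- function(model, y_prev, f_states = NULL, y_ref = NULL) {
  cfg <- model$cfg
  if (is.null(f_states)) f_states <- lapply(cfg$f_hidden, lstm_state0)
  if (is.null(y_ref)) y_ref <- y_prev
  mods <- .lstmkf_modules(model$params, cfg)
  ff <- .f_forward(mods, cfg, f_states, matrix(as.numeric(y_prev), ncol = 1),
                   matrix(as.numeric(y_ref), ncol = 1), training = FALSE)
  ad_value(ff$F_jac)
}

#' Predicted process noise covariance diagonal
#'
#' @param model An `lstmkf_model`.
#' @param y_prime Prior mean input (length d).
#' @param state Optional recurrent state of the covariance LSTM.
#' @param y_prev Previous posterior (relative mode reference); defaults
#'   to `y_prime` (zero increment).
#' @return List with `Q_diag` (length d, strictly positive) and `state`.
#' @export
predict_Q <- function(model, y_prime, state = NULL, y_prev = NULL) {
  cfg <- model$cfg
  if (is.null(state)) state <- lstm_state0(cfg$q_hidden)
  x <- as.numeric(y_prime)
  if (cfg$input_mode == "relative")
    x <- x - (if (is.null(y_prev)) x else as.numeric(y_prev))
  mods <- .lstmkf_modules(model$params, cfg)
  out <- .cov_forward(mods$q, mods$q_fc, cfg, state,
                      matrix(x, ncol = 1), FALSE, skip = mods$q_skip)
  list(Q_diag = as.numeric(ad_value(out$diag)), state = out$state)
}

#' Predicted measurement noise covariance diagonal
#'
#' @param model An `lstmkf_model`.
#' @param z Measurement input (length d).
#' @param state Optional recurrent state of the covariance LSTM.
#' @param y_prime Prior mean (relative mode reference: the module sees
#'   the innovation `z - y_prime`); defaults to `z` (zero innovation).
#' @return List with `R_diag` (length d, strictly positive) and `state`.
#' @export
predict_R <- function(model, z, state = NULL, y_prime = NULL) {
  cfg <- model$cfg
  if (is.null(state)) state <- lstm_state0(cfg$r_hidden)
  x <- as.numeric(z)
  if (cfg$input_mode == "relative")
    x <- x - (if (is.null(y_prime)) x else as.numeric(y_prime))
  mods <- .lstmkf_modules(model$params, cfg)
  out <- .cov_forward(mods$r, mods$r_fc, cfg, state,
                      matrix(x, ncol = 1), FALSE, skip = mods$r_skip)
  list(R_diag = as.numeric(ad_value(out$diag)), state = out$state)
}

#' Run the learned filter over a measurement sequence
#'
#' The belief is initialized at the first measurement (which must be
#' present); every later frame runs one [lstmkf_step()]. Gap frames (`NA`
#' rows) produce prediction-only estimates.
#'
#' @param model An `lstmkf_model`.
#' @param z_seq T x d measurement matrix with `NA` rows for gaps.
#' @return List of T x d matrices: `est` (posterior means), `pred` (prior
#'   means), `Q_diag`, `R_diag` (`NA` on gap frames), and `P_diag`.
#' @export
lstmkf_filter <- function(model, z_seq) {
  z <- as.matrix(z_seq)
  Tlen <- nrow(z)
  d <- model$cfg$d
  if (Tlen < 1) stop_lstmkf("empty sequence", "lstmkf_invalid_parameter")
  st <- lstmkf_state0(model, z[1, ])
  mods <- .lstmkf_modules(model$params, model$cfg)
  est <- pred <- Qd <- Rd <- Pd <- matrix(NA_real_, Tlen, d)
  est[1, ] <- z[1, ]
  pred[1, ] <- z[1, ]
  Pd[1, ] <- diag(st$P)
  for (t in seq_len(Tlen)[-1]) {
    z_t <- if (anyNA(z[t, ])) NULL else z[t, ]
    out <- .lstmkf_step_core(mods, model$cfg, st, z_t, training = FALSE)
    st <- out$st
    est[t, ] <- as.vector(out$y_hat)
    pred[t, ] <- as.vector(out$y_prime)
    Qd[t, ] <- as.vector(out$Q_diag)
    if (!is.null(out$R_diag)) Rd[t, ] <- as.vector(out$R_diag)
    Pd[t, ] <- diag(st$P)
  }
  list(est = est, pred = pred, Q_diag = Qd, R_diag = Rd, P_diag = Pd)
}

#' Training loss over a sequence
#'
#' `L = (1/T) sum_t ( ||y_t - yhat_t|| + lambda ||y_t - y'_t|| )` with
#' Euclidean norms (optionally squared). The second term feeds gradient
#' directly to the transition module, which otherwise learns poorly
#' through the gain-weighted first term alone.
#'
#' @param y_true_seq,y_hat_seq,y_hat_prime_seq T x d matrices: truth,
#'   posterior estimates, prior predictions.
#' @param lambda Weight of the prediction term.
#' @param squared Use squared norms.
#' @return Scalar loss.
#' @export
#' @examples
#' sequence_loss(matrix(0, 1, 2), matrix(c(1, 0), 1), matrix(c(0, 2), 1), 0.5)
sequence_loss <- function(y_true_seq, y_hat_seq, y_hat_prime_seq,
                          lambda = 1, squared = FALSE) {
  yt <- as.matrix(y_true_seq); yh <- as.matrix(y_hat_seq)
  yp <- as.matrix(y_hat_prime_seq)
  if (nrow(yt) < 1 || !all(dim(yt) == dim(yh)) || !all(dim(yt) == dim(yp)))
    stop_lstmkf("sequence lengths/widths must match", "lstmkf_dimension_error")
  n1 <- sqrt(rowSums((yt - yh)^2))
  n2 <- sqrt(rowSums((yt - yp)^2))
  if (squared) { n1 <- n1^2; n2 <- n2^2 }
  mean(n1 + lambda * n2)
}
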