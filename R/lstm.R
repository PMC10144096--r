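#' @title LSTM sequence-processing building blocks
#'
#' @description
#' A standard LSTM cell (forget/input/output gates over the concatenated
#' previous hidden state and current input), a modified output connection
#' that adds direct input-to-output weights over a bounded history window,
#' and a stacked multi-layer forward pass with inverted dropout. All
#' arithmetic goes through the package's autodiff primitives, so the same
#' code runs as plain matrix arithmetic (no tape) or records gradients
#' during training.
#'
#' @name lstm-cells
NULL

#' Initialize LSTM gate weights
#'
#' Weight matrices act on the concatenation `[h_{t-1}; x_t]` (hidden block
#' first). Entries are drawn uniformly in `+/- 1/sqrt(n_h + n_in)` from the
#' current RNG; the forget-gate bias starts at +1 so memory is initially
#' retained.
#'
#' @param n_in Input size.
#' @param n_h Hidden size.
#' @param scale Multiplier on the initialization range.
#' @return A list of class `lstm_weights` with `W_f, W_i, W_c, W_o`
#'   (`n_h x (n_h + n_in)`) and `b_f, b_i, b_c, b_o` (`n_h x 1`).
#' @export
lstm_weights <- function(n_in, n_h, scale = 1) {
  r <- scale / sqrt(n_h + n_in)
  m <- function() matrix(stats::runif(n_h * (n_h + n_in), -r, r), n_h)
  structure(list(W_f = m(), W_i = m(), W_c = m(), W_o = m(),
                 b_f = matrix(1, n_h, 1), b_i = matrix(0, n_h, 1),
                 b_c = matrix(0, n_h, 1), b_o = matrix(0, n_h, 1),
                 n_in = n_in, n_h = n_h),
            class = "lstm_weights")
}

#' Zero initial LSTM state
#' @param n_h Hidden size.
#' @return List with `h` and `C`, both `n_h x 1` zero matrices.
#' @export
lstm_state0 <- function(n_h) list(h = matrix(0, n_h, 1), C = matrix(0, n_h, 1))

#' One LSTM cell step
#'
#' Gates: `f, i, o = sigmoid(W [h, x] + b)`, candidate
#' `Ctilde = tanh(W_c [h, x] + b_c)`, cell `C_new = f * C + i * Ctilde`,
#' output `h_new = o * tanh(C_new)`.
#'
#' @param x Input column vector (`n_in x 1`), plain or tape variable.
#' @param state List `(h, C)` from [lstm_state0()] or a previous step.
#' @param w An `lstm_weights` list (entries may be tape variables).
#' @return List with `h` (the new hidden state), `state` (list `h`, `C`)
#'   and `internals` (gate activations, used by [lstm_jvp()]).
#' @export
lstm_step <- function(x, state, w) {
  nh <- nrow(ad_value(state$h))
  nx <- nrow(ad_value(x))
  if (!is.null(w$n_in) && nx != w$n_in)
    stop_lstmkf("input size does not match the cell weights",
                "lstmkf_dimension_error")
  z <- ad_rbind2(state$h, x)
  f <- ad_sigmoid(ad_addcol(ad_matmul(w$W_f, z), w$b_f))
  i <- ad_sigmoid(ad_addcol(ad_matmul(w$W_i, z), w$b_i))
  ct <- ad_tanh(ad_addcol(ad_matmul(w$W_c, z), w$b_c))
  o <- ad_sigmoid(ad_addcol(ad_matmul(w$W_o, z), w$b_o))
  C_new <- ad_add(ad_mul(f, state$C), ad_mul(i, ct))
  tC <- ad_tanh(C_new)
  h_new <- ad_mul(o, tC)
  list(h = h_new, state = list(h = h_new, C = C_new),
       internals = list(f = f, i = i, o = o, ctilde = ct,
                        C_prev = state$C, tanhC = tC, n_h = nh, n_x = nx))
}

# sigmoid derivative s*(1-s) as tape ops
.dsig <- function(s) ad_mul(s, ad_sub(1, s))

#' Jacobian of an LSTM step with respect to its input, times a matrix
#'
#' Computes `(dh_new/dx) %*% M` analytically from the gate activations of
#' a completed [lstm_step()], holding the previous recurrent state fixed.
#' Expressed in autodiff primitives, so it can itself be differentiated
#' (the covariance propagation of the learned filter needs gradients
#' through the transition Jacobian).
#'
#' When the step was evaluated on a batch of `B` state columns, `M` holds
#' `B` horizontal blocks of width `d` (`n_x x B*d`) and the per-column
#' Jacobians are applied blockwise.
#'
#' @param w The `lstm_weights` used for the step.
#' @param internals The `internals` element returned by [lstm_step()].
#' @param M An `n_x x k` matrix to multiply the Jacobian onto.
#' @return `n_h x k` matrix (tape variable if recording).
#' @export
lstm_jvp <- function(w, internals, M) {
  it <- internals
  B <- ncol(ad_value(it$f))
  d <- ncol(ad_value(M)) / B
  rs <- if (B == 1) function(v, m) ad_rowscale(v, m)
        else function(v, m) ad_rowscale_bcols(v, m, d)
  Mz <- ad_rbind2(matrix(0, it$n_h, ncol(ad_value(M))), M)
  af <- ad_matmul(w$W_f, Mz)
  ai <- ad_matmul(w$W_i, Mz)
  ac <- ad_matmul(w$W_c, Mz)
  ao <- ad_matmul(w$W_o, Mz)
  dC <- ad_add(ad_add(rs(ad_mul(it$C_prev, .dsig(it$f)), af),
                      rs(ad_mul(it$ctilde, .dsig(it$i)), ai)),
               rs(ad_mul(it$i, ad_sub(1, ad_mul(it$ctilde, it$ctilde))), ac))
  ad_add(rs(ad_mul(it$tanhC, .dsig(it$o)), ao),
         rs(ad_mul(it$o, ad_sub(1, ad_mul(it$tanhC, it$tanhC))), dC))
}

#' Parameters of the modified output connection
#'
#' @param V Coefficient matrix applied to the cell state (`out x n_h`).
#' @param W_direct List of direct input-to-output matrices (`out x n_in`),
#'   indexed by lag: `W_direct[[1]]` applies to the most recent input.
#' @param window_len History length retained; defaults to
#'   `length(W_direct)`.
#' @return A list of class `modified_output_params`.
#' @export
modified_output_params <- function(V, W_direct, window_len = length(W_direct)) {
  if (window_len < 0) stop_lstmkf("window_len must be >= 0",
                                  "lstmkf_invalid_parameter")
  structure(list(V = V, W_direct = W_direct, window_len = window_len),
            class = "modified_output_params")
}

#' Modified LSTM output with direct input connections
#'
#' `Y_t = V C_t + sum_n W[n] X_n` over a bounded window of the most recent
#' inputs. The direct connections short-circuit the recurrent path, which
#' counteracts overfitting when training sequences are scarce. A history
#' longer than the window is truncated to the most recent `window_len`
#' entries (with a message).
#'
#' @param C_t Current cell state (`n_h x 1`).
#' @param input_history List of past inputs in chronological order (most
#'   recent last).
#' @param params A [modified_output_params()].
#' @return The output vector `Y_t`.
#' @export
modified_output <- function(C_t, input_history, params) {
  stopifnot(inherits(params, "modified_output_params"))
  n <- length(input_history)
  if (n > params$window_len) {
    message("modified_output: truncating history of ", n,
            " to window of ", params$window_len)
    input_history <- input_history[seq.int(n - params$window_len + 1, n)]
    n <- params$window_len
  }
  Y <- ad_matmul(params$V, C_t)
  for (k in seq_len(n)) {
    # lag k-1: W_direct[[k]] applies to the k-th most recent input
    Y <- ad_add(Y, ad_matmul(params$W_direct[[k]], input_history[[n - k + 1]]))
  }
  Y
}

#' Forward pass through stacked LSTM layers with inverted dropout
#'
#' Layer `l` consumes layer `l-1`'s hidden sequence. In training mode an
#' inverted-dropout mask (kept units scaled by `1/keep_prob`) is applied
#' to each layer's output at every timestep; in evaluation mode the pass
#' is deterministic. Masks are drawn from the current RNG, so a fixed seed
#' reproduces them exactly.
#'
#' @param x_seq T x n_in matrix, one row per timestep.
#' @param layers List of `lstm_weights`, one per layer.
#' @param keep_prob Retention probability in (0, 1].
#' @param training Logical; apply dropout only if `TRUE`.
#' @param init_states Optional list of per-layer states; defaults to zeros.
#' @return List with `h_seq` (T x n_h of the last layer) and `states`
#'   (final per-layer states).
#' @export
stacked_forward <- function(x_seq, layers, keep_prob = 1, training = FALSE,
                            init_states = NULL) {
  if (keep_prob <= 0 || keep_prob > 1)
    stop_lstmkf("keep_prob must lie in (0, 1]", "lstmkf_invalid_parameter")
  x_seq <- as.matrix(x_seq)
  Tlen <- nrow(x_seq)
  L <- length(layers)
  states <- if (is.null(init_states))
    lapply(layers, function(w) lstm_state0(w$n_h)) else init_states
  nh_last <- layers[[L]]$n_h
  h_out <- matrix(NA_real_, Tlen, nh_last)
  for (t in seq_len(Tlen)) {
    inp <- matrix(x_seq[t, ], ncol = 1)
    for (l in seq_len(L)) {
      st <- lstm_step(inp, states[[l]], layers[[l]])
      states[[l]] <- st$state
      inp <- st$h
      if (training && keep_prob < 1) {
        mask <- (stats::runif(layers[[l]]$n_h) < keep_prob) / keep_prob
        inp <- ad_rowscale(matrix(mask, ncol = 1), inp)
      }
    }
    h_out[t, ] <- as.vector(ad_value(inp))
  }
  list(h_seq = h_out, states = states)
}
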