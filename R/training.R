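#' @title Training loops: truncated backpropagation through time
#'
#' @description
#' End-to-end training of the learned Kalman filter and of the plain
#' LSTM regressor baseline. Sequences are consumed in fixed-length
#' windows: recurrent and belief state values are carried across window
#' boundaries while gradients are stopped there (TBPTT). Parameters are
#' updated with the package's infinity-norm Adam optimizer under a
#' per-epoch geometric learning-rate schedule.
#'
#' @name training
NULL

#' Training configuration
#'
#' Defaults are the learned filter's reference schedule: initial learning
#' rate `2e-5` decaying by `0.95` per epoch from the second epoch, and
#' 100-step gradient windows.
#'
#' @param lr0 Initial learning rate.
#' @param decay Per-epoch learning-rate multiplier in (0, 1].
#' @param decay_start_epoch First epoch at which decay applies.
#' @param tbptt_window Gradient window length in time steps.
#' @param batch_size Sequences per gradient step.
#' @param epochs Number of passes over the training set.
#' @param seed RNG seed governing initialization order, dropout masks.
#' @param clip Global gradient-norm clip (`Inf` disables).
#' @param beta1,beta2 Optimizer decay rates.
#' @param patience Early-stopping patience in epochs when a validation
#'   set is supplied (`Inf` disables).
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr0 = 2e-5, decay = 0.95, decay_start_epoch = 2,
                         tbptt_window = 100, batch_size = 1, epochs = 10,
                         seed = 1, clip = 10, beta1 = 0.9, beta2 = 0.999,
                         patience = Inf) {
  stopifnot(lr0 > 0, decay > 0, decay <= 1, tbptt_window >= 1,
            batch_size >= 1, epochs >= 1)
  structure(list(lr0 = lr0, decay = decay,
                 decay_start_epoch = decay_start_epoch,
                 tbptt_window = tbptt_window, batch_size = batch_size,
                 epochs = epochs, seed = seed, clip = clip,
                 beta1 = beta1, beta2 = beta2, patience = patience),
            class = "train_config")
}

#' Per-epoch learning rate
#'
#' Constant at `lr0` before `decay_start_epoch`, then multiplied by
#' `decay` each epoch: with the defaults, epoch 1 trains at `lr0`, epoch 2
#' at `0.95 * lr0`, and so on.
#'
#' @param epoch Epoch number (1-based).
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
#' @examples
#' lr_schedule(2, train_config(lr0 = 2e-5))
lr_schedule <- function(epoch, cfg) {
  stopifnot(epoch >= 1)
  cfg$lr0 * cfg$decay^max(0, epoch - (cfg$decay_start_epoch - 1))
}

# detach an lstmkf filter state to plain values
.detach_state <- function(st) {
  st$f_states <- lapply(st$f_states, function(s)
    list(h = ad_value(s$h), C = ad_value(s$C)))
  st$q_state <- list(h = ad_value(st$q_state$h), C = ad_value(st$q_state$C))
  st$r_state <- list(h = ad_value(st$r_state$h), C = ad_value(st$r_state$C))
  st$y <- ad_value(st$y)
  st$y_pp <- ad_value(st$y_pp)
  st$r_ema <- ad_value(st$r_ema)
  st$x_hist <- ad_value(st$x_hist)
  st$P <- ad_value(st$P)
  st
}

#' Loss and parameter gradient of the learned filter over a (sub)sequence
#'
#' Records the filter forward pass on a gradient tape and backpropagates
#' the sequence loss through the Kalman update, the covariance
#' propagation (including the transition Jacobian) and the recurrent
#' modules. When `st` is `NULL` the belief is initialized at the first
#' row of `z_seq` and the loss runs over frames `2..T`; otherwise all
#' rows are filtered and scored, which is how TBPTT windows after the
#' first are processed.
#'
#' @param model An `lstmkf_model`.
#' @param z_seq T x d measurements (`NA` rows = gaps).
#' @param y_seq T x d ground-truth states.
#' @param st Optional carried `lstmkf_state` (values, not tape nodes).
#' @param training Apply dropout (draws masks from the current RNG).
#' @return List: `loss` (scalar), `grads` (named list aligned with
#'   `model$params`; absent entries mean zero), `st` (detached final
#'   state), `n_frames` (frames scored).
#' @export
lstmkf_loss_grad <- function(model, z_seq, y_seq, st = NULL,
                             training = FALSE) {
  cfg <- model$cfg
  z <- as.matrix(z_seq); y <- as.matrix(y_seq)
  if (!all(dim(z) == dim(y)))
    stop_lstmkf("measurement and truth shapes differ", "lstmkf_dimension_error")
  first <- 1L
  if (is.null(st)) {
    st <- lstmkf_state0(model, z[1, ])
    first <- 2L
  }
  frames <- seq.int(first, nrow(z))
  if (length(frames) < 1)
    stop_lstmkf("no frames to score", "lstmkf_invalid_parameter")
  tape <- ad_tape()
  res <- with_tape(tape, {
    pv <- lapply(model$params, ad_param)
    mods <- .lstmkf_modules(pv, cfg)
    L <- matrix(0, 1, 1)
    for (t in frames) {
      z_t <- if (anyNA(z[t, ])) NULL else z[t, ]
      out <- .lstmkf_step_core(mods, cfg, st, z_t, training = training)
      st <- out$st
      yt <- matrix(y[t, ], ncol = 1)
      e1 <- ad_norm2(ad_sub(yt, out$y_hat))
      e2 <- ad_norm2(ad_sub(yt, out$y_prime))
      if (cfg$squared_loss) { e1 <- ad_mul(e1, e1); e2 <- ad_mul(e2, e2) }
      L <- ad_add(L, ad_add(e1, ad_scale(e2, cfg$lambda)))
    }
    L <- ad_scale(L, 1 / length(frames))
    list(L = L, pv = pv, st = st)
  })
  gr <- ad_backward(tape, res$L)
  grads <- lapply(res$pv, function(p) gr[[p$id]])
  list(loss = as.numeric(ad_value(res$L)), grads = grads,
       st = .detach_state(res$st), n_frames = length(frames))
}

#' Batched loss and gradient over aligned sequence windows
#'
#' Filters `B` equal-length sequences simultaneously: network states carry
#' one column per sequence and the filter covariances form a
#' block-diagonal system, so the per-frame arithmetic is shared. Requires
#' the squared loss (for which the batched loss is exactly the mean of
#' the per-sequence losses). Gap frames are handled per column by zeroing
#' the innovation and making the measurement uninformative
#' (`Rhat = 1e12`) for that column, which reproduces prediction-only
#' behavior to numerical precision; dropout masks are shared across the
#' batch.
#'
#' @param model An `lstmkf_model` with `cfg$squared_loss = TRUE`.
#' @param z_list,y_list Lists of B aligned T x d matrices.
#' @param st Optional carried batch state from a previous window.
#' @param training Apply dropout.
#' @return List: `loss`, `grads`, `st`, `n_frames`.
#' @export
lstmkf_loss_grad_batch <- function(model, z_list, y_list, st = NULL,
                                   training = FALSE) {
  cfg <- model$cfg
  if (!isTRUE(cfg$squared_loss))
    stop_lstmkf("batched training requires the squared loss",
                "lstmkf_invalid_parameter")
  B <- length(z_list)
  d <- cfg$d
  Tlen <- nrow(z_list[[1]])
  stopifnot(B >= 1, length(y_list) == B,
            all(vapply(z_list, nrow, 0L) == Tlen))
  first <- 1L
  if (is.null(st)) {
    z1 <- vapply(z_list, function(z) z[1, ], numeric(d))  # d x B
    if (anyNA(z1))
      stop_lstmkf("first frame of every sequence must be measured",
                  "lstmkf_invalid_parameter")
    st <- list(
      f_states = lapply(cfg$f_hidden, function(n)
        list(h = matrix(0, n, B), C = matrix(0, n, B))),
      q_state = list(h = matrix(0, cfg$q_hidden, B),
                     C = matrix(0, cfg$q_hidden, B)),
      r_state = list(h = matrix(0, cfg$r_hidden, B),
                     C = matrix(0, cfg$r_hidden, B)),
      y = matrix(z1, d, B), y_pp = matrix(z1, d, B),
      r_ema = matrix(cfg$r0, d, B),
      x_hist = matrix(0, d * max(cfg$f_lag_window - 1, 0), B),
      P = diag(cfg$p0, B * d))
    first <- 2L
  }
  frames <- seq.int(first, Tlen)
  big_r <- 1e12
  tape <- ad_tape()
  res <- with_tape(tape, {
    pv <- lapply(model$params, ad_param)
    mods <- .lstmkf_modules(pv, cfg)
    L <- matrix(0, 1, 1)
    for (t in frames) {
      zt <- vapply(z_list, function(z) z[t, ], numeric(d))   # d x B (may NA)
      present <- !apply(is.na(zt), 2, any)
      zt[, !present] <- 0
      maskd <- matrix(rep(as.numeric(present), each = d), d, B)
      ff <- .f_forward(mods, cfg, st$f_states, st$y, st$y_pp, training,
                       x_hist = st$x_hist)
      st$f_states <- ff$f_states
      st$x_hist <- ff$x_hist
      y_prime <- ff$y_prime
      Fbd <- ad_blockdiag(ff$F_jac, d)
      q_in <- if (cfg$input_mode == "relative") ad_sub(y_prime, st$y)
              else y_prime
      qq <- .cov_forward(mods$q, mods$q_fc, cfg, st$q_state, q_in, training,
                         skip = mods$q_skip)
      st$q_state <- qq$state
      Qm <- ad_diagm(ad_vec(qq$diag))
      st$y_pp <- st$y
      P_pred <- ad_add(ad_matmul(ad_matmul(Fbd, st$P), ad_t(Fbd)), Qm)
      # innovation, zeroed on gap columns
      e <- ad_mul(maskd, ad_sub(zt, y_prime))
      r_in <- if (cfg$input_mode == "relative") e else zt
      rr <- .cov_forward(mods$r, mods$r_fc, cfg, st$r_state, r_in, training,
                         skip = mods$r_skip)
      # freeze the measurement-module state on gap columns
      nhr <- cfg$r_hidden
      maskr <- matrix(rep(as.numeric(present), each = nhr), nhr, B)
      st$r_state <- list(
        h = ad_add(ad_mul(maskr, rr$state$h),
                   ad_mul(1 - maskr, st$r_state$h)),
        C = ad_add(ad_mul(maskr, rr$state$C),
                   ad_mul(1 - maskr, st$r_state$C)))
      Rdm <- rr$diag
      if (isTRUE(cfg$r_adaptive)) {
        Rdm <- ad_mul(Rdm, st$r_ema)
        ema_new <- ad_add(ad_scale(st$r_ema, cfg$r_ema_rho),
                          ad_scale(ad_mul(e, e), 1 - cfg$r_ema_rho))
        st$r_ema <- ad_add(ad_mul(maskd, ema_new),
                           ad_mul(1 - maskd, st$r_ema))
      }
      Rd <- ad_add(ad_mul(maskd, Rdm), big_r * (1 - maskd))
      Rm <- ad_diagm(ad_vec(Rd))
      S <- ad_add(P_pred, Rm)
      K <- ad_matmul(P_pred, ad_inv(S))
      y_new_vec <- ad_add(ad_vec(y_prime), ad_matmul(K, ad_vec(e)))
      P_new <- ad_matmul(ad_sub(diag(B * d), K), P_pred)
      st$P <- ad_scale(ad_add(P_new, ad_t(P_new)), 0.5)
      st$y <- ad_unvec(y_new_vec, d, B)
      yt <- vapply(y_list, function(y) y[t, ], numeric(d))
      e1 <- ad_sub(yt, st$y)
      e2 <- ad_sub(yt, y_prime)
      L <- ad_add(L, ad_scale(ad_add(ad_sum(ad_mul(e1, e1)),
                                     ad_scale(ad_sum(ad_mul(e2, e2)),
                                              cfg$lambda)), 1 / B))
    }
    L <- ad_scale(L, 1 / length(frames))
    list(L = L, pv = pv, st = st)
  })
  gr <- ad_backward(tape, res$L)
  grads <- lapply(res$pv, function(p) gr[[p$id]])
  st_out <- res$st
  st_out$f_states <- lapply(st_out$f_states, function(s)
    list(h = ad_value(s$h), C = ad_value(s$C)))
  st_out$q_state <- list(h = ad_value(st_out$q_state$h),
                         C = ad_value(st_out$q_state$C))
  st_out$r_state <- list(h = ad_value(st_out$r_state$h),
                         C = ad_value(st_out$r_state$C))
  st_out$y <- ad_value(st_out$y)
  st_out$y_pp <- ad_value(st_out$y_pp)
  st_out$r_ema <- ad_value(st_out$r_ema)
  st_out$x_hist <- ad_value(st_out$x_hist)
  st_out$P <- ad_value(st_out$P)
  list(loss = as.numeric(ad_value(res$L)), grads = grads, st = st_out,
       n_frames = length(frames))
}

.clip_grads <- function(grads, clip) {
  if (!is.finite(clip)) return(grads)
  ss <- sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g^2), 0))
  nrm <- sqrt(ss)
  if (nrm > clip) grads <- lapply(grads, function(g)
    if (is.null(g)) NULL else g * (clip / nrm))
  grads
}

#' Train the learned filter with truncated backpropagation through time
#'
#' Each sequence is filtered from its first measurement; frames after the
#' first are split into windows of `cfg$tbptt_window`. For every window a
#' gradient is computed with [lstmkf_loss_grad()] and one optimizer step
#' is applied; recurrent and belief state values carry across windows but
#' gradients stop at the boundary. When `val_dataset` is supplied, the
#' validation loss is evaluated each epoch and the parameters with the
#' best validation loss are returned (early stopping after
#' `cfg$patience` epochs without improvement).
#'
#' @param model An `lstmkf_model` (from [lstmkf_init()]).
#' @param dataset List of sequences, each a list with `z` (T x d
#'   measurements, `NA` rows = gaps) and `y` (T x d truth).
#' @param cfg A [train_config()].
#' @param val_dataset Optional validation sequences (same structure).
#' @param verbose Print one line per epoch.
#' @return The trained `lstmkf_model`, with attributes `loss_history`
#'   (per-epoch mean training loss) and, if validating, `val_history`.
#' @export
tbptt_train <- function(model, dataset, cfg = train_config(),
                        val_dataset = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "lstmkf_model"), inherits(cfg, "train_config"),
            length(dataset) >= 1)
  set.seed(cfg$seed)
  opt <- adamax_state(model$params, alpha = cfg$lr0,
                      beta1 = cfg$beta1, beta2 = cfg$beta2)
  hist <- numeric(cfg$epochs)
  val_hist <- numeric(0)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  lens <- vapply(dataset, function(sq) nrow(as.matrix(sq$z)), 0L)
  use_batch <- cfg$batch_size > 1 && isTRUE(model$cfg$squared_loss) &&
    length(unique(lens)) == 1
  groups <- if (use_batch)
    split(seq_along(dataset), ceiling(seq_along(dataset) / cfg$batch_size))
  else as.list(seq_along(dataset))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch, cfg)
    tot <- 0; n <- 0
    for (gi in groups) {
      zs <- lapply(dataset[gi], function(sq) as.matrix(sq$z))
      ys <- lapply(dataset[gi], function(sq) as.matrix(sq$y))
      Tlen <- nrow(zs[[1]])
      st <- NULL
      t0 <- 1L
      while (t0 < Tlen || (t0 == 1L && Tlen == 1L)) {
        t1 <- min(t0 + cfg$tbptt_window - 1L, Tlen)
        idx <- seq.int(t0, t1)
        res <- if (length(gi) > 1) {
          lstmkf_loss_grad_batch(model,
                                 lapply(zs, function(z) z[idx, , drop = FALSE]),
                                 lapply(ys, function(y) y[idx, , drop = FALSE]),
                                 st = st, training = TRUE)
        } else {
          lstmkf_loss_grad(model, zs[[1]][idx, , drop = FALSE],
                           ys[[1]][idx, , drop = FALSE],
                           st = st, training = TRUE)
        }
        grads <- .clip_grads(res$grads, cfg$clip)
        up <- apply_update(model$params, grads, opt, lr = lr)
        model$params <- up$params
        opt <- up$state
        st <- res$st
        tot <- tot + res$loss * res$n_frames * length(gi)
        n <- n + res$n_frames * length(gi)
        t0 <- t1 + 1L
        if (t1 >= Tlen) break
      }
    }
    hist[epoch] <- tot / n
    if (!is.null(val_dataset)) {
      vl <- mean(vapply(val_dataset, function(sq) {
        out <- lstmkf_filter(model, sq$z)
        sequence_loss(sq$y[-1, , drop = FALSE], out$est[-1, , drop = FALSE],
                      out$pred[-1, , drop = FALSE], model$cfg$lambda,
                      model$cfg$squared_loss)
      }, 0))
      val_hist <- c(val_hist, vl)
      if (vl < best$loss) best <- list(loss = vl, params = model$params,
                                       epoch = epoch)
      if (verbose)
        message(sprintf("epoch %d lr %.3g train %.4f val %.4f",
                        epoch, lr, hist[epoch], vl))
      if (epoch - best$epoch >= cfg$patience) {
        hist <- hist[seq_len(epoch)]
        break
      }
    } else if (verbose) {
      message(sprintf("epoch %d lr %.3g train %.4f", epoch, lr, hist[epoch]))
    }
  }
  if (!is.null(val_dataset)) model$params <- best$params
  attr(model, "loss_history") <- hist
  if (!is.null(val_dataset)) attr(model, "val_history") <- val_hist
  model
}

# ---- plain LSTM regressor baseline ----------------------------------------

#' Configuration of the plain LSTM baseline
#'
#' Defaults follow the reference setup for the standard-LSTM comparison:
#' a single layer of 16 hidden units, batch size 2, learning rate 5e-4,
#' 120 epochs, 10-step gradient windows.
#'
#' @param hidden Hidden units.
#' @param input_scale Input multiplier (as in [lstmkf_config()]).
#' @param lr0,decay,tbptt_window,batch_size,epochs As [train_config()].
#' @param ... Further overrides passed to [train_config()].
#' @return A `train_config` with extra fields `hidden`, `input_scale`.
#' @export
std_lstm_config <- function(hidden = 16, input_scale = 0.05, lr0 = 5e-4,
                            decay = 1, tbptt_window = 10, batch_size = 2,
                            epochs = 120, ...) {
  cfg <- train_config(lr0 = lr0, decay = decay, tbptt_window = tbptt_window,
                      batch_size = batch_size, epochs = epochs, ...)
  cfg$hidden <- hidden
  cfg$input_scale <- input_scale
  cfg
}

.std_lstm_window <- function(params, cfg, d, st, z_rows, y_rows) {
  w <- c(params[grep("^l1\\.", names(params))])
  names(w) <- sub("^l1\\.", "", names(w))
  w$n_in <- d; w$n_h <- cfg$hidden
  L <- matrix(0, 1, 1)
  for (t in seq_len(nrow(z_rows))) {
    x <- matrix(z_rows[t, ] * cfg$input_scale, ncol = 1)
    stp <- lstm_step(x, st, w)
    st <- stp$state
    yhat <- ad_add(ad_matmul(params[["head.W"]], stp$h), params[["head.b"]])
    L <- ad_add(L, ad_norm2(ad_sub(matrix(y_rows[t, ], ncol = 1), yhat)))
  }
  list(L = ad_scale(L, 1 / nrow(z_rows)), st = st)
}

#' Train the plain LSTM regressor baseline
#'
#' A single-layer LSTM plus linear head mapping the measurement `z_t`
#' directly to a state estimate, trained with the same windowed loop and
#' optimizer as the learned filter. Gap frames repeat the last available
#' measurement as input. This baseline has no filtering structure, so
#' with scarce training data it generalizes poorly -- the failure mode
#' the learned filter is designed to avoid.
#'
#' @param dataset List of sequences (`z`, `y`) as in [tbptt_train()].
#' @param cfg A [std_lstm_config()].
#' @param verbose Print one line per epoch.
#' @return A list of class `std_lstm_model` with `params`, `cfg`, `d` and
#'   attribute `loss_history`.
#' @export
train_std_lstm_baseline <- function(dataset, cfg = std_lstm_config(),
                                    verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  set.seed(cfg$seed)
  d <- ncol(as.matrix(dataset[[1]]$z))
  params <- .flatten_lstm("l1", lstm_weights(d, cfg$hidden))
  head <- .fc_init(d, cfg$hidden)
  params[["head.W"]] <- head$W
  params[["head.b"]] <- head$b
  opt <- adamax_state(params, alpha = cfg$lr0, beta1 = cfg$beta1,
                      beta2 = cfg$beta2)
  # impute gaps by carrying the last available measurement forward
  filled <- lapply(dataset, function(sq) {
    z <- as.matrix(sq$z)
    for (t in seq_len(nrow(z))[-1])
      if (anyNA(z[t, ])) z[t, ] <- z[t - 1, ]
    list(z = z, y = as.matrix(sq$y))
  })
  hist <- numeric(cfg$epochs)
  batches <- split(seq_along(filled),
                   ceiling(seq_along(filled) / cfg$batch_size))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch, cfg)
    tot <- 0; n <- 0
    for (bi in batches) {
      sts <- lapply(bi, function(i) lstm_state0(cfg$hidden))
      done <- rep(FALSE, length(bi))
      t0 <- 1L
      while (!all(done)) {
        tape <- ad_tape()
        res <- with_tape(tape, {
          pv <- lapply(params, ad_param)
          L <- matrix(0, 1, 1)
          k <- 0
          newst <- sts
          for (j in seq_along(bi)) {
            sq <- filled[[bi[j]]]
            Tlen <- nrow(sq$z)
            if (t0 > Tlen) { done[j] <- TRUE; next }
            idx <- seq.int(t0, min(t0 + cfg$tbptt_window - 1L, Tlen))
            wres <- .std_lstm_window(pv, cfg, d, sts[[j]],
                                     sq$z[idx, , drop = FALSE],
                                     sq$y[idx, , drop = FALSE])
            L <- ad_add(L, wres$L)
            newst[[j]] <- wres$st
            k <- k + 1
            if (max(idx) >= Tlen) done[j] <- TRUE
          }
          list(L = if (k > 0) ad_scale(L, 1 / k) else NULL, pv = pv,
               newst = newst, k = k)
        })
        if (res$k > 0) {
          gr <- ad_backward(tape, res$L)
          grads <- .clip_grads(lapply(res$pv, function(p) gr[[p$id]]),
                               cfg$clip)
          up <- apply_update(params, grads, opt, lr = lr)
          params <- up$params
          opt <- up$state
          tot <- tot + as.numeric(ad_value(res$L))
          n <- n + 1
        }
        sts <- lapply(res$newst, function(s)
          list(h = ad_value(s$h), C = ad_value(s$C)))
        t0 <- t0 + cfg$tbptt_window
      }
    }
    hist[epoch] <- if (n > 0) tot / n else NA_real_
    if (verbose)
      message(sprintf("std-lstm epoch %d lr %.3g loss %.4f",
                      epoch, lr, hist[epoch]))
  }
  structure(list(params = params, cfg = cfg, d = d,
                 loss_history = hist), class = "std_lstm_model")
}

#' Predict with a trained plain-LSTM baseline
#'
#' @param model A `std_lstm_model` from [train_std_lstm_baseline()].
#' @param z_seq T x d measurements (`NA` rows are carried forward).
#' @return T x d matrix of estimates.
#' @export
std_lstm_predict <- function(model, z_seq) {
  z <- as.matrix(z_seq)
  for (t in seq_len(nrow(z))[-1]) if (anyNA(z[t, ])) z[t, ] <- z[t - 1, ]
  w <- model$params[grep("^l1\\.", names(model$params))]
  names(w) <- sub("^l1\\.", "", names(w))
  w$n_in <- model$d; w$n_h <- model$cfg$hidden
  st <- lstm_state0(model$cfg$hidden)
  out <- matrix(NA_real_, nrow(z), model$d)
  for (t in seq_len(nrow(z))) {
    stp <- lstm_step(matrix(z[t, ] * model$cfg$input_scale, ncol = 1), st, w)
    st <- stp$state
    out[t, ] <- as.vector(model$params[["head.W"]] %*% stp$h +
                            model$params[["head.b"]])
  }
  out
}
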