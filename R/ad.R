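#' @title Reverse-mode automatic differentiation tape
#'
#' @description
#' A minimal reverse-mode automatic differentiation engine over dense
#' matrices. Every differentiable quantity is a node on a tape; operations
#' record their inputs and a local backward rule, and [ad_backward()] walks
#' the tape once to accumulate gradients with respect to every parameter.
#'
#' The engine exists so that the learned Kalman filter can be trained
#' end-to-end: gradients of the tracking loss flow through the Kalman gain,
#' the covariance propagation (including the transition Jacobian) and the
#' three recurrent modules. All operations also work on plain matrices when
#' no tape is active, so the same model code serves for inference at full
#' speed.
#'
#' Scalars are represented as 1x1 matrices; column vectors as nx1 matrices.
#'
#' @name ad-tape
#' @keywords internal
NULL

.ad_env <- new.env(parent = emptyenv())
.ad_env$tape <- NULL

#' Create a fresh gradient tape
#'
#' @return An environment holding the recorded nodes.
#' @export
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  # nodes live in a hashed environment keyed by id: O(1) insertion without
  # copy-on-write of a growing list
  t$e <- new.env(parent = emptyenv(), size = 4096L)
  t$n <- 0L
  t
}

#' Run an expression while recording onto a tape
#'
#' @param tape A tape created by [ad_tape()].
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_tape <- function(tape, expr) {
  old <- .ad_env$tape
  .ad_env$tape <- tape
  on.exit(.ad_env$tape <- old)
  expr
}

active_tape <- function() .ad_env$tape

#' Numeric value of a tape variable (or pass a plain matrix through)
#' @param x An `advar` or plain numeric matrix.
#' @export
ad_value <- function(x) if (is.list(x)) x$value else x

.pid <- function(x) if (is.list(x)) x$id else 0L

.push <- function(tape, value, parents, backward, extra = NULL) {
  n <- tape$n + 1L
  tape$n <- n
  assign(as.character(n),
         list(parents = parents, backward = backward, extra = extra),
         envir = tape$e)
  out <- list(value = value, id = n)
  class(out) <- "advar"
  out
}

#' Register a parameter (leaf) on the active tape
#'
#' @param value Numeric matrix.
#' @return An `advar` whose gradient is retrievable after [ad_backward()].
#' @export
ad_param <- function(value) {
  t <- active_tape()
  if (is.null(t)) return(value)
  .push(t, value, integer(0), NULL)
}

# --- primitive operations ---------------------------------------------------
# Each primitive computes on plain values, and records a node only when a
# tape is active. Backward rules receive the upstream gradient `g` and the
# node's `extra` list, and return one gradient per parent (NULL for
# non-advar parents).

ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  out <- av %*% bv
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, c(.pid(a), .pid(b)),
        function(g, e) list(tcrossprod(g, e$bv), crossprod(e$av, g)),
        list(av = av, bv = bv))
}

ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  t <- active_tape()
  out <- av + bv
  if (is.null(t)) return(out)
  .push(t, out, c(.pid(a), .pid(b)),
        function(g, e) list(g, g), NULL)
}

ad_sub <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  t <- active_tape()
  out <- av - bv
  if (is.null(t)) return(out)
  .push(t, out, c(.pid(a), .pid(b)),
        function(g, e) list(g, -g), NULL)
}

ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  t <- active_tape()
  out <- av * bv
  if (is.null(t)) return(out)
  .push(t, out, c(.pid(a), .pid(b)),
        function(g, e) list(g * e$bv, g * e$av),
        list(av = av, bv = bv))
}

# scale rows of matrix m by column vector v (diag(v) %*% m)
ad_rowscale <- function(v, m) {
  vv <- ad_value(v); mv <- ad_value(m)
  out <- mv * as.vector(vv)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, c(.pid(v), .pid(m)),
        function(g, e) list(matrix(rowSums(g * e$mv), ncol = 1),
                            g * as.vector(e$vv)),
        list(vv = vv, mv = mv))
}

# multiply by a plain (non-differentiated) scalar
ad_scale <- function(a, s) {
  av <- ad_value(a)
  out <- av * s
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a), function(g, e) list(g * e$s), list(s = s))
}

ad_sigmoid <- function(a) {
  av <- ad_value(a)
  out <- 1 / (1 + exp(-av))
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a),
        function(g, e) list(g * e$out * (1 - e$out)), list(out = out))
}

ad_tanh <- function(a) {
  av <- ad_value(a)
  out <- tanh(av)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a),
        function(g, e) list(g * (1 - e$out^2)), list(out = out))
}

ad_relu <- function(a) {
  av <- ad_value(a)
  out <- pmax(av, 0)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a),
        function(g, e) list(g * (e$av > 0)), list(av = av))
}

# heaviside step: piecewise-constant, gradient zero almost everywhere
ad_step <- function(a) {
  av <- ad_value(a)
  out <- (av > 0) * 1
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a), function(g, e) list(0 * g), NULL)
}

ad_abs <- function(a) {
  av <- ad_value(a)
  out <- abs(av)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a), function(g, e) list(g * sign(e$av)), list(av = av))
}

ad_exp <- function(a) {
  av <- ad_value(a)
  out <- exp(av)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a), function(g, e) list(g * e$out), list(out = out))
}

ad_sqrt <- function(a) {
  av <- ad_value(a)
  out <- sqrt(av)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a), function(g, e) list(g / (2 * e$out)), list(out = out))
}

ad_sum <- function(a) {
  av <- ad_value(a)
  out <- matrix(sum(av), 1, 1)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a),
        function(g, e) list(matrix(as.numeric(g), e$nr, e$nc)),
        list(nr = nrow(av), nc = ncol(av)))
}

ad_t <- function(a) {
  av <- ad_value(a)
  out <- t(av)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a), function(g, e) list(t(g)), NULL)
}

# matrix inverse; d(X^{-1}) rule: grad_X = -X^{-T} G X^{-T}
ad_inv <- function(a) {
  av <- ad_value(a)
  out <- solve(av)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a),
        function(g, e) list(-t(e$out) %*% g %*% t(e$out)), list(out = out))
}

# stack two column blocks vertically: [a; b]
ad_rbind2 <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  out <- rbind(av, bv)
  t <- active_tape()
  if (is.null(t)) return(out)
  na <- nrow(av)
  .push(t, out, c(.pid(a), .pid(b)),
        function(g, e) list(g[seq_len(e$na), , drop = FALSE],
                            g[-seq_len(e$na), , drop = FALSE]),
        list(na = na))
}

# row slice; backward scatters into the sliced rows
ad_rows <- function(a, idx) {
  av <- ad_value(a)
  out <- av[idx, , drop = FALSE]
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a),
        function(g, e) {
          full <- matrix(0, e$nr, e$nc)
          full[e$idx, ] <- g
          list(full)
        },
        list(idx = idx, nr = nrow(av), nc = ncol(av)))
}

# column vector -> diagonal matrix
ad_diagm <- function(v) {
  vv <- ad_value(v)
  out <- diag(as.vector(vv), nrow = length(vv))
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(v),
        function(g, e) list(matrix(diag(g), ncol = 1)), NULL)
}

# clamp with pass-through gradient inside the interval, zero outside
ad_clamp <- function(a, lo, hi) {
  av <- ad_value(a)
  out <- pmin(pmax(av, lo), hi)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a),
        function(g, e) list(g * (e$av > e$lo & e$av < e$hi)),
        list(av = av, lo = lo, hi = hi))
}

# smoothed Euclidean norm sqrt(sum(a^2) + eps): differentiable at 0
ad_norm2 <- function(a, eps = 1e-12) {
  av <- ad_value(a)
  out <- matrix(sqrt(sum(av^2) + eps), 1, 1)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(a),
        function(g, e) list(as.numeric(g) * e$av / as.numeric(e$out)),
        list(av = av, out = out))
}

# add a column vector to every column of a matrix (bias broadcast)
ad_addcol <- function(m, v) {
  mv <- ad_value(m); vv <- ad_value(v)
  out <- mv + as.vector(vv)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, c(.pid(m), .pid(v)),
        function(g, e) list(g, matrix(rowSums(g), ncol = 1)), NULL)
}

# reshape a matrix to a single column (column-major) and back
ad_vec <- function(m) {
  mv <- ad_value(m)
  out <- matrix(as.vector(mv), ncol = 1)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(m),
        function(g, e) list(matrix(g, e$nr, e$nc)),
        list(nr = nrow(mv), nc = ncol(mv)))
}

ad_unvec <- function(v, nr, nc) {
  vv <- ad_value(v)
  out <- matrix(as.vector(vv), nr, nc)
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(v), function(g, e) list(matrix(as.vector(g), ncol = 1)),
        NULL)
}

# scale column-blocks of M (n x B*d, B blocks of width d) row-wise by the
# matching column of V (n x B): batched version of ad_rowscale
ad_rowscale_bcols <- function(V, M, d) {
  vv <- ad_value(V); mv <- ad_value(M)
  B <- ncol(vv)
  vexp <- vv[, rep(seq_len(B), each = d), drop = FALSE]
  out <- mv * vexp
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, c(.pid(V), .pid(M)),
        function(g, e) {
          gv <- g * e$mv
          dV <- matrix(0, nrow(e$vv), ncol(e$vv))
          for (b in seq_len(e$B))
            dV[, b] <- rowSums(gv[, (b - 1) * e$d + seq_len(e$d), drop = FALSE])
          list(dV, g * e$vexp)
        },
        list(vv = vv, mv = mv, vexp = vexp, B = B, d = d))
}

# assemble a (B*d) x (B*d) block-diagonal matrix from B horizontal d x d
# blocks of M (d x B*d)
ad_blockdiag <- function(M, d) {
  mv <- ad_value(M)
  B <- ncol(mv) / d
  out <- matrix(0, B * d, B * d)
  for (b in seq_len(B)) {
    idx <- (b - 1) * d + seq_len(d)
    out[idx, idx] <- mv[, idx]
  }
  t <- active_tape()
  if (is.null(t)) return(out)
  .push(t, out, .pid(M),
        function(g, e) {
          dM <- matrix(0, e$d, e$B * e$d)
          for (b in seq_len(e$B)) {
            idx <- (b - 1) * e$d + seq_len(e$d)
            dM[, idx] <- g[idx, idx]
          }
          list(dM)
        },
        list(B = B, d = d))
}

# detach: value flows, gradient does not (used at TBPTT window boundaries)
ad_detach <- function(a) ad_value(a)

#' Backpropagate through a recorded tape
#'
#' @param tape The tape that recorded the computation.
#' @param loss An `advar` holding a 1x1 loss value.
#' @return A list `grads` indexed by node id; use the ids of [ad_param()]
#'   leaves to retrieve parameter gradients. Parameters not reached by the
#'   loss get `NULL` (treat as zero).
#' @export
ad_backward <- function(tape, loss) {
  stopifnot(inherits(loss, "advar"))
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- matrix(1, 1, 1)
  for (id in seq(loss$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- get(as.character(id), envir = tape$e, inherits = FALSE)
    if (is.null(node$backward)) next
    pg <- node$backward(g, node$extra)
    ps <- node$parents
    for (k in seq_along(ps)) {
      p <- ps[k]
      if (p > 0L && !is.null(pg[[k]])) {
        grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
      }
    }
  }
  grads
}
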