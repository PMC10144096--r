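#' @title Infinity-norm Adam optimizer
#'
#' @description
#' Adam's second-moment accumulator generalized from the L2 norm to the
#' Lp norm. Large finite `p` is numerically unstable, but the `p -> Inf`
#' limit collapses to the simple recursion
#' `v_t = max(beta2 * v_{t-1}, |g_t|)`, whose closed form is
#' `v_t = max_i beta2^(t-i) |g_i|`. Step sizes are scaled by `1/v_t`; the
#' infinity-norm accumulator needs no initialization-bias correction. The
#' first moment keeps Adam's exponentially decayed average with the usual
#' bias correction.
#'
#' @name optimizer-adamax
NULL

#' Infinity-norm accumulator update (recursive form)
#'
#' @param v_prev Previous accumulator (any numeric array, `>= 0`);
#'   initialize at 0.
#' @param g Current gradient (same shape).
#' @param beta2 Decay rate in `[0, 1)` (1 permitted: running maximum).
#' @return Elementwise `max(beta2 * v_prev, |g|)`.
#' @export
#' @examples
#' update_v_inf(0, 2, 0.99)
update_v_inf <- function(v_prev, g, beta2) {
  pmax(beta2 * v_prev, abs(g))
}

#' Infinity-norm accumulator, expanded closed form
#'
#' `v_t = max_i beta2^(t-i) |g_i|` over the whole gradient history; the
#' independent oracle for [update_v_inf()].
#'
#' @param g_list List of gradients `g_1 .. g_t` (same shapes).
#' @param beta2 Decay rate.
#' @return The accumulator after `t` steps.
#' @export
expanded_v_inf <- function(g_list, beta2) {
  t_len <- length(g_list)
  if (t_len < 1) stop_lstmkf("empty gradient sequence", "lstmkf_invalid_parameter")
  out <- abs(g_list[[t_len]]) * 0
  for (i in seq_len(t_len)) {
    out <- pmax(out, beta2^(t_len - i) * abs(g_list[[i]]))
  }
  out
}

#' Finite-p Lp-norm accumulator update
#'
#' `v_t = beta2^p v_{t-1} + (1 - beta2^p) |g_t|^p`. The effective scale is
#' `v_t^(1/p)`; as `p` grows this approaches the infinity-norm recursion,
#' at the cost of numerical overflow for large `p` (surfaced as an error).
#'
#' @param v_prev Previous accumulator.
#' @param g Current gradient.
#' @param beta2 Decay rate in `[0, 1)`.
#' @param p Norm order, finite `>= 1`.
#' @return The updated accumulator (not root-taken).
#' @export
update_v_p <- function(v_prev, g, beta2, p) {
  if (!is.finite(p) || p < 1)
    stop_lstmkf("p must be finite and >= 1", "lstmkf_invalid_parameter")
  out <- beta2^p * v_prev + (1 - beta2^p) * abs(g)^p
  if (any(!is.finite(out)))
    stop_lstmkf("Lp accumulator overflow at large p; use the infinity-norm form",
                "lstmkf_numeric_range")
  out
}

#' Create optimizer state for a parameter list
#'
#' @param params Named list of numeric arrays (the trainable parameters).
#' @param alpha Step size.
#' @param beta1 First-moment decay in `[0, 1)`.
#' @param beta2 Infinity-norm decay in `[0, 1)`.
#' @param eps Denominator offset.
#' @return A list of class `adamax_state` with zeroed accumulators.
#' @export
adamax_state <- function(params, alpha = 2e-5, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  zeros <- lapply(params, function(p) p * 0)
  structure(list(t = 0L, m = zeros, v = zeros, alpha = alpha,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adamax_state")
}

#' Apply one optimizer step
#'
#' First moment `m <- beta1 m + (1 - beta1) g` (bias-corrected by
#' `1 - beta1^t`); scale accumulator per [update_v_inf()]; parameter step
#' `theta <- theta - alpha * mhat / (v + eps)`. Parameters whose gradient
#' is non-finite are skipped for the step (with a warning) rather than
#' poisoning the model.
#'
#' @param params Named list of parameter arrays.
#' @param grads Named list of gradients (same names/shapes; `NULL` entries
#'   are treated as zero gradient).
#' @param state An [adamax_state()].
#' @param lr Optional learning-rate override for this step (schedules).
#' @return List with updated `params` and `state`.
#' @export
apply_update <- function(params, grads, state, lr = NULL) {
  stopifnot(inherits(state, "adamax_state"))
  state$t <- state$t + 1L
  alpha <- if (is.null(lr)) state$alpha else lr
  bc <- 1 - state$beta1^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    if (any(!is.finite(g))) {
      warning("non-finite gradient for '", nm, "'; skipping its update")
      next
    }
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- update_v_inf(state$v[[nm]], g, state$beta2)
    params[[nm]] <- params[[nm]] -
      alpha * (state$m[[nm]] / bc) / (state$v[[nm]] + state$eps)
  }
  list(params = params, state = state)
}
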