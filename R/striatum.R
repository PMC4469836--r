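#' Cortico-striatal weights of the three MSN pools
#'
#' Holds the weight tables `w_d1`, `w_d2`, `w_d1d2` over (state, action)
#' for the D1R, D2R and D1R-D2R co-expressing medium spiny neuron pools,
#' together with their learning rates.  With a one-hot cortical state code,
#' the response of a pool to its trained state-action pair equals the
#' weight entry, so `Q = y_D1` and `h = y_D1D2`.
#'
#' Weights are initialized uniformly at random in `[0, 1]` from R's current
#' random number generator (experiments seed a per-agent stream before
#' building the agent), matching the experimental protocol; pass `init` to
#' override.
#'
#' `complementary = TRUE` activates the two-stimulus, two-response coupling
#' used in the reversal-learning task: `w_d1` is constrained so that
#' \eqn{w_{D1}(s, a_1) = -w_{D1}(s, a_2)} and \eqn{w_{D1}(s_1, a) =
#' -w_{D1}(s_2, a)}, leaving a single free value that every update writes
#' through (the other three entries are mirrored).  It requires a 2 x 2
#' table and only constrains `w_d1`.
#'
#' @param n_states,n_actions Table dimensions.
#' @param eta Named numeric vector of learning rates
#'   `c(d1 = , d2 = , d1d2 = )`, all `> 0`.
#' @param init Either a function `n -> numeric(n)` used to fill each table,
#'   or a single number.
#' @param complementary Constrain `w_d1` as described above.
#' @return An object of class `msn_weights`.
#' @export
msn_weights <- function(n_states, n_actions,
                        eta = c(d1 = 0.1, d2 = 0.1, d1d2 = 0.1),
                        init = stats::runif, complementary = FALSE) {
  stopifnot(n_states >= 1, n_actions >= 1,
            all(c("d1", "d2", "d1d2") %in% names(eta)), all(eta > 0))
  fill <- function() {
    v <- if (is.function(init)) init(n_states * n_actions) else
      rep_len(init, n_states * n_actions)
    matrix(v, n_states, n_actions)
  }
  w <- structure(list(
    w_d1 = fill(), w_d2 = fill(), w_d1d2 = fill(),
    eta = eta[c("d1", "d2", "d1d2")],
    n_states = as.integer(n_states), n_actions = as.integer(n_actions),
    complementary = isTRUE(complementary)
  ), class = "msn_weights")
  if (w$complementary) {
    if (n_states != 2L || n_actions != 2L) {
      stop("complementary weights require a 2 x 2 state-action table")
    }
    # one free value; seed it from the (1,1) draw and mirror the rest
    w <- enforce_complementarity(w, 1L, 1L)
  }
  w
}

# Rebuild the 2x2 complementary w_d1 table from the entry at (state, action).
enforce_complementarity <- function(weights, state, action) {
  s_mat <- matrix(c(1, -1, -1, 1), 2L, 2L)
  q <- weights$w_d1[state, action] * s_mat[state, action]
  weights$w_d1 <- q * s_mat
  weights
}

#' MSN responses for a state-action pair
#'
#' With one-hot cortical input the response of each pool is its weight
#' entry: \eqn{y_P(s, a) = w_P(s, a)}.  The value and risk read-outs of the
#' network are `Q = y_d1` and `h = y_d1d2`.
#'
#' @param weights An [msn_weights()] object.
#' @param state,action Indices.
#' @return Named numeric vector `c(d1 = , d2 = , d1d2 = )`.
#' @export
msn_response <- function(weights, state, action) {
  check_windex(weights, state, action)
  c(d1 = weights$w_d1[state, action],
    d2 = weights$w_d2[state, action],
    d1d2 = weights$w_d1d2[state, action])
}

check_windex <- function(weights, state, action) {
  if (state < 1L || state > weights$n_states ||
      action < 1L || action > weights$n_actions) {
    stop(sprintf("unknown (state, action) index (%d, %d) for a %d x %d table",
                 state, action, weights$n_states, weights$n_actions))
  }
  invisible(TRUE)
}

#' Dopamine-gated Hebbian weight update
#'
#' Updates the three pools at the visited state-action pair:
#' \deqn{w_P(s_t, a_t) \mathrel{+}= \eta_P\, \lambda^{Str}_P(\delta),}
#' for \eqn{P \in \{D1, D2, D1D2\}}, where \eqn{\lambda^{Str}_{D1D2} =
#' \lambda_{h-D1} + \lambda_{h-D2}}.  The dopamine signal \eqn{\delta}
#' should already include any disease-state clamping (see [apply_pd()]).
#' Only the visited entry of each pool changes; pools whose gain is absent
#' from `gains` (e.g. no D2R column in a preset) are left untouched.
#' Weights are not clipped: the bounded gains limit each step intrinsically.
#'
#' @param weights An [msn_weights()] object.
#' @param gains A [gain_set()] with striatal-plasticity parameters.
#' @param state,action Visited pair.
#' @param delta Dopamine prediction-error signal.
#' @return The updated weights.
#' @export
update_weights <- function(weights, gains, state, action, delta) {
  stopifnot(inherits(gains, "gain_set"))
  check_windex(weights, state, action)
  eta <- weights$eta
  weights$w_d1[state, action] <- weights$w_d1[state, action] +
    eta[["d1"]] * evaluate_gain(gains$d1, delta)
  if (!is.null(gains$d2)) {
    weights$w_d2[state, action] <- weights$w_d2[state, action] +
      eta[["d2"]] * evaluate_gain(gains$d2, delta)
  }
  weights$w_d1d2[state, action] <- weights$w_d1d2[state, action] +
    eta[["d1d2"]] * d1d2_gain(gains, delta)
  if (weights$complementary) {
    weights <- enforce_complementarity(weights, state, action)
  }
  weights
}

#' Network utility of a state-action pair
#'
#' \eqn{U = y_{D1} - \alpha_{D1D2}\,\mathrm{sign}(y_{D1})\,y_{D1D2}}: the
#' network counterpart of [utility()], with the D1R pool supplying the
#' value and the co-expressing pool the risk.  `sign_term = FALSE` ablates
#' the sign non-linearity (the term is applied with sign fixed at +1), the
#' manipulation used to probe the gain/loss asymmetry of risk attitudes.
#'
#' @param weights An [msn_weights()] object.
#' @param alpha_d1d2 Serotonin multiplier on the co-expressing pool.
#' @param state,action Indices.
#' @param sign_term Keep the `sign(Q)` factor?
#' @return Scalar utility.
#' @export
network_utility <- function(weights, alpha_d1d2, state, action,
                            sign_term = TRUE) {
  y <- msn_response(weights, state, action)
  s <- if (sign_term) sign0(y[["d1"]]) else 1
  y[["d1"]] - alpha_d1d2 * s * y[["d1d2"]]
}

#' Trial-to-trial change in utility
#'
#' \eqn{\delta_U = U_t - U_{t-1}}, the dopamine signal that gates the
#' direct versus indirect pathway at GPi.  By package convention
#' \eqn{U_t} is the utility, under current weights, of the greedy-utility
#' action in the current state, and \eqn{U_{t-1}} is the stored utility of
#' the previously executed action at its selection time; on an agent's
#' first trial \eqn{\delta_U = 0}.
#'
#' @param u_current Current utility \eqn{U_t}.
#' @param u_previous Stored previous utility \eqn{U_{t-1}}, or `NULL` on
#'   the first trial.
#' @return Scalar \eqn{\delta_U}.
#' @export
delta_u <- function(u_current, u_previous) {
  if (is.null(u_previous)) return(0)
  u_current - u_previous
}

#' Tabulate MSN weights
#'
#' @param x An [msn_weights()] object.
#' @param ... Unused.
#' @return Data frame with columns `state`, `action`, `w_d1`, `w_d2`,
#'   `w_d1d2`.
#' @export
as.data.frame.msn_weights <- function(x, ...) {
  grid <- expand.grid(state = seq_len(x$n_states),
                      action = seq_len(x$n_actions))
  idx <- as.matrix(grid)
  data.frame(grid, w_d1 = x$w_d1[idx], w_d2 = x$w_d2[idx],
             w_d1d2 = x$w_d1d2[idx])
}

#' @export
print.msn_weights <- function(x, ...) {
  cat(sprintf("<msn_weights %d states x %d actions; eta = [%s]%s>\n",
              x$n_states, x$n_actions,
              paste(sprintf("%s=%g", names(x$eta), x$eta), collapse = ", "),
              if (x$complementary) "; complementary w_d1" else ""))
  invisible(x)
}
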