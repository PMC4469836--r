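#' STN-GPe-GPi-thalamus network parameters
#'
#' Parameters of the downstream action-selection dynamics.  The
#' subthalamic nucleus (STN) and globus pallidus externa (GPe) form a
#' coupled excitatory-inhibitory loop with one neuron (channel) per
#' available action; its oscillatory/chaotic activity supplies the
#' stochasticity of action selection that the lumped model obtains from a
#' softmax.  Both layers have complete lateral connectivity: the STN
#' weight matrix has `1 + eps_s` on the diagonal and `eps_s` elsewhere,
#' the GPe matrix is `eps_g` everywhere.
#'
#' @param eps_s STN lateral strength (default `+0.1`).
#' @param eps_g GPe lateral strength (default `-0.1`).
#' @param inv_tau_s Euler step size of the STN layer, \eqn{1/\tau_s}
#'   (default `0.1`).
#' @param inv_tau_g Euler step size of the GPe layer, \eqn{1/\tau_g}
#'   (default `0.033`).
#' @param lambda_stn Slope of the STN tanh output (default `3`).
#' @param w_stn_gpi STN to GPi weight per channel (default `1`).
#' @param n_steps Number of joint Euler steps integrated per decision
#'   (default `25`).
#' @param init_scale Half-width of the uniform random initialization of
#'   `x_stn` and `x_gpe` at the start of a decision (default `0.1`); the
#'   thalamic state starts at 0.
#' @param selection_rule `"final"` selects the channel whose thalamic
#'   activation is maximal at the last step; `"integral"` selects by the
#'   running time-integral of the activation.
#' @param persist_state Keep STN-GPe state across decisions instead of
#'   re-initializing per decision.
#' @param silence_stn Force the STN output to zero (diagnostic; selection
#'   is then driven purely by the direct pathway).
#' @return An object of class `network_params`.
#' @export
network_params <- function(eps_s = 0.1, eps_g = -0.1,
                           inv_tau_s = 0.1, inv_tau_g = 0.033,
                           lambda_stn = 3, w_stn_gpi = 1, n_steps = 25L,
                           init_scale = 0.1,
                           selection_rule = c("final", "integral"),
                           persist_state = FALSE, silence_stn = FALSE) {
  selection_rule <- match.arg(selection_rule)
  stopifnot(inv_tau_s > 0, inv_tau_g > 0, n_steps >= 1, init_scale >= 0)
  structure(list(eps_s = eps_s, eps_g = eps_g,
                 inv_tau_s = inv_tau_s, inv_tau_g = inv_tau_g,
                 lambda_stn = lambda_stn, w_stn_gpi = w_stn_gpi,
                 n_steps = as.integer(n_steps), init_scale = init_scale,
                 selection_rule = selection_rule,
                 persist_state = isTRUE(persist_state),
                 silence_stn = isTRUE(silence_stn)),
            class = "network_params")
}

#' Per-decision dynamical state of the selection network
#'
#' @param n_channels Number of action channels.
#' @param params A [network_params()]; `init_scale` controls the uniform
#'   random initialization of the STN and GPe states (drawn from R's
#'   current RNG).
#' @return An object of class `bg_dynamics_state` with vectors `x_stn`,
#'   `y_stn`, `x_gpe`, `x_gpi`, `x_thal`, `y_thal` over channels.
#' @export
bg_dynamics_state <- function(n_channels, params = network_params()) {
  stopifnot(n_channels >= 1)
  s <- params$init_scale
  x_stn <- stats::runif(n_channels, -s, s)
  x_gpe <- stats::runif(n_channels, -s, s)
  structure(list(
    x_stn = x_stn, y_stn = tanh(params$lambda_stn * x_stn),
    x_gpe = x_gpe,
    x_gpi = numeric(n_channels), x_thal = numeric(n_channels),
    y_thal = numeric(n_channels)
  ), class = "bg_dynamics_state")
}

#' Direct-pathway contribution to GPi
#'
#' Per channel \eqn{i}: \eqn{x^{DP}_i = \alpha_{D1}\,
#' \lambda^{GPi}_{D1}(\delta_U)\, y_{D1}(s, a_i)}.  The utility gradient
#' \eqn{\delta_U} is a single scalar shared across channels; the bipolar
#' GPi gain switches the direct pathway between "Go" (facilitating the
#' high-value channel when utility is rising) and its reversal.
#'
#' @param weights An [msn_weights()] object.
#' @param gains A [gain_set()] with GPi gating parameters.
#' @param alpha_d1 Serotonin multiplier on the D1R pathway.
#' @param du Utility gradient \eqn{\delta_U}.
#' @param state State index.
#' @param actions Action indices forming the channels (default: all).
#' @return Numeric vector `x_dp` over channels.
#' @export
dp_contribution <- function(weights, gains, alpha_d1, du, state,
                            actions = seq_len(weights$n_actions)) {
  stopifnot(inherits(gains, "gain_set"))
  y_d1 <- weights$w_d1[state, actions]
  alpha_d1 * evaluate_gain(gains$d1, du) * y_d1
}

#' Indirect-pathway contribution to GPe
#'
#' Per channel: \deqn{x^{IP}_i = \alpha_{D2}\, \lambda^{GPi}_{D2}(\delta_U)
#' \, y_{D2}(s, a_i) + \alpha_{D1D2}\, \mathrm{sign}(y_{D1}(s, a_i))\,
#' \lambda^{GPi}_{D1D2}(\delta_U)\, y_{D1D2}(s, a_i).}
#' The second (risk) term reproduces the gain/loss asymmetry of risk
#' attitudes at the pathway level: for gains it adds striatal inhibition of
#' GPe (suppressing the risky channel), for losses it subtracts it.
#' `sign_term = FALSE` ablates the sign factor (fixed at +1), making the
#' risk term independent of the sign of `y_d1`.
#'
#' @inheritParams dp_contribution
#' @param alpha_d2,alpha_d1d2 Serotonin multipliers on the D2R and
#'   co-expressing pathways.
#' @param sign_term Keep the `sign(y_d1)` factor?
#' @return Numeric vector `x_ip` over channels (fed to the GPe equation
#'   with negative sign: striatal inhibition).
#' @export
ip_contribution <- function(weights, gains, alpha_d2, alpha_d1d2, du, state,
                            actions = seq_len(weights$n_actions),
                            sign_term = TRUE) {
  stopifnot(inherits(gains, "gain_set"))
  y_d1 <- weights$w_d1[state, actions]
  y_d2 <- weights$w_d2[state, actions]
  y_d1d2 <- weights$w_d1d2[state, actions]
  s <- if (sign_term) sign0(y_d1) else 1
  d2_term <- if (is.null(gains$d2)) 0 else
    alpha_d2 * evaluate_gain(gains$d2, du) * y_d2
  d2_term + alpha_d1d2 * s * d1d2_gain(gains, du) * y_d1d2
}

#' One Euler step of the STN-GPe loop
#'
#' Advances the coupled system \deqn{\tau_s \dot x^{STN}_i = -x^{STN}_i +
#' \textstyle\sum_j W^{STN}_{ij} y^{STN}_j - x^{GPe}_i, \qquad
#' \tau_g \dot x^{GPe}_i = -x^{GPe}_i + \textstyle\sum_j W^{GPe}_{ij}
#' x^{GPe}_j + y^{STN}_i - x^{IP}_i,} with \eqn{y^{STN} =
#' \tanh(\lambda^{STN} x^{STN})}, by one explicit-Euler step with step
#' sizes `inv_tau_s`, `inv_tau_g`.  The all-to-all lateral sums reduce to
#' \eqn{W^{STN} y = y + \epsilon_s \sum_j y_j} and \eqn{W^{GPe} x =
#' \epsilon_g \sum_j x_j}.  Both layer updates use the STN output computed
#' from the pre-step state; `y_stn` is refreshed from the new STN state on
#' return.
#'
#' @param state A [bg_dynamics_state()].
#' @param x_ip Indirect-pathway input vector (one entry per channel).
#' @param params A [network_params()].
#' @return The advanced `bg_dynamics_state`.
#' @export
step_stn_gpe <- function(state, x_ip, params) {
  n <- length(state$x_stn)
  if (length(x_ip) != n) {
    stop(sprintf("x_ip has %d entries but the network has %d channels",
                 length(x_ip), n))
  }
  y <- if (params$silence_stn) numeric(n) else
    tanh(params$lambda_stn * state$x_stn)
  x_stn <- state$x_stn + params$inv_tau_s *
    (-state$x_stn + y + params$eps_s * sum(y) - state$x_gpe)
  x_gpe <- state$x_gpe + params$inv_tau_g *
    (-state$x_gpe + params$eps_g * sum(state$x_gpe) + y - x_ip)
  state$x_stn <- x_stn
  state$x_gpe <- x_gpe
  state$y_stn <- if (params$silence_stn) numeric(n) else
    tanh(params$lambda_stn * x_stn)
  state
}

#' Combine direct and indirect pathways at GPi
#'
#' \eqn{x^{GPi}_i = -x^{DP}_i + w^{STN-GPi}_i\, y^{STN}_i}: the direct
#' pathway inhibits GPi while STN excites it.
#'
#' @param x_dp Direct-pathway vector from [dp_contribution()].
#' @param y_stn STN output vector.
#' @param params A [network_params()] supplying `w_stn_gpi`.
#' @return GPi activation vector.
#' @export
gpi_combine <- function(x_dp, y_stn, params = network_params()) {
  -x_dp + params$w_stn_gpi * y_stn
}

#' Integrate a decision and select an action at thalamus
#'
#' Runs `n_steps` joint Euler steps of the STN-GPe loop with the striatal
#' drives `x_dp` and `x_ip` held constant (striatal responses change only
#' between trials).  At every step the thalamic afferent is the negation
#' of the GPi activation, \eqn{x^{Thal} = x^{DP} - w^{STN-GPi} y^{STN} =
#' -x^{GPi}}, and the thalamic state integrates it by explicit Euler with
#' unit step, \eqn{y^{Thal} \leftarrow y^{Thal} + (x^{Thal} - y^{Thal})}.
#' The selected action is the channel whose thalamic activation (or
#' time-integral, under `selection_rule = "integral"`) is maximal after
#' integration; exact ties are broken uniformly at random from R's
#' current RNG.
#'
#' @param x_dp,x_ip Pathway drive vectors (equal length; one entry per
#'   channel).
#' @param params A [network_params()].
#' @param state Optional [bg_dynamics_state()] to continue from; by
#'   default a fresh randomly-initialized state is drawn.
#' @return List with `action` (selected channel index), `state` (final
#'   `bg_dynamics_state`) and `y_thal` (final thalamic activations).
#' @export
select_action <- function(x_dp, x_ip, params = network_params(),
                          state = NULL) {
  n <- length(x_dp)
  if (length(x_ip) != n) stop("x_dp and x_ip must have equal length")
  if (n < 1L) stop("empty action set")
  if (is.null(state)) state <- bg_dynamics_state(n, params)
  integral <- numeric(n)
  for (k in seq_len(params$n_steps)) {
    state <- step_stn_gpe(state, x_ip, params)
    state$x_gpi <- gpi_combine(x_dp, state$y_stn, params)
    state$x_thal <- -state$x_gpi
    state$y_thal <- state$y_thal + (state$x_thal - state$y_thal)
    integral <- integral + state$y_thal
  }
  score <- if (params$selection_rule == "integral") integral else
    state$y_thal
  if (any(!is.finite(score))) {
    stop(sprintf(paste0("non-finite thalamic activation [%s] ",
                        "(x_dp = [%s], x_ip = [%s])"),
                 paste(signif(score, 4), collapse = ", "),
                 paste(signif(x_dp, 4), collapse = ", "),
                 paste(signif(x_ip, 4), collapse = ", ")))
  }
  winners <- which(score == max(score))
  action <- if (length(winners) == 1L) winners else
    winners[[sample.int(length(winners), 1L)]]
  list(action = action, state = state, y_thal = state$y_thal)
}

#' Action selection from striatal read-outs
#'
#' Convenience wrapper that builds the pathway drives from the weights,
#' GPi gains and serotonin parameters for a given state and utility
#' gradient, then integrates the decision with [select_action()].
#'
#' @param weights An [msn_weights()] object.
#' @param gains_gpi A [gain_set()] with GPi gating parameters.
#' @param serotonin A [serotonin_params()].
#' @param du Utility gradient \eqn{\delta_U} for this decision.
#' @param state State index.
#' @param params A [network_params()].
#' @param actions Action indices forming the channels (default: all).
#' @param sign_term Keep the `sign(y_d1)` factor in the risk term?
#' @param dyn_state Optional persisting [bg_dynamics_state()].
#' @return As [select_action()].
#' @export
thalamus_select <- function(weights, gains_gpi, serotonin, du, state,
                            params = network_params(),
                            actions = seq_len(weights$n_actions),
                            sign_term = TRUE, dyn_state = NULL) {
  x_dp <- dp_contribution(weights, gains_gpi, serotonin$alpha_d1, du,
                          state, actions)
  x_ip <- ip_contribution(weights, gains_gpi, serotonin$alpha_d2,
                          serotonin$alpha_d1d2, du, state, actions,
                          sign_term = sign_term)
  res <- select_action(x_dp, x_ip, params, state = dyn_state)
  res$action <- actions[[res$action]]
  res
}
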