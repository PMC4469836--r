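#' Abstract risk-sensitive reinforcement-learning agent
#'
#' The lumped (non-network) model of utility-based decision making.  The
#' agent maintains a value table `Q` (expected reward) and a risk table `h`
#' (variance of the prediction error) over an enumerated finite state x
#' action space.  `Q` is trained by temporal-difference learning and `h` by
#' a risk prediction error \eqn{\xi = \delta^2 - h}, whose fixed point is
#' the outcome variance.  Decisions are based on the utility
#' \deqn{U = Q - \alpha\,\mathrm{sign}(Q)\,h,} which is risk averse for
#' gains (`Q > 0`) and risk seeking for losses (`Q < 0`); `sign(0)` is
#' defined as 0 so that utility degenerates to value at `Q = 0`.  Actions
#' are drawn from a softmax policy with inverse temperature `beta`.
#'
#' This module also serves as a brute-force oracle for the network model:
#' with a linear gain function and matched learning rates the D1R weight
#' trajectory of the network equals this agent's `Q` trajectory exactly.
#'
#' @param n_states,n_actions Size of the state and action space (integers).
#' @param gamma Discount factor in `[0, 1)`; only used by the multi-step
#'   temporal-difference rule.
#' @param eta_q Value learning rate, `> 0`.
#' @param eta_h Risk learning rate, `> 0`.
#' @param alpha Risk-sensitivity coefficient, `>= 0` (the serotonin
#'   correlate of the lumped model).
#' @param beta Softmax inverse temperature, `>= 0`.
#' @param q_init,h_init Initial table values (scalar or matrix).
#' @return An object of class `abstract_agent` with matrix fields `Q`, `h`.
#' @export
#' @examples
#' ag <- abstract_agent(1, 2, eta_q = 0.5)
#' d  <- td_error(ag, 1, 1, reward = 1)    # 1: zero-value baseline
#' ag <- update_value(ag, 1, 1, d)
#' ag$Q[1, 1]                              # 0.5
abstract_agent <- function(n_states, n_actions, gamma = 0.9,
                           eta_q = 0.1, eta_h = 0.1,
                           alpha = 0, beta = 1,
                           q_init = 0, h_init = 0) {
  stopifnot(n_states >= 1, n_actions >= 1,
            gamma >= 0, gamma < 1, eta_q > 0, eta_h > 0,
            alpha >= 0, beta >= 0)
  structure(list(
    Q = matrix(q_init, n_states, n_actions),
    h = matrix(h_init, n_states, n_actions),
    n_states = as.integer(n_states), n_actions = as.integer(n_actions),
    gamma = gamma, eta_q = eta_q, eta_h = eta_h,
    alpha = alpha, beta = beta
  ), class = "abstract_agent")
}

check_index <- function(agent, state, action) {
  if (state < 1L || state > agent$n_states ||
      action < 1L || action > agent$n_actions) {
    stop(sprintf("unknown (state, action) index (%d, %d) for a %d x %d table",
                 state, action, agent$n_states, agent$n_actions))
  }
  invisible(TRUE)
}

#' Temporal-difference error
#'
#' `multi_step` returns \eqn{r + \gamma Q(s', a') - Q(s, a)}; `single_step`
#' returns \eqn{r - Q(s, a)}.  All three simulated experiments are
#' single-step; the multi-step rule is provided for completeness.
#'
#' @param agent An [abstract_agent()].
#' @param state,action Indices of the current state-action pair.
#' @param reward Observed reward.
#' @param next_state,next_action Indices of the successor pair; required
#'   only for `mode = "multi_step"`.
#' @param mode `"single_step"` or `"multi_step"`.
#' @return Scalar TD error \eqn{\delta}.
#' @export
td_error <- function(agent, state, action, reward,
                     next_state = NULL, next_action = NULL,
                     mode = c("single_step", "multi_step")) {
  mode <- match.arg(mode)
  check_index(agent, state, action)
  if (mode == "single_step") {
    return(reward - agent$Q[state, action])
  }
  if (is.null(next_state) || is.null(next_action)) {
    stop("multi_step TD error requires next_state and next_action")
  }
  check_index(agent, next_state, next_action)
  reward + agent$gamma * agent$Q[next_state, next_action] -
    agent$Q[state, action]
}

#' Value update
#'
#' \eqn{Q(s,a) \leftarrow Q(s,a) + \eta_Q \delta}; all other entries are
#' unchanged.
#'
#' @inheritParams td_error
#' @param delta TD error from [td_error()].
#' @param eta_q Learning rate; defaults to the agent's.
#' @return The updated agent.
#' @export
update_value <- function(agent, state, action, delta, eta_q = agent$eta_q) {
  stopifnot(eta_q > 0)
  check_index(agent, state, action)
  agent$Q[state, action] <- agent$Q[state, action] + eta_q * delta
  agent
}

#' Risk prediction error
#'
#' \eqn{\xi = \delta^2 - h(s, a)}.  Its fixed point over repeated updates is
#' \eqn{h = E[\delta^2]}, the variance of the prediction error.
#'
#' @inheritParams update_value
#' @return Scalar risk prediction error \eqn{\xi}.
#' @export
risk_prediction_error <- function(agent, state, action, delta) {
  check_index(agent, state, action)
  delta^2 - agent$h[state, action]
}

#' Risk update
#'
#' \eqn{h(s,a) \leftarrow h(s,a) + \eta_h \xi}.
#'
#' @inheritParams update_value
#' @param xi Risk prediction error from [risk_prediction_error()].
#' @param eta_h Learning rate; defaults to the agent's.
#' @return The updated agent.
#' @export
update_risk <- function(agent, state, action, xi, eta_h = agent$eta_h) {
  stopifnot(eta_h > 0)
  check_index(agent, state, action)
  agent$h[state, action] <- agent$h[state, action] + eta_h * xi
  agent
}

#' Sign with sign(0) = 0
#'
#' The convention used throughout: at `Q = 0` the risk term drops out of
#' the utility, so gains and losses are treated symmetrically around an
#' exactly neutral value.
#' @param x Numeric.
#' @return `sign(x)` with `sign(0) = 0` (base R semantics, kept explicit).
#' @keywords internal
sign0 <- function(x) sign(x)

#' Utility of a state-action pair
#'
#' \eqn{U = Q - \alpha\,\mathrm{sign}(Q)\,h}.  For gains (`Q > 0`) risk is
#' subtracted (risk aversion); for losses (`Q < 0`) risk is added (risk
#' seeking); at `Q = 0`, `U = Q`.
#'
#' @param q Value estimate(s).
#' @param h Risk estimate(s).
#' @param alpha Risk-sensitivity coefficient, `>= 0`.
#' @return Utility, same shape as `q`.
#' @export
#' @examples
#' utility(0.5, 0.2, 1)    #  0.3: risk-averse subtraction
#' utility(-0.5, 0.2, 1)   # -0.3: risk-seeking addition
utility <- function(q, h, alpha) {
  stopifnot(all(alpha >= 0))
  q - alpha * sign0(q) * h
}

#' Softmax policy probabilities
#'
#' \eqn{P(a) = \exp(\beta U_a) / \sum_i \exp(\beta U_i)}, computed with
#' max-subtraction for overflow safety.  `beta = 0` makes all actions
#' equiprobable; `beta` large approaches greedy selection.
#'
#' @param u Numeric vector of utilities, one per available action.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability vector summing to 1.
#' @export
softmax_probs <- function(u, beta) {
  stopifnot(length(u) >= 1, beta >= 0, all(is.finite(u)))
  z <- beta * u
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Sample an action from the softmax policy
#'
#' Draws one action index from [softmax_probs()] using R's global random
#' number generator; the inverse-CDF draw resolves ties through the uniform
#' deviate itself.
#'
#' @inheritParams softmax_probs
#' @return A list with `action` (index) and `probs` (probability vector).
#' @export
softmax_policy <- function(u, beta) {
  if (length(u) == 0L) stop("empty action set")
  p <- softmax_probs(u, beta)
  a <- findInterval(stats::runif(1), cumsum(p)) + 1L
  a <- min(a, length(p))  # guard against cumsum rounding at 1
  list(action = a, probs = p)
}

#' Train the abstract agent on an i.i.d. reward stream
#'
#' Repeatedly applies the single-step TD and risk updates for one
#' state-action pair fed with a fixed reward sequence.  Used to study the
#' fixed points of the value and risk estimators (the value converges to
#' the mean reward, the risk to the reward variance).
#'
#' @param agent An [abstract_agent()].
#' @param rewards Numeric vector; one update per element.
#' @param state,action Pair to train (defaults 1, 1).
#' @param learn_risk Update `h` alongside `Q`?
#' @return The trained agent.
#' @export
train_iid <- function(agent, rewards, state = 1L, action = 1L,
                      learn_risk = TRUE) {
  for (r in rewards) {
    d <- td_error(agent, state, action, r)
    if (learn_risk) {
      xi <- risk_prediction_error(agent, state, action, d)
      agent <- update_risk(agent, state, action, xi)
    }
    agent <- update_value(agent, state, action, d)
  }
  agent
}

#' Tabulate agent value and risk estimates
#'
#' @param x An [abstract_agent()].
#' @param ... Unused.
#' @return A data frame with columns `state`, `action`, `Q`, `h`, suitable
#'   for writing to CSV.
#' @export
as.data.frame.abstract_agent <- function(x, ...) {
  grid <- expand.grid(state = seq_len(x$n_states),
                      action = seq_len(x$n_actions))
  data.frame(grid, Q = x$Q[as.matrix(grid)], h = x$h[as.matrix(grid)])
}

#' @export
print.abstract_agent <- function(x, ...) {
  cat(sprintf(paste0("<abstract_agent %d states x %d actions; gamma=%g ",
                     "eta_q=%g eta_h=%g alpha=%g beta=%g>\n"),
              x$n_states, x$n_actions, x$gamma, x$eta_q, x$eta_h,
              x$alpha, x$beta))
  invisible(x)
}
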