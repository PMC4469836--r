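#' Network decision-making agent
#'
#' Bundles everything one simulated subject needs: the three MSN weight
#' pools, the striatal-plasticity and GPi gain sets, serotonin multipliers,
#' the dopamine/PD condition and the selection-network parameters.  The
#' per-trial causal order is fixed: (1) observe the state, (2) select an
#' action through the STN-GPe-GPi-thalamus dynamics gated by
#' \eqn{\delta_U}, (3) observe the reward, (4) compute the dopamine signal
#' \eqn{\delta = r - y_{D1}} and apply any PD clamp, (5) update all three
#' weight pools, (6) store the selected action's utility (computed before
#' the update) for the next trial's \eqn{\delta_U}.
#'
#' Weight tables are initialized uniformly in `[0, 1]` from R's current
#' RNG, so seed the per-agent stream before construction.
#'
#' @param n_states,n_actions State and action space sizes.
#' @param gains_str Striatal-plasticity [gain_set()].
#' @param gains_gpi GPi gating [gain_set()] (default `table3`, shared by
#'   all published experiments).
#' @param serotonin A [serotonin_params()].
#' @param eta Named learning rates `c(d1 = , d2 = , d1d2 = )`.
#' @param pd A [pd_condition()].
#' @param net A [network_params()].
#' @param sign_term Keep the `sign(Q)` non-linearity in the utility and in
#'   the indirect-pathway risk term?
#' @param complementary Use the complementary 2 x 2 `w_d1` coupling (the
#'   reversal-learning task design)?
#' @param du_scope How the utility gradient \eqn{\delta_U} is formed.
#'   `"action"` (default): the temporal gradient of the executed action's
#'   utility -- on each visit to a state, the utility (under current
#'   weights) of the action executed at that state's previous visit minus
#'   its stored utility at that time; the gradient is then dominated by
#'   the outcome-driven weight update of the last visit, so rising utility
#'   (reward, falling risk) engages the direct "Go" pathway and falling
#'   utility the indirect "NoGo" pathway.  `"state"`: compares the
#'   current greedy utility of the state with the stored utility of the
#'   previously executed action there.  `"global"`: as `"state"` but
#'   across consecutive trials regardless of state, so \eqn{\delta_U}
#'   also carries utility jumps between states.
#' @param zero_outcome_update Treat `reward = 0` outcomes as feedback
#'   (`TRUE`, default: a zero-point outcome still generates a prediction
#'   error and a weight update) or as non-events (`FALSE`: no plasticity
#'   and no stored utility change on zero-outcome trials).
#' @return An object of class `bg_agent`.
#' @export
bg_agent <- function(n_states, n_actions, gains_str,
                     gains_gpi = gain_preset("table3"),
                     serotonin = serotonin_params(),
                     eta = c(d1 = 0.1, d2 = 0.1, d1d2 = 0.1),
                     pd = pd_condition("control"),
                     net = network_params(),
                     sign_term = TRUE, complementary = FALSE,
                     du_scope = c("state", "action", "trial", "global"),
                     zero_outcome_update = TRUE) {
  du_scope <- match.arg(du_scope)
  stopifnot(inherits(gains_str, "gain_set"), inherits(gains_gpi, "gain_set"),
            inherits(serotonin, "serotonin_params"),
            inherits(pd, "pd_condition"), inherits(net, "network_params"))
  structure(list(
    weights = msn_weights(n_states, n_actions, eta,
                          complementary = complementary),
    gains_str = gains_str, gains_gpi = gains_gpi,
    serotonin = serotonin, pd = pd, net = net,
    sign_term = isTRUE(sign_term), du_scope = du_scope,
    zero_outcome_update = isTRUE(zero_outcome_update),
    n_states = as.integer(n_states), n_actions = as.integer(n_actions),
    u_prev = rep(NA_real_, if (du_scope %in% c("global", "trial")) 1L else
      n_states),
    a_prev = rep(NA_integer_, n_states),
    du_next = 0, dyn_state = NULL
  ), class = "bg_agent")
}

#' Run one trial of a network agent
#'
#' Executes the full per-trial cycle documented in [bg_agent()] and
#' returns both the updated agent and a per-trial record.
#'
#' @param agent A [bg_agent()].
#' @param state Observed state index.
#' @param reward_fn Function `action -> reward` implementing the
#'   environment's outcome for this trial.
#' @param actions Available action indices (default: all).
#' @return List with `agent` (updated) and `record`, a list with elements
#'   `state`, `action`, `reward`, `delta_raw` (unclamped), `delta` (after
#'   any PD clamp) and `delta_u`.
#' @export
agent_trial <- function(agent, state, reward_fn,
                        actions = seq_len(agent$n_actions)) {
  # greedy utility of the current state under current weights
  key <- if (agent$du_scope %in% c("global", "trial")) 1L else state
  u_prev <- agent$u_prev[[key]]
  du <- if (agent$du_scope == "trial") {
    # global broadcast: the utility change produced by the last trial
    agent$du_next
  } else if (agent$du_scope == "action") {
    # utility, under current weights, of the action executed at this
    # state's previous visit, against its stored utility at that time
    a_prev <- agent$a_prev[[state]]
    if (is.na(a_prev) || is.na(u_prev)) 0 else
      delta_u(network_utility(agent$weights, agent$serotonin$alpha_d1d2,
                              state, a_prev, sign_term = agent$sign_term),
              u_prev)
  } else {
    u_now <- max(vapply(actions, function(a) {
      network_utility(agent$weights, agent$serotonin$alpha_d1d2, state, a,
                      sign_term = agent$sign_term)
    }, numeric(1)))
    if (is.na(u_prev)) 0 else delta_u(u_now, u_prev)
  }

  sel <- thalamus_select(agent$weights, agent$gains_gpi, agent$serotonin,
                         du, state, agent$net, actions,
                         sign_term = agent$sign_term,
                         dyn_state = if (agent$net$persist_state)
                           agent$dyn_state else NULL)
  a <- sel$action
  if (agent$net$persist_state) agent$dyn_state <- sel$state

  r <- reward_fn(a)
  d_raw <- compute_delta(agent$weights, state, a, r)
  d <- apply_pd(d_raw, agent$pd)

  # utility of the executed action at selection time (pre-update weights)
  u_sel <- network_utility(agent$weights, agent$serotonin$alpha_d1d2,
                           state, a, sign_term = agent$sign_term)
  learn <- agent$zero_outcome_update || r != 0
  if (learn) {
    agent$weights <- update_weights(agent$weights, agent$gains_str,
                                    state, a, d)
  }
  agent$u_prev[[key]] <- u_sel
  agent$a_prev[[state]] <- a
  if (agent$du_scope == "trial") {
    u_post <- network_utility(agent$weights, agent$serotonin$alpha_d1d2,
                              state, a, sign_term = agent$sign_term)
    agent$du_next <- delta_u(u_post, u_sel)
  }

  list(agent = agent,
       record = list(state = state, action = a, reward = r,
                     delta_raw = d_raw, delta = d, delta_u = du))
}

#' @export
print.bg_agent <- function(x, ...) {
  cat(sprintf(paste0("<bg_agent %d states x %d actions; %s; ",
                     "alpha = [%g, %g, %g]%s>\n"),
              x$n_states, x$n_actions, x$pd$status,
              x$serotonin$alpha_d1, x$serotonin$alpha_d2,
              x$serotonin$alpha_d1d2,
              if (x$sign_term) "" else "; sign term ablated"))
  invisible(x)
}

#' Derive per-agent seeds from a master seed
#'
#' Fixed two-level seed hierarchy used by every experiment harness: the
#' master seed seeds R's RNG once, from which `n` independent per-agent
#' seeds are drawn; each agent then runs its whole trial sequence
#' (weight initialization, environment outcomes, network initial
#' conditions, tie breaks) on its own seeded stream.  Re-using the same
#' master seed therefore reproduces every summary bit-exactly, and
#' evaluating different parameter settings under one master seed shares
#' the per-agent random numbers (common random numbers).
#'
#' @param master_seed Integer master seed.
#' @param n Number of agents.
#' @return Integer vector of `n` per-agent seeds.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- globalenv()$.Random.seed
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  seeds
}

# mean and standard error over agents
mean_se <- function(x) {
  n <- sum(is.finite(x))
  m <- mean(x, na.rm = TRUE)
  se <- stats::sd(x, na.rm = TRUE) / sqrt(n)
  c(mean = m, se = se, n = n)
}
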