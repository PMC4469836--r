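#' Serotonin conditions for the reversal-learning experiment
#'
#' Balanced serotonin uses \eqn{[\alpha_{D1}, \alpha_{D2}, \alpha_{D1D2}]
#' = [1, 5, 1]}; tryptophan depletion lowers the D2R multiplier to
#' `2.25`.
#'
#' @return Named list of [serotonin_params()].
#' @export
reversal_conditions <- function() {
  list(balanced = serotonin_params(1, 5, 1),
       depleted = serotonin_params(1, 2.25, 1))
}

#' Run one reversal-learning block
#'
#' One experimental block of the deterministic reward/punishment
#' prediction task.  Two stimuli are the states; the two actions predict
#' a rewarding (`a = 1`) or punishing (`a = 2`) outcome.  The outcome is
#' stimulus-dependent: the currently rewarding stimulus always yields
#' `r = +1`, the other `r = -1`.  A trial is an error when the predicted
#' category mismatches the realized outcome; erroneous trials repeat the
#' same stimulus.  The block starts with an acquisition stage; each stage
#' ends once the cumulative number of correct responses since stage start
#' reaches a criterion drawn uniformly from 5..9, whereupon the
#' stimulus-outcome map reverses (at most `max_reversals` reversal
#' stages).  Under the `"unexpected_reward"` condition the first trial of
#' a reversal stage presents the newly rewarding (previously punishing)
#' stimulus; under `"unexpected_punishment"` the newly punishing one.
#' The block always runs exactly `block_trials` trials; if the reversal
#' budget is exhausted the final contingency simply continues.
#'
#' @param agent A [bg_agent()] built with `complementary = TRUE` (2 x 2).
#' @param condition `"unexpected_reward"` or `"unexpected_punishment"`.
#' @param block_trials Trials per block (default 120).
#' @param max_reversals Maximum reversal stages (default 16).
#' @param criterion_range Range of the correct-response criterion
#'   (default `5:9`); `criterion_mode = "cumulative"` counts all correct
#'   responses in the stage, `"consecutive"` only unbroken runs.
#' @param criterion_mode See above.
#' @param select_override Optional policy `function(state, rewarding)`
#'   returning an action, bypassing the network (diagnostic, e.g. an
#'   always-correct oracle).
#' @return List with `agent` and `trials`, a data frame with one row per
#'   trial (`trial`, `stage` (0 = acquisition), `state`, `action`,
#'   `outcome`, `error`, `switch_trial`).
#' @export
run_reversal_block <- function(agent, condition = c("unexpected_reward",
                                                    "unexpected_punishment"),
                               block_trials = 120L, max_reversals = 16L,
                               criterion_range = 5:9,
                               criterion_mode = c("cumulative",
                                                  "consecutive"),
                               select_override = NULL) {
  condition <- match.arg(condition)
  criterion_mode <- match.arg(criterion_mode)
  rewarding <- sample(1:2, 1L)      # which stimulus currently yields +1
  stage <- 0L                       # 0 = acquisition
  criterion <- sample(criterion_range, 1L)
  n_correct <- 0L
  pending <- NULL                   # stimulus forced on the next trial
  col_stage <- integer(block_trials); col_state <- integer(block_trials)
  col_action <- integer(block_trials); col_outcome <- numeric(block_trials)
  col_error <- logical(block_trials); col_switch <- logical(block_trials)
  stage_start <- 1L

  for (t in seq_len(block_trials)) {
    s <- if (!is.null(pending)) pending else sample(1:2, 1L)
    pending <- NULL
    r <- if (s == rewarding) 1 else -1
    if (is.null(select_override)) {
      res <- agent_trial(agent, s, function(a) r)
      agent <- res$agent
      a <- res$record$action
    } else {
      a <- select_override(s, rewarding)
      # learning still proceeds through the standard update path
      d <- apply_pd(compute_delta(agent$weights, s, a, r), agent$pd)
      agent$weights <- update_weights(agent$weights, agent$gains_str,
                                      s, a, d)
    }
    correct <- (a == 1L) == (r == 1)
    col_stage[t] <- stage; col_state[t] <- s; col_action[t] <- a
    col_outcome[t] <- r; col_error[t] <- !correct
    col_switch[t] <- (t == stage_start && stage > 0L)
    if (!correct) {
      pending <- s
      if (criterion_mode == "consecutive") n_correct <- 0L
    } else {
      n_correct <- n_correct + 1L
    }
    if (n_correct >= criterion && stage < max_reversals) {
      rewarding <- 3L - rewarding
      stage <- stage + 1L
      n_correct <- 0L
      criterion <- sample(criterion_range, 1L)
      stage_start <- t + 1L
      pending <- if (condition == "unexpected_reward") rewarding else
        3L - rewarding
    }
  }
  list(agent = agent,
       trials = data.frame(trial = seq_len(block_trials), stage = col_stage,
                           state = col_state, action = col_action,
                           outcome = col_outcome, error = col_error,
                           switch_trial = col_switch))
}

#' Run the reversal-learning experiment
#'
#' Simulates a population of agents on the deterministic
#' reward/punishment prediction task with reversals.  Each agent performs
#' four blocks of `block_trials` trials, two per condition (unexpected
#' reward, unexpected punishment) in randomized order, with fresh weights
#' per block; the D1R weights carry the complementary 2 x 2 coupling of
#' the task design.  The headline statistic is the mean number of errors
#' on non-switch trials (reversal stages only, excluding both acquisition
#' and the first trial after each reversal), split (a) by realized
#' outcome type (reward vs punishment trials) and (b) by block condition,
#' per serotonin condition.
#'
#' @inheritParams run_risk_experiment
#' @param conditions Named list of [serotonin_params()] (default
#'   [reversal_conditions()]).
#' @param gains_str Striatal gain set (default `table6`).
#' @param eta Learning rates (default 0.01 for all pools).
#' @param block_trials,max_reversals,criterion_range,criterion_mode See
#'   [run_reversal_block()].
#' @return A `bg_experiment` object; summary statistics are
#'   `errors_total`, `errors_reward`, `errors_punishment`,
#'   `errors_unexpected_reward`, `errors_unexpected_punishment` (mean
#'   error counts per agent).
#' @export
run_reversal_experiment <- function(conditions = reversal_conditions(),
                                    n_agents = 100L, master_seed = 1L,
                                    gains_str = gain_preset("table6"),
                                    gains_gpi = gain_preset("table3"),
                                    eta = c(d1 = 0.01, d2 = 0.01,
                                            d1d2 = 0.01),
                                    net = network_params(),
                                    sign_term = TRUE, du_scope = "state",
                                    block_trials = 120L,
                                    max_reversals = 16L,
                                    criterion_range = 5:9,
                                    criterion_mode = "cumulative",
                                    keep_trials = FALSE) {
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)))
  seeds <- derive_seeds(master_seed, n_agents)
  block_conditions <- c("unexpected_reward", "unexpected_punishment")

  per_agent <- list()
  trials <- list()
  for (cond in names(conditions)) {
    sero <- conditions[[cond]]
    stopifnot(inherits(sero, "serotonin_params"))
    stats_agent <- vector("list", n_agents)
    for (i in seq_len(n_agents)) {
      set.seed(seeds[[i]])
      block_order <- sample(rep(block_conditions, 2L))
      logs <- lapply(seq_along(block_order), function(b) {
        ag <- bg_agent(2L, 2L, gains_str, gains_gpi, sero, eta,
                       net = net, sign_term = sign_term,
                       complementary = TRUE, du_scope = du_scope)
        res <- run_reversal_block(ag, block_order[[b]], block_trials,
                                  max_reversals, criterion_range,
                                  criterion_mode)
        cbind(block = b, block_condition = block_order[[b]], res$trials)
      })
      log <- do.call(rbind, logs)
      scored <- log[log$stage > 0L & !log$switch_trial, ]
      err <- scored$error
      stats_agent[[i]] <- data.frame(
        condition = cond, agent = i,
        errors_total = sum(err),
        errors_reward = sum(err[scored$outcome == 1]),
        errors_punishment = sum(err[scored$outcome == -1]),
        errors_unexpected_reward =
          sum(err[scored$block_condition == "unexpected_reward"]),
        errors_unexpected_punishment =
          sum(err[scored$block_condition == "unexpected_punishment"]))
      if (keep_trials) {
        trials[[length(trials) + 1L]] <-
          cbind(condition = cond, agent = i, log)
      }
    }
    per_agent[[cond]] <- do.call(rbind, stats_agent)
  }
  per_agent <- do.call(rbind, per_agent)
  rownames(per_agent) <- NULL

  stats <- c("errors_total", "errors_reward", "errors_punishment",
             "errors_unexpected_reward", "errors_unexpected_punishment")
  summary <- do.call(rbind, lapply(names(conditions), function(cond) {
    sub <- per_agent[per_agent$condition == cond, ]
    do.call(rbind, lapply(stats, function(st) {
      ms <- mean_se(sub[[st]])
      data.frame(condition = cond, statistic = st,
                 mean = ms[["mean"]], se = ms[["se"]], n = ms[["n"]])
    }))
  }))
  rownames(summary) <- NULL
  out <- list(summary = summary, per_agent = per_agent,
              experiment = "reversal", master_seed = master_seed)
  if (keep_trials) out$trials <- do.call(rbind, trials)
  structure(out, class = "bg_experiment")
}
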