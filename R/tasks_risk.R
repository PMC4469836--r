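#' Safe/risky juice-reward schedule
#'
#' The six-state reward schedule of the primate risk-sensitivity task.
#' Each state offers a safe target (a deterministic juice amount, in ms of
#' valve opening) and a risky target delivering one of two amounts with
#' probability 0.5 each.  States 1-3 are equal-expected-value (EEV) pairs:
#' the risky mean equals the safe amount, so the options differ only in
#' variance.  States 4-6 form the unequal-expected-value (UEV) group of
#' the published schedule, in which the safe amount is varied against a
#' fixed wide-variance risky target.
#'
#' @param file CSV file with columns `state`, `safe`, `risky1`, `risky2`,
#'   `group`; defaults to the packaged schedule.
#' @param reward_base Reward base \eqn{r^b} (ms) subtracted from every
#'   juice amount to give the subjective reward \eqn{r = r^j - r^b};
#'   amounts below the base act as losses, above it as gains.  Default
#'   `159.83`.
#' @return A data frame of class `risk_schedule` with attribute
#'   `reward_base`.
#' @export
risk_schedule <- function(file = system.file("extdata", "risk_schedule.csv",
                                             package = "bgutility"),
                          reward_base = 159.83) {
  sched <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("state", "safe", "risky1", "risky2", "group")
  if (!all(need %in% names(sched))) {
    stop("schedule must have columns ", paste(need, collapse = ", "))
  }
  if (!all(sched$group %in% c("eev", "uev"))) {
    stop("schedule group must be 'eev' or 'uev'")
  }
  eev <- sched$group == "eev"
  if (any(abs((sched$risky1[eev] + sched$risky2[eev]) / 2 -
              sched$safe[eev]) > 1e-9)) {
    stop("EEV states must have mean(risky) equal to the safe amount")
  }
  structure(sched, class = c("risk_schedule", "data.frame"),
            reward_base = reward_base)
}

#' Sample a subjective reward from the risk schedule
#'
#' The safe choice returns its fixed amount; the risky choice returns one
#' of its two amounts with probability 0.5 each.  The reward base is
#' subtracted, so the returned value is the subjective reward the agent
#' learns from.
#'
#' @param schedule A [risk_schedule()].
#' @param state State index (schedule row).
#' @param choice `"safe"` or `"risky"`.
#' @param n Number of draws.
#' @return Numeric vector of `n` subjective rewards.
#' @export
#' @examples
#' sch <- risk_schedule()
#' sample_risk_outcome(sch, 1, "safe")    # 150 - 159.83 = -9.83
sample_risk_outcome <- function(schedule, state, choice = c("safe", "risky"),
                                n = 1L) {
  choice <- match.arg(choice)
  stopifnot(inherits(schedule, "risk_schedule"),
            state >= 1L, state <= nrow(schedule))
  rb <- attr(schedule, "reward_base")
  rj <- if (choice == "safe") {
    rep(schedule$safe[[state]], n)
  } else {
    ifelse(stats::runif(n) < 0.5, schedule$risky1[[state]],
           schedule$risky2[[state]])
  }
  rj - rb
}

#' Serotonin conditions for the risk-sensitivity experiment
#'
#' Baseline (balanced serotonin) uses \eqn{[\alpha_{D1}, \alpha_{D2},
#' \alpha_{D1D2}] = [1, 1, 1.32]}; rapid tryptophan depletion (RTD)
#' lowers the co-expressing-pool multiplier to `0.0012`.
#'
#' @return Named list of [serotonin_params()].
#' @export
risk_conditions <- function() {
  list(baseline = serotonin_params(1, 1, 1.32),
       rtd = serotonin_params(1, 1, 0.0012))
}

#' Run the risk-sensitivity experiment
#'
#' Simulates a population of network agents on the safe/risky choice task.
#' Each agent sees every schedule state `trials_per_state` times in
#' randomly interleaved order, choosing between the safe (channel 1) and
#' risky (channel 2) target through the selection network.  The headline
#' statistic is the proportion of safe choices, reported overall and split
#' by the EEV and UEV state groups, per serotonin condition, as mean and
#' standard error over agents.  Agents in different conditions share
#' per-agent seeds (common random numbers).
#'
#' @param conditions Named list of [serotonin_params()] (default
#'   [risk_conditions()]).
#' @param n_agents Number of simulated agents per condition (default 100).
#' @param trials_per_state Trials per schedule state per agent (default
#'   50; enough for weight convergence at the published learning rates).
#' @param master_seed Master seed for the two-level seed hierarchy.
#' @param schedule A [risk_schedule()].
#' @param gains_str Striatal gain set (default `table5`).
#' @param gains_gpi GPi gain set (default `table3`).
#' @param eta Learning rates (default `c(d1 = 0.3, d2 = 0.1, d1d2 = 0.1)`).
#' @param net A [network_params()].
#' @param sign_term Keep the `sign(Q)` non-linearity?
#' @param du_scope Utility-gradient convention passed to [bg_agent()]
#'   (default `"state"`).
#' @param keep_trials Also return the per-trial log.
#' @return An object of class `bg_experiment`: list with `summary` (data
#'   frame with columns `condition`, `statistic`, `mean`, `se`, `n`),
#'   `per_agent`, and optionally `trials`.
#' @export
run_risk_experiment <- function(conditions = risk_conditions(),
                                n_agents = 100L, trials_per_state = 50L,
                                master_seed = 1L,
                                schedule = risk_schedule(),
                                gains_str = gain_preset("table5"),
                                gains_gpi = gain_preset("table3"),
                                eta = c(d1 = 0.3, d2 = 0.1, d1d2 = 0.1),
                                net = network_params(),
                                sign_term = TRUE, du_scope = "state",
                                keep_trials = FALSE) {
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)))
  n_states <- nrow(schedule)
  seeds <- derive_seeds(master_seed, n_agents)
  eev_states <- schedule$state[schedule$group == "eev"]
  uev_states <- schedule$state[schedule$group == "uev"]

  per_agent <- list()
  trials <- list()
  for (cond in names(conditions)) {
    sero <- conditions[[cond]]
    stopifnot(inherits(sero, "serotonin_params"))
    stats_agent <- vector("list", n_agents)
    for (i in seq_len(n_agents)) {
      set.seed(seeds[[i]])
      ag <- bg_agent(n_states, 2L, gains_str, gains_gpi, sero, eta,
                     net = net, sign_term = sign_term,
                     du_scope = du_scope)
      seq_states <- sample(rep(seq_len(n_states), trials_per_state))
      st <- integer(length(seq_states)); ac <- integer(length(seq_states))
      for (t in seq_along(seq_states)) {
        s <- seq_states[[t]]
        res <- agent_trial(ag, s, function(a) {
          sample_risk_outcome(schedule, s,
                              if (a == 1L) "safe" else "risky")
        })
        ag <- res$agent
        st[[t]] <- s; ac[[t]] <- res$record$action
      }
      safe <- ac == 1L
      stats_agent[[i]] <- data.frame(
        condition = cond, agent = i,
        safe_overall = mean(safe),
        safe_eev = mean(safe[st %in% eev_states]),
        safe_uev = mean(safe[st %in% uev_states]),
        safe_gain = mean(safe[schedule$safe[st] >
                                attr(schedule, "reward_base")]),
        safe_loss = mean(safe[schedule$safe[st] <
                                attr(schedule, "reward_base")]))
      if (keep_trials) {
        trials[[length(trials) + 1L]] <- data.frame(
          condition = cond, agent = i, trial = seq_along(st),
          state = st, action = ac)
      }
    }
    per_agent[[cond]] <- do.call(rbind, stats_agent)
  }
  per_agent <- do.call(rbind, per_agent)
  rownames(per_agent) <- NULL

  stats <- c("safe_overall", "safe_eev", "safe_uev", "safe_gain",
             "safe_loss")
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
              experiment = "risk", master_seed = master_seed)
  if (keep_trials) out$trials <- do.call(rbind, trials)
  structure(out, class = "bg_experiment")
}

#' @export
print.bg_experiment <- function(x, digits = 3, ...) {
  cat(sprintf("<bg_experiment '%s'; master seed %s>\n", x$experiment,
              format(x$master_seed)))
  df <- x$summary
  df$mean <- signif(df$mean, digits)
  df$se <- signif(df$se, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
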