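#' Probabilistic reward-punishment classification task
#'
#' The four-image classification task used to assess reward versus
#' punishment learning in Parkinson's disease.  Each trial presents one of
#' four images; the agent responds A or B.  Images I1, I2 are reward
#' images: the optimal response yields +25 points (coded `r = +1`) with
#' probability 0.8 and 0 points otherwise, the non-optimal response with
#' probability 0.2.  Images I3, I4 are punishment images: the optimal
#' response avoids the -25-point outcome (coded `r = -1`), receiving it
#' with probability only 0.2 against 0.8 for the non-optimal response.
#' Zero-point outcomes are coded `r = 0`.
#'
#' @param file CSV with columns `state`, `image`, `optimal_action`,
#'   `valence`, `points`, `p_points_optimal`, `p_points_nonoptimal`;
#'   defaults to the packaged table.
#' @return A data frame of class `classification_task`.
#' @export
classification_task <- function(file = system.file(
    "extdata", "classification_task.csv", package = "bgutility")) {
  task <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("state", "image", "optimal_action", "valence", "points",
            "p_points_optimal", "p_points_nonoptimal")
  if (!all(need %in% names(task))) {
    stop("task table must have columns ", paste(need, collapse = ", "))
  }
  stopifnot(all(task$valence %in% c("reward", "punishment")),
            all(task$points[task$valence == "reward"] > 0),
            all(task$points[task$valence == "punishment"] < 0))
  structure(task, class = c("classification_task", "data.frame"))
}

#' Sample a coded outcome from the classification task
#'
#' Returns the reinforcement-coded outcome: `+1` when a reward image pays
#' out, `-1` when a punishment image penalizes, `0` otherwise.  Reward
#' images never yield negative outcomes and punishment images never yield
#' positive ones.
#'
#' @param task A [classification_task()].
#' @param state Image index (task row).
#' @param action Chosen response (1 = A, 2 = B).
#' @param n Number of draws.
#' @return Numeric vector of coded outcomes in `{-1, 0, +1}`.
#' @export
sample_classification_outcome <- function(task, state, action, n = 1L) {
  stopifnot(inherits(task, "classification_task"),
            state >= 1L, state <= nrow(task), action %in% c(1L, 2L))
  row <- task[state, ]
  p <- if (action == row$optimal_action) row$p_points_optimal else
    row$p_points_nonoptimal
  hit <- stats::runif(n) < p
  sign(row$points) * as.numeric(hit)
}

#' Condition presets for the PD classification experiment
#'
#' @return Named list of [pd_preset()] results (`control`, `pd_off`,
#'   `pd_on`).
#' @export
pd_conditions <- function() {
  list(control = pd_preset("controls"),
       pd_off = pd_preset("pd_off"),
       pd_on = pd_preset("pd_on"))
}

#' Run the PD reward-punishment classification experiment
#'
#' Simulates a population of agents on the four-image probabilistic
#' classification task (160 trials in 4 blocks of 40; each image appears
#' 10 times per block in shuffled order).  The headline statistics are
#' the reward optimality (fraction of optimal responses on reward-image
#' trials) and punishment optimality (fraction on punishment-image
#' trials), per condition, as mean and standard error over agents.
#'
#' @inheritParams run_risk_experiment
#' @param conditions Named list of lists with elements `serotonin`
#'   ([serotonin_params()]) and `pd` ([pd_condition()]); default
#'   [pd_conditions()].
#' @param task A [classification_task()].
#' @param gains_str Striatal gain set (default `table8`).
#' @param eta Learning rates (default `c(d1 = 0.01, d2 = 0.1,
#'   d1d2 = 0.1)`).
#' @param zero_outcome_update Passed to [bg_agent()]: treat zero-point
#'   outcomes as feedback (default) or as non-events.
#' @param n_blocks,trials_per_image_block Task size (defaults 4 and 10,
#'   i.e. 160 trials).
#' @return A `bg_experiment` object; summary statistics are
#'   `reward_optimality` and `punishment_optimality`.
#' @export
run_pd_experiment <- function(conditions = pd_conditions(),
                              n_agents = 100L, master_seed = 1L,
                              task = classification_task(),
                              gains_str = gain_preset("table8"),
                              gains_gpi = gain_preset("table3"),
                              eta = c(d1 = 0.01, d2 = 0.1, d1d2 = 0.1),
                              net = network_params(),
                              sign_term = TRUE, du_scope = "state",
                              zero_outcome_update = TRUE,
                              n_blocks = 4L, trials_per_image_block = 10L,
                              keep_trials = FALSE) {
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)))
  n_states <- nrow(task)
  seeds <- derive_seeds(master_seed, n_agents)
  reward_states <- task$state[task$valence == "reward"]
  punish_states <- task$state[task$valence == "punishment"]

  per_agent <- list()
  trials <- list()
  for (cond in names(conditions)) {
    preset <- conditions[[cond]]
    stopifnot(inherits(preset$serotonin, "serotonin_params"),
              inherits(preset$pd, "pd_condition"))
    stats_agent <- vector("list", n_agents)
    for (i in seq_len(n_agents)) {
      set.seed(seeds[[i]])
      ag <- bg_agent(n_states, 2L, gains_str, gains_gpi,
                     preset$serotonin, eta, pd = preset$pd,
                     net = net, sign_term = sign_term, du_scope = du_scope,
                     zero_outcome_update = zero_outcome_update)
      seq_states <- unlist(lapply(seq_len(n_blocks), function(b) {
        sample(rep(seq_len(n_states), trials_per_image_block))
      }))
      st <- integer(length(seq_states)); ac <- integer(length(seq_states))
      for (t in seq_along(seq_states)) {
        s <- seq_states[[t]]
        res <- agent_trial(ag, s, function(a) {
          sample_classification_outcome(task, s, a)
        })
        ag <- res$agent
        st[[t]] <- s; ac[[t]] <- res$record$action
      }
      optimal <- ac == task$optimal_action[st]
      stats_agent[[i]] <- data.frame(
        condition = cond, agent = i,
        reward_optimality = mean(optimal[st %in% reward_states]),
        punishment_optimality = mean(optimal[st %in% punish_states]))
      if (keep_trials) {
        trials[[length(trials) + 1L]] <- data.frame(
          condition = cond, agent = i, trial = seq_along(st),
          state = st, action = ac, optimal = optimal)
      }
    }
    per_agent[[cond]] <- do.call(rbind, stats_agent)
  }
  per_agent <- do.call(rbind, per_agent)
  rownames(per_agent) <- NULL

  stats <- c("reward_optimality", "punishment_optimality")
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
              experiment = "pd_classification", master_seed = master_seed)
  if (keep_trials) out$trials <- do.call(rbind, trials)
  structure(out, class = "bg_experiment")
}
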