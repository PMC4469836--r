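#' Weighted sum-of-squares objective for summary statistics
#'
#' \eqn{\sum_k w_k (\mathrm{sim}_k - \mathrm{target}_k)^2} over the named
#' target statistics.  Zero iff every targeted statistic is matched
#' exactly; invariant to the ordering of the target table.
#'
#' @param stats Named numeric vector of simulated statistics.
#' @param targets Named numeric vector of target values.
#' @param weights Optional named weights (default: all 1).
#' @return Non-negative scalar.
#' @export
stat_objective <- function(stats, targets, weights = NULL) {
  stopifnot(!is.null(names(targets)), all(names(targets) %in% names(stats)))
  if (is.null(weights)) weights <- rep(1, length(targets))
  if (!is.null(names(weights))) weights <- weights[names(targets)]
  sum(weights * (stats[names(targets)] - targets)^2)
}

#' Build an experiment evaluator for parameter search
#'
#' Returns a function `f(par, master_seed)` that runs one experiment at a
#' given parameter vector and returns its condition-free summary
#' statistics as a named numeric vector.  Recognized parameter names are
#' `alpha_d1`, `alpha_d2`, `alpha_d1d2` (serotonin multipliers),
#' `delta_lim`, `delta_med` (PD clamp, `pd` experiment only) and
#' `reward_base` (`risk` experiment only); unrecognized names are an
#' error.  Because the harnesses derive all randomness from
#' `master_seed`, evaluations at different parameter vectors under one
#' master seed share per-agent random numbers (common random numbers),
#' and re-evaluating the same vector reproduces the statistics exactly.
#'
#' @param experiment `"risk"`, `"reversal"` or `"pd"`.
#' @param n_agents Agents per evaluation.
#' @param ... Further fixed arguments passed to the harness (e.g.
#'   `trials_per_state`, `gains_str`).
#' @return Function `(par, master_seed) -> named numeric vector`.
#' @export
experiment_evaluator <- function(experiment = c("risk", "reversal", "pd"),
                                 n_agents = 25L, ...) {
  experiment <- match.arg(experiment)
  fixed <- list(...)
  alpha_names <- c("alpha_d1", "alpha_d2", "alpha_d1d2")
  base_alpha <- switch(experiment,
    risk = c(alpha_d1 = 1, alpha_d2 = 1, alpha_d1d2 = 1.32),
    reversal = c(alpha_d1 = 1, alpha_d2 = 5, alpha_d1d2 = 1),
    pd = c(alpha_d1 = 1, alpha_d2 = 1, alpha_d1d2 = 0.2))

  function(par, master_seed) {
    stopifnot(!is.null(names(par)))
    known <- c(alpha_names,
               if (experiment == "pd") c("delta_lim", "delta_med"),
               if (experiment == "risk") "reward_base")
    bad <- setdiff(names(par), known)
    if (length(bad)) {
      stop("unknown search parameter(s): ", paste(bad, collapse = ", "))
    }
    alpha <- base_alpha
    alpha[intersect(names(par), alpha_names)] <-
      par[intersect(names(par), alpha_names)]
    sero <- serotonin_params(alpha[["alpha_d1"]], alpha[["alpha_d2"]],
                             alpha[["alpha_d1d2"]])
    if (experiment == "risk") {
      sched_args <- list()
      if ("reward_base" %in% names(par)) {
        sched_args$reward_base <- par[["reward_base"]]
      }
      args <- c(list(conditions = list(fit = sero), n_agents = n_agents,
                     master_seed = master_seed,
                     schedule = do.call(risk_schedule, sched_args)),
                fixed)
      res <- do.call(run_risk_experiment, args)
    } else if (experiment == "reversal") {
      args <- c(list(conditions = list(fit = sero), n_agents = n_agents,
                     master_seed = master_seed), fixed)
      res <- do.call(run_reversal_experiment, args)
    } else {
      pd <- if (any(c("delta_lim", "delta_med") %in% names(par))) {
        pd_condition(if ("delta_med" %in% names(par)) "pd_on" else "pd_off",
                     delta_lim = if ("delta_lim" %in% names(par))
                       par[["delta_lim"]] else 0.001,
                     delta_med = if ("delta_med" %in% names(par))
                       par[["delta_med"]] else 0)
      } else {
        pd_condition("control")
      }
      args <- c(list(conditions = list(fit = list(serotonin = sero,
                                                  pd = pd)),
                     n_agents = n_agents, master_seed = master_seed),
                fixed)
      res <- do.call(run_pd_experiment, args)
    }
    stats::setNames(res$summary$mean, res$summary$statistic)
  }
}

#' Parameter sweep with common random numbers
#'
#' Evaluates an experiment at every row of a parameter grid, re-using the
#' same master seed (hence the same per-agent seeds) at every point so
#' that differences between rows reflect the parameters, not sampling
#' noise.
#'
#' @param evaluator Function `(par, master_seed) -> named numeric vector`,
#'   e.g. from [experiment_evaluator()].
#' @param grid Data frame; one column per parameter, one row per point.
#' @param master_seed Shared master seed.
#' @param targets,weights Optional target statistics; when supplied an
#'   `objective` column ([stat_objective()]) is appended.
#' @return Data frame: the grid columns, one column per returned
#'   statistic, and optionally `objective`.
#' @export
sweep_experiment <- function(evaluator, grid, master_seed,
                             targets = NULL, weights = NULL) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    par <- unlist(grid[i, , drop = FALSE])
    stats <- evaluator(par, master_seed)
    out <- cbind(grid[i, , drop = FALSE],
                 as.data.frame(as.list(stats)))
    if (!is.null(targets)) {
      out$objective <- stat_objective(stats, targets, weights)
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Real-coded genetic-algorithm minimizer
#'
#' A small GA used for parameter calibration: tournament selection (size
#' 3), uniform blend crossover, Gaussian mutation (sd = a tenth of each
#' bound width, clamped to bounds) and elitism of one.  The best-so-far
#' objective is non-increasing across generations by construction.
#' Option defaults are desk-scale and deliberately modest.
#'
#' @param objective Function `par -> scalar` to minimize.
#' @param lower,upper Named numeric bounds (finite, equal names).
#' @param pop_size Population size (default 24).
#' @param generations Number of generations (default 40).
#' @param p_mutate Per-gene mutation probability (default 0.1).
#' @param p_cross Crossover probability (default 0.7).
#' @return List with `par` (best vector), `value` (its objective) and
#'   `trace` (best objective per generation, non-increasing).
#' @export
ga_optimize <- function(objective, lower, upper, pop_size = 24L,
                        generations = 40L, p_mutate = 0.1, p_cross = 0.7) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower),
            pop_size >= 2, generations >= 1)
  if (generations * pop_size <= 0) stop("zero search budget")
  d <- length(lower)
  nm <- names(lower)
  pop <- vapply(seq_len(d), function(j) {
    stats::runif(pop_size, lower[[j]], upper[[j]])
  }, numeric(pop_size))
  pop <- matrix(pop, pop_size, d)
  fit <- apply(pop, 1, objective)
  trace <- numeric(generations)
  tournament <- function() {
    idx <- sample.int(pop_size, 3L)
    idx[which.min(fit[idx])]
  }
  for (g in seq_len(generations)) {
    elite <- which.min(fit)
    newpop <- matrix(0, pop_size, d)
    newpop[1, ] <- pop[elite, ]
    for (k in 2:pop_size) {
      p1 <- pop[tournament(), ]
      p2 <- pop[tournament(), ]
      child <- if (stats::runif(1) < p_cross) {
        w <- stats::runif(d)
        w * p1 + (1 - w) * p2
      } else p1
      mut <- stats::runif(d) < p_mutate
      if (any(mut)) {
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, 0.1 * (upper - lower)[mut])
      }
      newpop[k, ] <- pmin(pmax(child, lower), upper)
    }
    pop <- newpop
    fit <- apply(pop, 1, objective)
    trace[g] <- min(fit, if (g > 1) trace[g - 1] else Inf)
  }
  best <- which.min(fit)
  par <- stats::setNames(pop[best, ], nm)
  list(par = par, value = fit[[best]], trace = trace)
}

#' Fit experiment parameters to target statistics
#'
#' Minimizes the weighted squared distance between simulated and target
#' summary statistics over a bounded parameter box, by exhaustive grid
#' search or by the genetic algorithm.  All simulator randomness is tied
#' to `master_seed` (common random numbers), so the objective is a
#' deterministic function of the parameters.
#'
#' @param evaluator Function `(par, master_seed) -> named statistics`.
#' @param lower,upper Named parameter bounds.
#' @param targets,weights Target statistics as in [stat_objective()].
#' @param master_seed Master seed for the simulator.
#' @param method `"grid"` or `"ga"`.
#' @param grid_points Points per dimension for `method = "grid"`
#'   (default 5).
#' @param ... Options passed to [ga_optimize()].
#' @return List with `par`, `value`, `trace` (GA) or the evaluated grid
#'   (`sweep`, grid method).
#' @export
fit_experiment <- function(evaluator, lower, upper, targets,
                           weights = NULL, master_seed = 1L,
                           method = c("ga", "grid"), grid_points = 5L,
                           ...) {
  method <- match.arg(method)
  stopifnot(!is.null(names(lower)), identical(names(lower), names(upper)))
  objective <- function(par) {
    stat_objective(evaluator(stats::setNames(par, names(lower)),
                             master_seed), targets, weights)
  }
  if (method == "grid") {
    axes <- Map(function(l, u) seq(l, u, length.out = grid_points),
                lower, upper)
    grid <- do.call(expand.grid, axes)
    res <- sweep_experiment(evaluator, grid, master_seed, targets, weights)
    best <- which.min(res$objective)
    list(par = unlist(grid[best, , drop = FALSE]),
         value = res$objective[[best]], sweep = res)
  } else {
    ga_optimize(objective, lower, upper, ...)
  }
}
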