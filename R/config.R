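#' Load a run configuration
#'
#' Run configurations are YAML files describing one experiment run:
#' which experiment, how many agents, the master seed, optional serotonin
#' / PD condition overrides, learning rates and network flags.  Preset
#' configurations for the three published experiments ship under
#' `system.file("presets", package = "bgutility")`.
#'
#' @param path Path to a YAML file.
#' @return The configuration list, validated by [validate_run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  cfg
}

config_keys <- function() {
  c("experiment", "n_agents", "master_seed", "trials_per_state",
    "n_blocks", "trials_per_image_block", "block_trials", "max_reversals",
    "criterion_mode", "sign_term", "eta", "conditions", "reward_base",
    "keep_trials", "net", "output_dir")
}

#' Validate a run configuration
#'
#' Rejects unknown keys and out-of-range values with an error naming the
#' offending key.
#'
#' @param cfg Configuration list (see [load_run_config()]).
#' @return `cfg`, invisibly, on success.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  bad <- setdiff(names(cfg), config_keys())
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$experiment) ||
      !cfg$experiment %in% c("risk", "reversal", "pd_classification")) {
    stop("config key 'experiment' must be one of ",
         "'risk', 'reversal', 'pd_classification'")
  }
  for (key in c("n_agents", "master_seed")) {
    if (!is.null(cfg[[key]]) &&
        (!is.numeric(cfg[[key]]) || cfg[[key]] < 1)) {
      stop("config key '", key, "' must be a positive number")
    }
  }
  if (!is.null(cfg$eta)) {
    bad_eta <- setdiff(names(cfg$eta), c("d1", "d2", "d1d2"))
    if (length(bad_eta)) {
      stop("unknown config key(s) under eta: ",
           paste(bad_eta, collapse = ", "))
    }
    if (any(unlist(cfg$eta) <= 0)) stop("config key 'eta': rates must be > 0")
  }
  if (!is.null(cfg$net)) {
    allowed <- names(formals(network_params))
    bad_net <- setdiff(names(cfg$net), allowed)
    if (length(bad_net)) {
      stop("unknown config key(s) under net: ",
           paste(bad_net, collapse = ", "))
    }
  }
  if (!is.null(cfg$conditions)) {
    if (is.null(names(cfg$conditions))) {
      stop("config key 'conditions' must be a named mapping")
    }
    for (nm in names(cfg$conditions)) {
      cnd <- cfg$conditions[[nm]]
      bad_c <- setdiff(names(cnd),
                       c("alpha_d1", "alpha_d2", "alpha_d1d2",
                         "status", "delta_lim", "delta_med"))
      if (length(bad_c)) {
        stop("unknown config key(s) under conditions$", nm, ": ",
             paste(bad_c, collapse = ", "))
      }
      for (a in intersect(names(cnd),
                          c("alpha_d1", "alpha_d2", "alpha_d1d2"))) {
        if (!is.numeric(cnd[[a]]) || cnd[[a]] < 0) {
          stop("config key conditions$", nm, "$", a,
               " must be a non-negative number")
        }
      }
      if (!is.null(cnd$status) &&
          !cnd$status %in% c("control", "pd_off", "pd_on")) {
        stop("config key conditions$", nm, "$status must be one of ",
             "'control', 'pd_off', 'pd_on'")
      }
    }
  }
  invisible(cfg)
}

config_conditions <- function(cfg) {
  if (is.null(cfg$conditions)) {
    return(switch(cfg$experiment,
                  risk = risk_conditions(),
                  reversal = reversal_conditions(),
                  pd_classification = pd_conditions()))
  }
  build_sero <- function(cnd) {
    serotonin_params(cnd$alpha_d1 %||% 1, cnd$alpha_d2 %||% 1,
                     cnd$alpha_d1d2 %||% 1)
  }
  if (cfg$experiment == "pd_classification") {
    lapply(cfg$conditions, function(cnd) {
      list(serotonin = build_sero(cnd),
           pd = pd_condition(cnd$status %||% "control",
                             delta_lim = cnd$delta_lim %||% 0.001,
                             delta_med = cnd$delta_med %||% 0.021))
    })
  } else {
    lapply(cfg$conditions, build_sero)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a run configuration
#'
#' Resolves the configuration against the experiment defaults, runs the
#' experiment, and (when an output directory is given) writes
#' `summary.csv`, `per_agent.csv`, optionally `trials.csv`, the fully
#' resolved configuration (`config_resolved.yaml`) and a short run log,
#' so every run directory is self-describing.
#'
#' @param cfg A configuration list or a YAML path.
#' @param output_dir Output directory; overrides `cfg$output_dir`.  With
#'   `NULL` nothing is written.
#' @return The `bg_experiment` result, invisibly when writing.
#' @export
run_from_config <- function(cfg, output_dir = NULL) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  validate_run_config(cfg)
  output_dir <- output_dir %||% cfg$output_dir

  eta_vec <- function(default) {
    if (is.null(cfg$eta)) return(default)
    out <- default
    out[names(cfg$eta)] <- unlist(cfg$eta)
    out
  }
  net <- if (is.null(cfg$net)) network_params() else
    do.call(network_params, cfg$net)
  common <- list(conditions = config_conditions(cfg),
                 n_agents = as.integer(cfg$n_agents %||% 100L),
                 master_seed = as.integer(cfg$master_seed %||% 1L),
                 net = net,
                 sign_term = cfg$sign_term %||% TRUE,
                 keep_trials = isTRUE(cfg$keep_trials))
  res <- switch(cfg$experiment,
    risk = do.call(run_risk_experiment, c(common, list(
      trials_per_state = as.integer(cfg$trials_per_state %||% 50L),
      schedule = risk_schedule(reward_base = cfg$reward_base %||% 159.83),
      eta = eta_vec(c(d1 = 0.3, d2 = 0.1, d1d2 = 0.1))))),
    reversal = do.call(run_reversal_experiment, c(common, list(
      block_trials = as.integer(cfg$block_trials %||% 120L),
      max_reversals = as.integer(cfg$max_reversals %||% 16L),
      criterion_mode = cfg$criterion_mode %||% "cumulative",
      eta = eta_vec(c(d1 = 0.01, d2 = 0.01, d1d2 = 0.01))))),
    pd_classification = do.call(run_pd_experiment, c(common, list(
      n_blocks = as.integer(cfg$n_blocks %||% 4L),
      trials_per_image_block =
        as.integer(cfg$trials_per_image_block %||% 10L),
      eta = eta_vec(c(d1 = 0.01, d2 = 0.1, d1d2 = 0.1)))))
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$summary, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(res$per_agent, file.path(output_dir, "per_agent.csv"),
                     row.names = FALSE)
    if (!is.null(res$trials)) {
      utils::write.csv(res$trials, file.path(output_dir, "trials.csv"),
                       row.names = FALSE)
    }
    resolved <- cfg
    resolved$n_agents <- common$n_agents
    resolved$master_seed <- common$master_seed
    yaml::write_yaml(resolved,
                     file.path(output_dir, "config_resolved.yaml"))
    writeLines(c(
      sprintf("experiment: %s", cfg$experiment),
      sprintf("master_seed: %d", common$master_seed),
      sprintf("n_agents: %d", common$n_agents),
      sprintf("bgutility version: %s",
              as.character(utils::packageVersion("bgutility"))),
      sprintf("R version: %s", R.version.string)),
      file.path(output_dir, "run_log.txt"))
    return(invisible(res))
  }
  res
}
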