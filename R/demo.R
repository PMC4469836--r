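#' Risk tracking by the D1R-D2R co-expressing pool
#'
#' Demonstrates that a neuron pool with a "U"-shaped dopamine gain tracks
#' outcome variance.  For each reward probability `p`, a single
#' state-action pair is trained on Bernoulli rewards (`r = 1` with
#' probability `p`, else 0): the D1R weight learns the value through its
#' increasing bipolar gain while the co-expressing weight accumulates
#' through the U-shaped gain, which only responds to large-magnitude
#' prediction errors.  Across `p`, the co-expressing response after a
#' fixed number of trials follows the shape of the analytic variance
#' \eqn{p(1-p)}: peaked at `p = 0.5` and vanishing toward `p = 0` and
#' `p = 1`.  For comparison, the abstract agent's risk estimate `h`
#' converges to \eqn{p(1-p)} itself.
#'
#' @param p_values Reward probabilities to test.
#' @param n_trials Training trials per probability (default 2000).
#' @param gains Striatal [gain_set()] (default `table1`).
#' @param eta Network learning rates (default
#'   `c(d1 = 0.1, d2 = 0.1, d1d2 = 0.005)`).
#' @param eta_q,eta_h Abstract-agent learning rates.
#' @param seed Seed for the Bernoulli streams.
#' @return Data frame with columns `p`, `variance` (analytic
#'   \eqn{p(1-p)}), `y_d1`, `y_d1d2` (network read-outs) and `h_abstract`
#'   (abstract risk estimate).
#' @export
risk_tracking_demo <- function(p_values = seq(0.1, 0.9, by = 0.1),
                               n_trials = 2000L,
                               gains = gain_preset("table1"),
                               eta = c(d1 = 0.1, d2 = 0.1, d1d2 = 0.005),
                               eta_q = 0.1, eta_h = 0.01, seed = 1L) {
  rows <- lapply(p_values, function(p) {
    set.seed(seed)
    rewards <- as.numeric(stats::runif(n_trials) < p)
    w <- msn_weights(1L, 1L, eta, init = 0)
    for (r in rewards) {
      d <- compute_delta(w, 1L, 1L, r)
      w <- update_weights(w, gains, 1L, 1L, d)
    }
    ag <- abstract_agent(1L, 1L, eta_q = eta_q, eta_h = eta_h)
    ag <- train_iid(ag, rewards)
    data.frame(p = p, variance = p * (1 - p),
               y_d1 = w$w_d1[1, 1], y_d1d2 = w$w_d1d2[1, 1],
               h_abstract = ag$h[1, 1])
  })
  do.call(rbind, rows)
}
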