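#' Serotonin modulation parameters
#'
#' Tonic serotonin level is represented by three non-negative multipliers
#' on the pathway outputs of the three MSN pools: `alpha_d1` scales the
#' D1R (direct-pathway) drive, `alpha_d2` the D2R indirect-pathway drive
#' and `alpha_d1d2` the risk (D1R-D2R co-expressing) drive.  Tryptophan
#' depletion and disease states are modelled by lowering one or more of
#' these multipliers.
#'
#' @param alpha_d1,alpha_d2,alpha_d1d2 Non-negative multipliers.
#' @return An object of class `serotonin_params`.
#' @export
serotonin_params <- function(alpha_d1 = 1, alpha_d2 = 1, alpha_d1d2 = 1) {
  stopifnot(is.numeric(alpha_d1), is.numeric(alpha_d2),
            is.numeric(alpha_d1d2),
            alpha_d1 >= 0, alpha_d2 >= 0, alpha_d1d2 >= 0)
  structure(list(alpha_d1 = alpha_d1, alpha_d2 = alpha_d2,
                 alpha_d1d2 = alpha_d1d2),
            class = "serotonin_params")
}

#' Parkinson's-disease dopamine condition
#'
#' In PD the dopaminergic cell loss caps the positive range of the
#' prediction-error signal: `pd_off` clamps \eqn{\delta} from above at
#' `delta_lim`, and `pd_on` additionally adds a fixed medication increment
#' `delta_med` after clamping, so the attainable range becomes
#' \eqn{[a, \delta_{Lim}]} (OFF) or \eqn{[a, \delta_{Lim} + \delta_{Med}]}
#' (ON) against the control range \eqn{[a, b]}; `delta_lim + delta_med`
#' must stay below the control maximum `b`.
#'
#' @param status `"control"`, `"pd_off"` or `"pd_on"`.
#' @param delta_lim Clamp ceiling (used when `status != "control"`).
#' @param delta_med Medication increment (used when `status = "pd_on"`).
#' @return An object of class `pd_condition`.
#' @export
pd_condition <- function(status = c("control", "pd_off", "pd_on"),
                         delta_lim = 0.001, delta_med = 0.021) {
  status <- match.arg(status)
  stopifnot(is.numeric(delta_lim), is.numeric(delta_med), delta_med >= 0)
  structure(list(status = status, delta_lim = delta_lim,
                 delta_med = delta_med),
            class = "pd_condition")
}

#' Dopamine prediction error of the network model
#'
#' The single-step reward prediction error computed from the D1R value
#' read-out: \eqn{\delta = r - y_{D1}(s, a)}.
#'
#' @param weights An [msn_weights()] object.
#' @param state,action Visited pair.
#' @param reward Observed reward.
#' @return Scalar \eqn{\delta}.
#' @export
compute_delta <- function(weights, state, action, reward) {
  check_windex(weights, state, action)
  reward - weights$w_d1[state, action]
}

#' Apply the Parkinson's-disease dopamine clamp
#'
#' Control is the identity map.  PD-OFF returns
#' \eqn{\min(\delta, \delta_{Lim})}; PD-ON returns
#' \eqn{\min(\delta, \delta_{Lim}) + \delta_{Med}}.  The clamp is applied
#' to the striatal-plasticity signal before any weight update;
#' \eqn{\delta_U} is then computed from utilities built on the
#' clamp-trained weights rather than clamped independently.  The map is
#' monotone non-decreasing in \eqn{\delta} and leaves sub-ceiling values
#' (e.g. punishments) untouched, which is the mechanism behind the
#' punishment-dominant learning of the never-medicated state.
#'
#' @param delta Dopamine prediction error(s); numeric vector.
#' @param condition A [pd_condition()].
#' @return Clamped signal, same shape as `delta`.
#' @export
#' @examples
#' apply_pd(0.5, pd_condition("pd_off", delta_lim = 0.001))        # 0.001
#' apply_pd(0.5, pd_condition("pd_on", 0.001, 0.021))              # 0.022
#' apply_pd(-0.2, pd_condition("pd_off", delta_lim = 0.001))       # -0.2
apply_pd <- function(delta, condition) {
  stopifnot(inherits(condition, "pd_condition"))
  switch(condition$status,
    control = delta,
    pd_off = pmin(delta, condition$delta_lim),
    pd_on = pmin(delta, condition$delta_lim) + condition$delta_med
  )
}

#' Neuromodulator presets for the PD classification experiment
#'
#' The serotonin multipliers and dopamine clamp published for the
#' probabilistic reward-punishment classification task:
#' `controls` uses \eqn{[\alpha_{D1}, \alpha_{D2}, \alpha_{D1D2}] =
#' [1, 1, 0.2]} with no clamp; `pd_off` uses \eqn{\delta_{Lim} = 0.001}
#' with \eqn{[1, 0.99, 0.001]}; `pd_on` uses \eqn{\delta_{Lim} = 0.001,
#' \delta_{Med} = 0.021} with \eqn{[1, 0.2, 0.001]}.
#'
#' @param name One of `"controls"`, `"pd_off"`, `"pd_on"`.
#' @return List with elements `serotonin` ([serotonin_params()]) and `pd`
#'   ([pd_condition()]).
#' @export
pd_preset <- function(name = c("controls", "pd_off", "pd_on")) {
  name <- match.arg(name)
  switch(name,
    controls = list(serotonin = serotonin_params(1, 1, 0.2),
                    pd = pd_condition("control")),
    pd_off = list(serotonin = serotonin_params(1, 0.99, 0.001),
                  pd = pd_condition("pd_off", delta_lim = 0.001)),
    pd_on = list(serotonin = serotonin_params(1, 0.2, 0.001),
                 pd = pd_condition("pd_on", delta_lim = 0.001,
                                   delta_med = 0.021))
  )
}

#' @export
print.serotonin_params <- function(x, ...) {
  cat(sprintf("<serotonin_params alpha_d1=%g alpha_d2=%g alpha_d1d2=%g>\n",
              x$alpha_d1, x$alpha_d2, x$alpha_d1d2))
  invisible(x)
}

#' @export
print.pd_condition <- function(x, ...) {
  cat(sprintf("<pd_condition %s delta_lim=%g delta_med=%g>\n",
              x$status, x$delta_lim, x$delta_med))
  invisible(x)
}
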