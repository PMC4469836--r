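#' Dopamine gain-function parameters
#'
#' A gain function maps the dopamine signal (a prediction error, either the
#' reward prediction error \eqn{\delta} or the utility gradient
#' \eqn{\delta_U}) to a multiplicative effect on medium spiny neuron (MSN)
#' firing or plasticity.  Two sigmoidal forms are used: a bipolar
#' tangent-sigmoid \deqn{\lambda(\delta) = \frac{2 c_1}{1 + \exp(c_2 (\delta
#' + c_3))} - c_1,} with range \eqn{(-c_1, c_1)}, used for the D1R and D2R
#' MSN pools, and a unipolar logarithmic-sigmoid \deqn{\lambda(\delta) =
#' \frac{c_1}{1 + \exp(c_2 (\delta + c_3))},} with range \eqn{(0, c_1)},
#' used for the two receptor components of the D1R-D2R co-expressing pool.
#' The direction of dopamine action (increasing for D1R, decreasing for D2R)
#' is carried entirely by the sign of `c2`: negative `c2` gives an
#' increasing sigmoid.  A `linear` form \eqn{\lambda(\delta) = c_1 \delta}
#' is provided for reducing the network plasticity rule to plain
#' temporal-difference learning.
#'
#' @param c1 Amplitude constant.
#' @param c2 Slope constant; its sign encodes the receptor direction.
#' @param c3 Offset constant (the sigmoid is centred at `-c3`).
#' @param form One of `"tangent_sigmoid"`, `"log_sigmoid"`, `"linear"`.
#' @return An object of class `gain_params`.
#' @seealso [evaluate_gain()], [gain_set()], [gain_preset()]
#' @export
#' @examples
#' g <- gain_params(1, -5, 0, "tangent_sigmoid")
#' evaluate_gain(g, 0)      # midpoint of a bipolar sigmoid is 0
gain_params <- function(c1, c2, c3,
                        form = c("tangent_sigmoid", "log_sigmoid", "linear")) {
  form <- match.arg(form)
  stopifnot(is.numeric(c1), is.numeric(c2), is.numeric(c3),
            length(c1) == 1L, length(c2) == 1L, length(c3) == 1L,
            is.finite(c1), is.finite(c2), is.finite(c3))
  structure(list(c1 = c1, c2 = c2, c3 = c3, form = form),
            class = "gain_params")
}

#' Evaluate a dopamine gain function
#'
#' @param params A [gain_params()] object.
#' @param delta Dopamine signal(s); numeric vector.
#' @return Numeric vector of gains, finite for all finite `delta`.
#' @export
evaluate_gain <- function(params, delta) {
  stopifnot(inherits(params, "gain_params"), is.numeric(delta))
  c1 <- params$c1
  switch(params$form,
    tangent_sigmoid = 2 * c1 / (1 + exp(params$c2 * (delta + params$c3))) - c1,
    log_sigmoid = c1 / (1 + exp(params$c2 * (delta + params$c3))),
    linear = c1 * delta
  )
}

#' Gain set for one modulation site
#'
#' Bundles the gain functions of the three MSN pools used at one site:
#' either cortico-striatal plasticity (driven by the reward prediction error
#' \eqn{\delta}) or pathway gating at GPi (driven by the utility gradient
#' \eqn{\delta_U}).  The D1R-D2R co-expressing pool has no gain of its own;
#' its gain is the sum of a D1R-like and a D2R-like unipolar component
#' (`hd1`, `hd2`), which yields the "U"-shaped response needed for risk
#' (variance) coding.
#'
#' @param d1,d2 [gain_params()] for the D1R and D2R pools (`d2` may be
#'   `NULL` where a configuration does not use the D2R pool).
#' @param hd1,hd2 [gain_params()] for the D1R and D2R components of the
#'   co-expressing pool.
#' @return An object of class `gain_set`.
#' @export
gain_set <- function(d1, d2 = NULL, hd1, hd2) {
  stopifnot(inherits(d1, "gain_params"),
            is.null(d2) || inherits(d2, "gain_params"),
            inherits(hd1, "gain_params"), inherits(hd2, "gain_params"))
  structure(list(d1 = d1, d2 = d2, hd1 = hd1, hd2 = hd2),
            class = "gain_set")
}

#' Gain of the D1R-D2R co-expressing pool
#'
#' The co-expressing pool responds with the superposition of its two
#' receptor components, \eqn{\lambda_{D1D2}(\delta) = \lambda_{h-D1}(\delta)
#' + \lambda_{h-D2}(\delta)}.  When the two components are mirror images of
#' each other (equal `c1`, `c2` and `c3` of opposite sign) the sum is an
#' even, "U"-shaped function of the dopamine signal, increasing with
#' \eqn{|\delta|} and hence with \eqn{\delta^2}.
#'
#' @param gains A [gain_set()].
#' @inheritParams evaluate_gain
#' @return Numeric vector of summed gains.
#' @export
d1d2_gain <- function(gains, delta) {
  stopifnot(inherits(gains, "gain_set"))
  evaluate_gain(gains$hd1, delta) + evaluate_gain(gains$hd2, delta)
}

#' Published gain-parameter presets
#'
#' Named parameter sets for the gain functions, one per experimental
#' configuration:
#' \describe{
#'   \item{`table1`}{Striatal plasticity gains for the risk-tracking
#'     demonstration (no D2R column; only D1R and the two co-expression
#'     components are exercised there).}
#'   \item{`table3`}{GPi gating gains (functions of \eqn{\delta_U}), shared
#'     by all three behavioral experiments.}
#'   \item{`table5`}{Striatal plasticity gains for the risk-sensitivity
#'     (safe/risky juice) experiment.}
#'   \item{`table6`}{Striatal plasticity gains for the reversal-learning
#'     (tryptophan depletion) experiment.}
#'   \item{`table8`}{Striatal plasticity gains for the probabilistic
#'     reward-punishment classification (PD) experiment.}
#' }
#'
#' @param name Preset name.
#' @return A [gain_set()].
#' @export
#' @examples
#' gp <- gain_preset("table3")
#' evaluate_gain(gp$d1, 0.5)
gain_preset <- function(name = c("table1", "table3", "table5", "table6",
                                 "table8")) {
  name <- match.arg(name)
  switch(name,
    table1 = gain_set(
      d1  = gain_params(1, -5, 0, "tangent_sigmoid"),
      d2  = NULL,
      hd1 = gain_params(0.1, -25, -0.5, "log_sigmoid"),
      hd2 = gain_params(0.1, 25, 0.5, "log_sigmoid")),
    table3 = gain_set(
      d1  = gain_params(1, -50, 0.01, "tangent_sigmoid"),
      d2  = gain_params(1, 50, 0.01, "tangent_sigmoid"),
      hd1 = gain_params(0.05, -0.01, -0.05, "log_sigmoid"),
      hd2 = gain_params(0.05, 0.01, 0.05, "log_sigmoid")),
    table5 = gain_set(
      d1  = gain_params(10, -0.1, 0, "tangent_sigmoid"),
      d2  = gain_params(0.01, 0.05, 0, "tangent_sigmoid"),
      hd1 = gain_params(0.05, -5, -100.1, "log_sigmoid"),
      hd2 = gain_params(0.05, 0.5, 100.1, "log_sigmoid")),
    table6 = gain_set(
      d1  = gain_params(0.06, -0.155, -0.574, "tangent_sigmoid"),
      d2  = gain_params(0.115, 0.488, 0.317, "tangent_sigmoid"),
      hd1 = gain_params(0.939, -0.188, -1.723, "log_sigmoid"),
      hd2 = gain_params(0.939, 0.188, 1.723, "log_sigmoid")),
    table8 = gain_set(
      d1  = gain_params(1, -50, 0, "tangent_sigmoid"),
      d2  = gain_params(1, 50, -1, "tangent_sigmoid"),
      hd1 = gain_params(0.05, -0.01, -0.05, "log_sigmoid"),
      hd2 = gain_params(0.05, 0.01, 0.05, "log_sigmoid"))
  )
}

#' @export
print.gain_params <- function(x, ...) {
  cat(sprintf("<gain_params %s: c1=%g c2=%g c3=%g>\n",
              x$form, x$c1, x$c2, x$c3))
  invisible(x)
}

#' @export
print.gain_set <- function(x, ...) {
  cat("<gain_set>\n")
  for (nm in c("d1", "d2", "hd1", "hd2")) {
    if (is.null(x[[nm]])) {
      cat(sprintf("  %-4s (absent)\n", nm))
    } else {
      cat(sprintf("  %-4s %s c1=%g c2=%g c3=%g\n", nm, x[[nm]]$form,
                  x[[nm]]$c1, x[[nm]]$c2, x[[nm]]$c3))
    }
  }
  invisible(x)
}
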