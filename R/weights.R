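# Switch-count probability weights conditional on the visited states.
# For one interval of length dt started in state s1 with first switch to s2:
#   P(W = 0 | s1)        = exp(-lambda_1 dt)
#   P(W = 1 | s1, s2)    = P(tau_1 <= dt, tau_2 > dt - tau_1)
#   P(W >= 2 | s1, s2)   = P(tau_1 + tau_2 <= dt)   (hypoexponential CDF)
# and the three weights partition unity for every (s1, s2).

#' Probability of no switch in one interval
#'
#' @param lambda_s Positive switching rate of the occupying state.
#' @param dt Non-negative interval length.
#' @return `exp(-lambda_s * dt)`.
#' @export
no_switch_weight <- function(lambda_s, dt) {
  if (any(lambda_s <= 0) || any(dt < 0)) {
    stop_vjump("lambda must be positive and dt non-negative",
               "vjump_error_input")
  }
  exp(-lambda_s * dt)
}

#' Probability of exactly one switch given the first two states
#'
#' Closed form `lambda_1 (exp(-lambda_2 dt) - exp(-lambda_1 dt)) /
#' (lambda_1 - lambda_2)`, evaluated through a stable `expm1` form that
#' covers the equal-rate limit `lambda dt exp(-lambda dt)` continuously.
#'
#' @param s1,s2 Distinct state indices.
#' @param model A `vj_model`.
#' @param dt Interval length.
#' @return `P(W = 1 | S1 = s1, S2 = s2)`.
#' @export
one_switch_weight <- function(s1, s2, model, dt) {
  if (s1 == s2) stop_vjump("s1 and s2 must differ", "vjump_error_input")
  one_switch_weight_rates(model$rates[s1], model$rates[s2], dt)
}

one_switch_weight_rates <- function(l1, l2, dt) {
  mu <- l1 - l2
  # l1 * (e^{-l2 dt} - e^{-l1 dt}) / mu = l1 dt e^{-l2 dt} * (1-e^{-mu dt})/(mu dt)
  l1 * dt * exp(-l2 * dt) * expm1_ratio(mu * dt)
}

#' Probability of at least two switches given the first two states
#'
#' Hypoexponential CDF of `tau_1 + tau_2` at `dt`; independent of the third
#' state. Uses the `1 - exp(-lambda dt) (1 + lambda dt)` limit when the two
#' rates agree to within `1e-8 / dt`.
#'
#' @inheritParams one_switch_weight
#' @return `P(W >= 2 | S1 = s1, S2 = s2)`.
#' @export
two_plus_switch_weight <- function(s1, s2, model, dt) {
  if (s1 == s2) stop_vjump("s1 and s2 must differ", "vjump_error_input")
  two_plus_switch_weight_rates(model$rates[s1], model$rates[s2], dt)
}

two_plus_switch_weight_rates <- function(l1, l2, dt) {
  if (abs(l1 - l2) * dt < 1e-8) {
    lbar <- (l1 + l2) / 2
    -expm1(-lbar * dt) - lbar * dt * exp(-lbar * dt)
  } else {
    1 - (l2 * exp(-l1 * dt) - l1 * exp(-l2 * dt)) / (l2 - l1)
  }
}
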