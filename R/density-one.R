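# Conditional increment densities for zero and one switch per interval.
# Noisy increments carry variance 2 sigma^2 (difference of two independent
# endpoint errors).

velocity_tol <- function(model) 1e-12 * max(1, max(abs(model$velocities)))

# Stable log of P(lo < Z < hi), standard normal.
log_pnorm_diff <- function(lo, hi) {
  upper <- (lo + hi) > 0
  la <- ifelse(upper, pnorm(lo, lower.tail = FALSE, log.p = TRUE),
               pnorm(hi, log.p = TRUE))
  lb <- ifelse(upper, pnorm(hi, lower.tail = FALSE, log.p = TRUE),
               pnorm(lo, log.p = TRUE))
  la + log1p(-pmin(exp(lb - la), 1))
}

#' Zero-switch noisy increment density
#'
#' With no switch the agent keeps velocity `v_s` for the whole interval, so
#' the noisy increment is `Normal(v_s * dt, 2 sigma^2)`.
#'
#' @param dy Numeric vector of noisy increments.
#' @param s State index occupied for the whole interval.
#' @param model A `vj_model`.
#' @param scheme A `vj_scheme` with `sigma > 0`.
#' @return Density values (1/length).
#' @export
zero_switch_density <- function(dy, s, model, scheme) {
  if (scheme$sigma <= 0) {
    stop_vjump("degenerate density: sigma must be positive",
               "vjump_error_degenerate")
  }
  dnorm(dy, mean = model$velocities[s] * scheme$dt,
        sd = sqrt(2) * scheme$sigma)
}

#' Exact one-switch increment density
#'
#' Conditional on exactly one switch from `s1` to `s2`, the switching time
#' has a truncated-exponential density proportional to
#' `exp(-(lambda_1 - lambda_2) t1)` on `[0, dt]`; the exact increment
#' `dx = v1 t1 + v2 (dt - t1)` is its monotone image, so the density is the
#' change of variables with Jacobian `1 / |v1 - v2|`, supported on the
#' interval between `v1 dt` and `v2 dt`.
#'
#' @param dx Numeric vector of exact increments.
#' @param s1,s2 Distinct state indices with distinct velocities.
#' @param model A `vj_model`.
#' @param dt Interval length.
#' @return Density values (1/length).
#' @export
one_switch_exact_density <- function(dx, s1, s2, model, dt) {
  if (s1 == s2) stop_vjump("s1 and s2 must differ", "vjump_error_input")
  v1 <- model$velocities[s1]
  v2 <- model$velocities[s2]
  if (abs(v1 - v2) <= velocity_tol(model)) {
    stop_vjump("degenerate: equal velocities, use zero-switch form",
               "vjump_error_degenerate")
  }
  mu <- model$rates[s1] - model$rates[s2]
  z_norm <- dt * expm1_ratio(mu * dt)   # integral of exp(-mu t) over [0, dt]
  t1 <- (dx - v2 * dt) / (v1 - v2)
  out <- ifelse(t1 >= 0 & t1 <= dt,
                exp(-mu * t1) / (z_norm * abs(v1 - v2)),
                0)
  out
}

#' One-switch noisy increment density (closed form)
#'
#' Convolution of the exact one-switch density with `Normal(0, 2 sigma^2)`.
#' The truncated-exponential-times-Gaussian integral has the closed form
#' `C exp(-alpha dy + alpha^2 s^2 / 2) * (Phi(h) - Phi(l))` with
#' `alpha = (lambda_1 - lambda_2) / (v1 - v2)` and `s^2 = 2 sigma^2`,
#' evaluated in log space for stability. With tied velocities the increment
#' is deterministic and the density is the shared-velocity Gaussian.
#'
#' @inheritParams one_switch_exact_density
#' @param dy Numeric vector of noisy increments.
#' @param scheme A `vj_scheme` with `sigma > 0`.
#' @param method `"closed_form"` (default) or `"quadrature"` (adaptive
#'   integration fallback of the defining convolution).
#' @return Density values with a `"branch"` attribute naming the branch used.
#' @export
one_switch_noisy_density <- function(dy, s1, s2, model, scheme,
                                     method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  if (s1 == s2) stop_vjump("s1 and s2 must differ", "vjump_error_input")
  if (scheme$sigma <= 0) {
    stop_vjump("sigma must be positive", "vjump_error_degenerate")
  }
  v1 <- model$velocities[s1]
  v2 <- model$velocities[s2]
  dt <- scheme$dt
  s <- sqrt(2) * scheme$sigma
  if (abs(v1 - v2) <= velocity_tol(model)) {
    out <- dnorm(dy, mean = v1 * dt, sd = s)
    attr(out, "branch") <- "velocity_tie"
    return(out)
  }
  a <- min(v1 * dt, v2 * dt)
  b <- max(v1 * dt, v2 * dt)
  if (method == "quadrature") {
    out <- vapply(dy, function(z) {
      integrate(function(u) {
        one_switch_exact_density(u, s1, s2, model, dt) * dnorm(z - u, sd = s)
      }, lower = a, upper = b, rel.tol = 1e-10, abs.tol = 1e-12,
      subdivisions = 400L)$value
    }, numeric(1))
    attr(out, "branch") <- "quadrature"
    return(out)
  }
  mu <- model$rates[s1] - model$rates[s2]
  alpha <- mu / (v1 - v2)
  z_norm <- dt * expm1_ratio(mu * dt)
  log_c <- alpha * v2 * dt - log(z_norm * abs(v1 - v2))
  m <- dy - alpha * s^2
  log_val <- log_c - alpha * dy + alpha^2 * s^2 / 2 +
    log_pnorm_diff((a - m) / s, (b - m) / s)
  out <- exp(log_val)
  attr(out, "branch") <- "closed_form"
  out
}
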