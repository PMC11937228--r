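# Conditional increment densities for exactly two switches per interval.
#
# Given states s1 -> s2 -> s3 and W = 2, the holding times (t1, t2) have
# joint density proportional to exp(-(l1-l3) t1) exp(-(l2-l3) t2) on the
# triangle {t1 > 0, t2 > 0, t1 + t2 < dt}. The exact increment
#   dx = v1 t1 + v2 t2 + v3 (dt - t1 - t2)
# is obtained by sifting the Dirac delta over t2, leaving a one-dimensional
# exponential integral over t1 whose domain A = [E0, E1] is the exact
# intersection of three linear constraints (piecewise linear in dx). States
# with tied velocities (including s3 = s1, where v3 = v1) reduce to
# one-dimensional changes of variables.

# Z = \int\int_{t1 + t2 < dt} exp(-a t1 - b t2) dt2 dt1 (symmetric in a, b):
# the normalizer of the (t1, t2) density conditional on exactly two switches,
# since lambda1 lambda2 e^{-lambda3 dt} Z = P(W = 2 | s1, s2, s3).
two_switch_log_norm <- function(l1, l2, l3, dt) {
  a <- l1 - l3
  b <- l2 - l3
  if (abs(a) < abs(b)) { tmp <- a; a <- b; b <- tmp }
  z <- if (abs(a) * dt < 1e-6) {
    dt^2 / 2 * (1 - (a + b) * dt / 3)
  } else {
    (exp_int(b, dt) - exp(-a * dt) * exp_int(b - a, dt)) / a
  }
  log(z)
}

# exp(-a t) integrated over [0, u], vectorized, stable at a -> 0; zero for
# negative u.
exp_int <- function(a, u) {
  ifelse(u > 0, u * expm1_ratio(a * u), 0)
}

#' Exact two-switch increment density
#'
#' Density of the exact increment conditional on exactly two switches with
#' visited states `s1 -> s2 -> s3`. Supported on
#' `[min(v) * dt, max(v) * dt]` over the three velocities involved. The
#' `s3 = s1` case and velocity ties reduce to one-dimensional densities of a
#' single holding time (or of `t1 + t2`).
#'
#' @param dx Numeric vector of exact increments.
#' @param s1,s2,s3 State indices with `s1 != s2`, `s2 != s3`.
#' @param model A `vj_model`.
#' @param dt Interval length.
#' @return Density values with a `"branch"` attribute.
#' @export
two_switch_exact_density <- function(dx, s1, s2, s3, model, dt) {
  if (s1 == s2 || s2 == s3) {
    stop_vjump("consecutive states must differ", "vjump_error_input")
  }
  v <- model$velocities[c(s1, s2, s3)]
  lam <- model$rates[c(s1, s2, s3)]
  vtol <- velocity_tol(model)
  a <- lam[1] - lam[3]
  b <- lam[2] - lam[3]
  log_z <- two_switch_log_norm(lam[1], lam[2], lam[3], dt)

  tie12 <- abs(v[1] - v[2]) <= vtol
  tie13 <- abs(v[1] - v[3]) <= vtol
  tie23 <- abs(v[2] - v[3]) <= vtol

  if (tie12 && tie13 && tie23) {
    stop_vjump("degenerate: all three velocities equal",
               "vjump_error_degenerate")
  }

  if (tie13) {
    # dx depends on t2 only (covers s3 = s1); marginal of t2 given W = 2.
    t2 <- (dx - v[1] * dt) / (v[2] - v[1])
    dens <- exp(-b * t2 - log_z) * exp_int(a, dt - t2)
    out <- ifelse(t2 >= 0 & t2 <= dt, dens, 0) / abs(v[2] - v[1])
    attr(out, "branch") <- if (s3 == s1) "s3_equals_s1" else "tie_v1_v3"
    return(out)
  }
  if (tie23) {
    # dx depends on t1 only; marginal of t1 given W = 2.
    t1 <- (dx - v[2] * dt) / (v[1] - v[2])
    dens <- exp(-a * t1 - log_z) * exp_int(b, dt - t1)
    out <- ifelse(t1 >= 0 & t1 <= dt, dens, 0) / abs(v[1] - v[2])
    attr(out, "branch") <- "tie_v2_v3"
    return(out)
  }
  if (tie12) {
    # dx depends on u = t1 + t2 only; density of u on [0, dt].
    u <- (dx - v[3] * dt) / (v[1] - v[3])
    dens <- exp(-b * u - log_z) * exp_int(a - b, u)
    out <- ifelse(u >= 0 & u <= dt, dens, 0) / abs(v[1] - v[3])
    attr(out, "branch") <- "tie_v1_v2"
    return(out)
  }

  # General case: all three velocities distinct.
  p <- (v[1] - v[3]) / (v[3] - v[2])
  q <- (v[3] * dt - dx) / (v[3] - v[2])
  beta <- a + b * p
  lower <- rep(0, length(dx))
  upper <- rep(dt, length(dx))
  # t2*(t1) = p t1 + q >= 0
  if (p > 0) lower <- pmax(lower, -q / p) else upper <- pmin(upper, -q / p)
  # (p + 1) t1 <= dt - q, p + 1 = (v1 - v2)/(v3 - v2) != 0 here
  bound <- (dt - q) / (p + 1)
  if (p + 1 > 0) upper <- pmin(upper, bound) else lower <- pmax(lower, bound)
  len <- upper - lower
  t2_at_lower <- p * lower + q
  # integrand exponent is linear in t1; integrate from the lower endpoint
  out <- ifelse(
    len > 0,
    exp(-a * lower - b * t2_at_lower - log_z) * exp_int(beta, len) /
      abs(v[3] - v[2]),
    0
  )
  attr(out, "branch") <- "general"
  out
}

#' Two-switch noisy increment density
#'
#' Convolution of [two_switch_exact_density()] with `Normal(0, 2 sigma^2)`,
#' evaluated by adaptive quadrature over the support, split at the interior
#' velocity breakpoints where the exact density has kinks.
#'
#' @inheritParams two_switch_exact_density
#' @param dy Numeric vector of noisy increments.
#' @param scheme A `vj_scheme` with `sigma > 0`.
#' @return Density values with a `"branch"` attribute (always
#'   `"quadrature"` over the closed-form exact density).
#' @export
two_switch_noisy_density <- function(dy, s1, s2, s3, model, scheme) {
  if (scheme$sigma <= 0) {
    stop_vjump("sigma must be positive", "vjump_error_degenerate")
  }
  dt <- scheme$dt
  s <- sqrt(2) * scheme$sigma
  v <- model$velocities[c(s1, s2, s3)]
  pts <- sort(unique(v)) * dt
  out <- vapply(dy, function(z) {
    total <- 0
    for (k in seq_len(length(pts) - 1L)) {
      total <- total + integrate(
        function(u) {
          two_switch_exact_density(u, s1, s2, s3, model, dt) *
            dnorm(z - u, sd = s)
        },
        lower = pts[k], upper = pts[k + 1L],
        rel.tol = 1e-9, abs.tol = 1e-12, subdivisions = 400L
      )$value
    }
    total
  }, numeric(1))
  attr(out, "branch") <- "quadrature"
  out
}
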