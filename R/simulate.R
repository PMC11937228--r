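#' Simulate an exact continuous-time state path
#'
#' Gillespie-style exact simulation of the hidden CTMC: the initial state is
#' drawn from the stationary distribution, holding times are exponential with
#' the current state's rate, and the next state is drawn from the embedded
#' transition matrix. The path overshoots `duration` by one holding time and
#' is truncated, so the state is defined on all of `[0, duration]`.
#'
#' @param model A validated `vj_model`.
#' @param duration Positive total time to cover.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param init_state Optional fixed initial state index; default samples from
#'   the stationary distribution.
#' @return An object of class `vj_path`: list with `jump_times` (starting at
#'   0), `states` (state index occupied from each jump time), `duration`,
#'   and `seed`.
#' @export
sample_state_path <- function(model, duration, seed = NULL,
                              init_state = NULL) {
  if (!is_scalar_number(duration) || duration <= 0) {
    stop_vjump("duration must be positive", "vjump_error_input")
  }
  pi0 <- stationary_vector(model)
  with_seed(seed, {
    n_guess <- max(16L, ceiling(duration * max(model$rates) * 1.5))
    times <- numeric(n_guess)
    states <- integer(n_guess)
    if (is.null(init_state)) {
      s <- sample.int(model$n, 1L, prob = pi0)
    } else {
      s <- as.integer(init_state)
    }
    times[1L] <- 0
    states[1L] <- s
    k <- 1L
    t_now <- 0
    repeat {
      t_now <- t_now + rexp(1L, rate = model$rates[s])
      if (t_now > duration) break
      s <- sample.int(model$n, 1L, prob = model$transition_probs[s, ])
      k <- k + 1L
      if (k > length(times)) {
        times <- c(times, numeric(length(times)))
        states <- c(states, integer(length(states)))
      }
      times[k] <- t_now
      states[k] <- s
    }
    structure(
      list(jump_times = times[seq_len(k)], states = states[seq_len(k)],
           duration = duration, seed = seed),
      class = "vj_path"
    )
  })
}

#' @export
print.vj_path <- function(x, ...) {
  cat(sprintf("<vj_path> %d jumps over [0, %g]\n",
              length(x$jump_times) - 1L, x$duration))
  invisible(x)
}

# State occupied at each time point (right-continuous at jumps).
path_state_at <- function(path, t) {
  path$states[findInterval(t, path$jump_times)]
}

# Exact position x(t) by piecewise-linear integration of the velocity.
path_position_at <- function(path, t, velocities) {
  jt <- path$jump_times
  vseg <- velocities[path$states]
  seg_len <- diff(c(jt, path$duration))
  cumdisp <- c(0, cumsum(vseg * seg_len))[seq_along(jt)]
  k <- findInterval(t, jt)
  cumdisp[k] + vseg[k] * (t - jt[k])
}

#' Observe a state path as a discrete-time noisy track
#'
#' Records the agent location every `dt` time units and adds independent
#' Gaussian measurement noise. Positions are computed by exact piecewise
#' linear integration of the velocity along the path, so there is no
#' time-discretization error. Interval `j` is the half-open interval
#' `(t_{j-1}, t_j]`; a jump exactly at a frame time is counted in the earlier
#' interval.
#'
#' @param path A `vj_path` with `duration >= n_increments * dt`.
#' @param scheme A `vj_scheme`.
#' @param velocities Per-state velocities (defaults can be supplied via
#'   `model`).
#' @param model Optional `vj_model` supplying `velocities` and state names.
#' @param seed Optional integer seed for the measurement noise.
#' @return A tibble with one row per frame: `frame` (0-based), `t`, `x`
#'   (exact), `y` (noisy), `state` (index at the frame time) and `w` (number
#'   of switches in the interval ending at this frame; `NA` for frame 0).
#' @export
observe_track <- function(path, scheme, velocities = NULL, model = NULL,
                          seed = NULL) {
  if (is.null(velocities)) {
    if (is.null(model)) {
      stop_vjump("supply velocities or a model", "vjump_error_input")
    }
    velocities <- model$velocities
  }
  N <- scheme$n_increments
  if (path$duration < N * scheme$dt - 1e-12) {
    stop_vjump("path shorter than n_increments * dt", "vjump_error_input")
  }
  t_frames <- (0:N) * scheme$dt
  x <- path_position_at(path, t_frames, velocities)
  eps <- with_seed(seed, rnorm(N + 1L, sd = scheme$sigma))
  # Interior jumps only (the path's first entry is the t = 0 start record).
  jumps <- path$jump_times[-1L]
  idx <- findInterval(jumps, t_frames, left.open = TRUE)
  w <- tabulate(idx[idx >= 1L & idx <= N], nbins = N)
  tibble::tibble(
    frame = 0:N,
    t = t_frames,
    x = x,
    y = x + eps,
    state = path_state_at(path, t_frames),
    w = c(NA_integer_, w)
  )
}

#' Simulate a set of noisy tracks
#'
#' Convenience wrapper: simulates `n_tracks` independent stationary-start
#' state paths and observes each with the given scheme.
#'
#' @inheritParams sample_state_path
#' @param scheme A `vj_scheme`.
#' @param n_tracks Number of independent tracks.
#' @return A tibble with columns `track_id`, `frame`, `t`, `x`, `y`, `state`,
#'   `w`; the seed is recorded in the `"seed"` attribute.
#' @export
simulate_tracks <- function(model, scheme, n_tracks = 1L, seed = NULL) {
  out <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_tracks), function(id) {
      path <- sample_state_path(model, scheme$total_time)
      dplyr::mutate(observe_track(path, scheme, model$velocities),
                    track_id = id, .before = 1L)
    })
  })
  attr(out, "seed") <- seed
  out
}

# Vectorized stationary single-interval sampler over [0, dt]: returns exact
# increment dx and switch count w for `reps` independent intervals.
stationary_interval_sample <- function(model, dt, reps) {
  v <- model$velocities
  lam <- model$rates
  P <- model$transition_probs
  state <- sample.int(model$n, reps, replace = TRUE,
                      prob = stationary_vector(model))
  remaining <- rep(dt, reps)
  dx <- numeric(reps)
  w <- integer(reps)
  active <- seq_len(reps)
  while (length(active) > 0) {
    tau <- rexp(length(active), rate = lam[state[active]])
    stay <- tau >= remaining[active]
    move <- pmin(tau, remaining[active])
    dx[active] <- dx[active] + v[state[active]] * move
    remaining[active] <- remaining[active] - move
    switching <- active[!stay]
    if (length(switching) > 0) {
      w[switching] <- w[switching] + 1L
      from <- state[switching]
      for (s in unique(from)) {
        idx <- switching[from == s]
        state[idx] <- sample.int(model$n, length(idx), replace = TRUE,
                                 prob = P[s, ])
      }
    }
    active <- switching
  }
  list(dx = dx, w = w, end_state = state)
}

#' Draw independent stationary noisy increments
#'
#' Each draw simulates a single frame interval `[0, dt]` started from the
#' stationary state distribution and returns the noisy increment and the
#' number of switches. Marginally this has the same law as a consecutive
#' increment of a long stationary track (the joint laws differ).
#'
#' @inheritParams simulate_tracks
#' @param reps Number of independent intervals.
#' @return A tibble with columns `dx` (exact increment), `dy` (noisy
#'   increment) and `w` (switch count).
#' @export
draw_stationary_increments <- function(model, scheme, reps, seed = NULL) {
  stopifnot(reps >= 1)
  with_seed(seed, {
    sim <- stationary_interval_sample(model, scheme$dt, reps)
    tibble::tibble(
      dx = sim$dx,
      dy = sim$dx + rnorm(reps, sd = sqrt(2) * scheme$sigma),
      w = sim$w
    )
  })
}

#' Monte-Carlo switch-count distribution
#'
#' Estimates the stationary-start probability mass function of the number of
#' switches `W` in one frame interval.
#'
#' @inheritParams simulate_tracks
#' @param dt Frame interval.
#' @param reps Number of Monte-Carlo intervals.
#' @return A tibble with columns `w` (0 up to the largest observed count) and
#'   `prob`; probabilities sum to one. The number of replicates is stored in
#'   the `"reps"` attribute.
#' @export
switch_count_distribution <- function(model, dt, reps, seed = NULL) {
  stopifnot(reps >= 1)
  w <- with_seed(seed, stationary_interval_sample(model, dt, reps)$w)
  counts <- tabulate(w + 1L, nbins = max(w) + 1L)
  out <- tibble::tibble(w = seq_along(counts) - 1L, prob = counts / reps)
  attr(out, "reps") <- reps
  out
}

#' Rejection-sampling oracle for conditional exact increments
#'
#' Samples the exact location increment over one interval conditional on a
#' prescribed ordered sequence of visited states and exactly `w = length(s) -
#' 1` switches. Holding times are proposed from their unconditional
#' exponential laws and accepted when exactly the prescribed number of
#' switches falls in `[0, dt]`. Used as a Monte-Carlo ground truth for the
#' analytic conditional densities.
#'
#' @param model A validated `vj_model`.
#' @param dt Frame interval.
#' @param states Integer vector of visited states (consecutive entries must
#'   differ).
#' @param reps Number of accepted draws required.
#' @param seed Optional integer seed.
#' @param max_batches Safety cap on proposal batches.
#' @return Numeric vector of `reps` accepted exact increments; the estimated
#'   acceptance probability is attached as the `"acceptance"` attribute.
#' @export
conditional_increment_oracle <- function(model, dt, states, reps,
                                         seed = NULL, max_batches = 400L) {
  states <- as.integer(states)
  w <- length(states) - 1L
  if (w > 0 && any(states[-1L] == states[-length(states)])) {
    stop_vjump("consecutive states must differ", "vjump_error_input")
  }
  lam <- model$rates[states]
  v <- model$velocities[states]
  with_seed(seed, {
    acc <- numeric(0)
    proposed <- 0
    batch <- max(10000L, 4L * reps)
    for (i in seq_len(max_batches)) {
      tau <- matrix(rexp((w + 1L) * batch, rate = lam),
                    nrow = batch, byrow = TRUE)
      cum_w <- if (w == 0) numeric(batch) else {
        if (w == 1L) tau[, 1L] else rowSums(tau[, seq_len(w), drop = FALSE])
      }
      ok <- cum_w <= dt & (cum_w + tau[, w + 1L]) > dt
      proposed <- proposed + batch
      if (any(ok)) {
        tau_ok <- tau[ok, , drop = FALSE]
        dx <- if (w == 0) rep(v[1L] * dt, nrow(tau_ok)) else {
          drop(tau_ok[, seq_len(w), drop = FALSE] %*% v[seq_len(w)]) +
            v[w + 1L] * (dt - cum_w[ok])
        }
        acc <- c(acc, dx)
      }
      if (length(acc) >= reps) break
      if (proposed >= 2e5 && length(acc) / proposed < 1e-6) {
        stop_vjump(
          sprintf("acceptance probability ~%.2g below 1e-6; aborting",
                  length(acc) / proposed),
          "vjump_error_acceptance"
        )
      }
    }
    if (length(acc) < reps) {
      stop_vjump("rejection oracle failed to reach requested draws",
                 "vjump_error_acceptance")
    }
    out <- acc[seq_len(reps)]
    attr(out, "acceptance") <- length(acc) / proposed
    out
  })
}
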