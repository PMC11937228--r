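# Up-to-one-switch approximation of the joint density of a track's noisy
# increments, computed by a forward filter over the hidden state at the start
# of each interval. Cross-interval noise correlation (the -sigma^2 covariance
# between successive noise increments) is neglected, following the
# independence approximation used throughout; each emission carries variance
# 2 sigma^2.

#' Pairwise interval density-probability kernel
#'
#' Up-to-one-switch approximation of the joint density-probability
#' `P(dy_j, S^{j+1}_1 = u | S^j_1 = s)` of observing an increment `dy` while
#' the hidden state moves from `s` at the start of the interval to `u` at its
#' end: with no switch (`u = s`) the zero-switch Gaussian weighted by
#' `exp(-lambda_s dt)`; with one switch (`u != s`) the one-switch noisy
#' density weighted by `p_su (1 - exp(-lambda_s dt))`.
#'
#' @param dy Numeric vector of noisy increments.
#' @param s,u State indices (start and end of the interval).
#' @param model A validated `vj_model`.
#' @param scheme A `vj_scheme` with `sigma > 0`.
#' @return Numeric vector of joint density-probability values.
#' @export
pairwise_interval_density <- function(dy, s, u, model, scheme) {
  n <- model$n
  if (!(s %in% seq_len(n)) || !(u %in% seq_len(n))) {
    stop_vjump("invalid state index", "vjump_error_input")
  }
  w0 <- no_switch_weight(model$rates[s], scheme$dt)
  if (u == s) {
    zero_switch_density(dy, s, model, scheme) * w0
  } else if (model$transition_probs[s, u] == 0) {
    rep(0, length(dy))
  } else {
    as.numeric(one_switch_noisy_density(dy, s, u, model, scheme)) *
      model$transition_probs[s, u] * (1 - w0)
  }
}

# n x n x N array K[s, u, j] = pairwise(dy_j, s, u), vectorized over j.
pairwise_kernel_array <- function(increments, model, scheme) {
  n <- model$n
  K <- array(0, dim = c(n, n, length(increments)))
  for (s in seq_len(n)) {
    for (u in seq_len(n)) {
      if (u != s && model$transition_probs[s, u] == 0) next
      K[s, u, ] <- pairwise_interval_density(increments, s, u, model, scheme)
    }
  }
  K
}

#' Forward filter over a sequence of noisy increments
#'
#' Computes the up-to-one-switch approximation of the joint density of `N`
#' subsequent noisy increments by the recursion: starting from the stationary
#' state distribution `b_1 = pi`, each step forms
#' `m[s, u] = pairwise(dy_j, s, u) b_j[s]`, accumulates the per-step evidence
#' `e_j = sum(m)` and updates `b_{j+1}[u] = sum_s m[s, u] / e_j`. The product
#' of the evidences is the approximate joint density; the recursion is exact
#' algebra given the pairwise kernel.
#'
#' @param increments Numeric vector of noisy increments (one track, in
#'   order).
#' @param model A validated `vj_model`.
#' @param scheme A `vj_scheme` with `sigma > 0`.
#' @return An object of class `vj_filter`: list with `log_lik` (sum of log
#'   evidences), `evidence` (per-step log evidence) and `state_probs`, an
#'   `(N + 1) x n` matrix whose row `j` is `P(S^j_1 | dy_1 .. dy_{j-1})`.
#' @export
forward_filter <- function(increments, model, scheme) {
  N <- length(increments)
  if (N < 1) stop_vjump("need at least one increment", "vjump_error_input")
  n <- model$n
  K <- pairwise_kernel_array(increments, model, scheme)
  b <- stationary_vector(model)
  state_probs <- matrix(0, nrow = N + 1L, ncol = n,
                        dimnames = list(NULL, model$state_names))
  state_probs[1L, ] <- b
  log_ev <- numeric(N)
  for (j in seq_len(N)) {
    m <- K[, , j] * b
    e_j <- sum(m)
    if (!is.finite(e_j) || e_j <= 0) {
      stop_vjump(
        sprintf("zero-likelihood at interval %d: increment outside the support of the approximation", j),
        "vjump_error_zero_likelihood"
      )
    }
    log_ev[j] <- log(e_j)
    b <- colSums(m) / e_j
    state_probs[j + 1L, ] <- b
  }
  structure(
    list(log_lik = sum(log_ev), evidence = log_ev,
         state_probs = state_probs, n_increments = N),
    class = "vj_filter"
  )
}

#' @export
print.vj_filter <- function(x, ...) {
  cat(sprintf("<vj_filter> N = %d increments, log density = %.4f\n",
              x$n_increments, x$log_lik))
  invisible(x)
}

#' Tidy filter states
#'
#' @param x A `vj_filter`.
#' @param ... Unused.
#' @return A tibble with columns `interval` (1 is the prior before any
#'   data), `state` and `prob`.
#' @export
tidy.vj_filter <- function(x, ...) {
  tibble::as_tibble(x$state_probs) |>
    dplyr::mutate(interval = dplyr::row_number()) |>
    tidyr::pivot_longer(-"interval", names_to = "state", values_to = "prob")
}

#' Naive independent-product log density
#'
#' Baseline that multiplies the order-1 marginal density of each increment,
#' ignoring the correlation between subsequent increments induced by the
#' hidden state.
#'
#' @inheritParams forward_filter
#' @return Scalar log density.
#' @export
naive_product_loglik <- function(increments, model, scheme) {
  vals <- marginal_density(increments, model, scheme, order = 1)
  if (any(vals <= 0 | !is.finite(vals))) {
    stop_vjump("zero-likelihood increment in naive product",
               "vjump_error_zero_likelihood")
  }
  sum(log(vals))
}

#' Per-track log densities for a table of tracks
#'
#' @param tracks A tibble with columns `track_id`, `frame`, `y` (as produced
#'   by [simulate_tracks()] or [read_tracks()]).
#' @param model A validated `vj_model`.
#' @param scheme A `vj_scheme`.
#' @return A tibble with one row per track: `track_id`, `n_increments`,
#'   `loglik_filter` and `loglik_naive`.
#' @export
track_loglik <- function(tracks, model, scheme) {
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_increments = dplyr::n() - 1L,
      loglik_filter = forward_filter(diff(.data$y), model, scheme)$log_lik,
      loglik_naive = naive_product_loglik(diff(.data$y), model, scheme),
      .groups = "drop"
    )
}

#' Joint up-to-one-switch density of two subsequent increments
#'
#' Evaluates `P1(dy1, dy2) = sum_{s,u} pi_s k(dy1, s, u) sum_r k(dy2, u, r)`
#' on a grid, together with the naive product `P1(dy1) P1(dy2)` for
#' comparison.
#'
#' @param grid1,grid2 Numeric grids for the first and second increment.
#' @param model A validated `vj_model`.
#' @param scheme A `vj_scheme` with `sigma > 0`.
#' @return A tibble with columns `dy1`, `dy2`, `joint` (the filtered
#'   approximation) and `product` (the independence baseline).
#' @export
joint_pair_density <- function(grid1, grid2, model, scheme) {
  n <- model$n
  pi0 <- stationary_vector(model)
  K1 <- pairwise_kernel_array(grid1, model, scheme)  # n x n x |grid1|
  K2 <- pairwise_kernel_array(grid2, model, scheme)
  # M2[u, ] = sum_r k(dy2, u, r): density of dy2 given start state u.
  M2 <- apply(K2, c(1, 3), sum)
  # joint(y1, y2) = sum_u [ sum_s pi_s K1[s, u, y1] ] * M2[u, y2]
  A <- apply(K1 * pi0, c(2, 3), sum)                 # n x |grid1|
  joint <- t(A) %*% M2                               # |grid1| x |grid2|
  p1 <- colSums(A)                                   # P1(dy1) on grid1
  p2 <- colSums(apply(K2 * pi0, c(2, 3), sum))       # P1(dy2) on grid2
  tibble::tibble(
    dy1 = rep(grid1, times = length(grid2)),
    dy2 = rep(grid2, each = length(grid1)),
    joint = as.vector(joint),
    product = as.vector(outer(p1, p2))
  )
}
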