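# Shared model builders and independent oracles used across tests.

two_state <- function(v = c(1, -1), rates = c(1, 1)) {
  vj_model(v, rates, matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
}

three_state_full <- function(v = c(1, -1, 0), rates = c(1, 2, 0.5)) {
  vj_model(v, rates,
           matrix(c(0, 0.5, 0.5,
                    0.5, 0, 0.5,
                    0.5, 0.5, 0), 3, byrow = TRUE))
}

# Random irreducible model: all off-diagonal transition probabilities
# positive, so the chain is strongly connected.
random_model <- function(n, rate_range = c(0.1, 5), v_range = c(-2, 2)) {
  P <- matrix(runif(n * n), n, n)
  diag(P) <- 0
  P <- P / rowSums(P)
  vj_model(runif(n, v_range[1], v_range[2]),
           runif(n, rate_range[1], rate_range[2]), P)
}

# Independent quadrature oracle for P(W = 1 | s1, s2): the defining double
# integral of the joint holding-time density.
one_switch_weight_quadrature <- function(l1, l2, dt) {
  integrate(Vectorize(function(t1) {
    dexp(t1, l1) * pexp(dt - t1, l2, lower.tail = FALSE)
  }), 0, dt, rel.tol = 1e-12)$value
}

two_plus_weight_quadrature <- function(l1, l2, dt) {
  integrate(Vectorize(function(t1) {
    dexp(t1, l1) * pexp(dt - t1, l2)
  }), 0, dt, rel.tol = 1e-12)$value
}

# Exhaustive state-sequence enumeration of the up-to-one-switch joint track
# density: sum over all (N + 1)-long state sequences of
# pi[s1] * prod_j pairwise(dy_j, s_j, s_{j+1}).
enumerate_track_density <- function(increments, model, scheme) {
  n <- model$n
  N <- length(increments)
  pi0 <- stationary_distribution(model)$pi
  seqs <- expand.grid(rep(list(seq_len(n)), N + 1L))
  total <- 0
  for (i in seq_len(nrow(seqs))) {
    s <- as.integer(seqs[i, ])
    p <- pi0[s[1]]
    for (j in seq_len(N)) {
      if (p == 0) break
      p <- p * pairwise_interval_density(increments[j], s[j], s[j + 1L],
                                         model, scheme)
    }
    total <- total + p
  }
  total
}

# Per-bin comparison of an analytic density against a Monte-Carlo histogram
# of `draws`, with the analytic bin mass computed by quadrature. A bin is
# flagged when |observed - expected| mass exceeds 3 binomial s.e.; with ~40
# bins about 0.1 false flags are expected by chance, so consistency allows at
# most 2 flagged bins and no bin beyond 6 s.e. (a genuinely wrong density
# blows many bins, or one bin by far more).
expect_histogram_consistent <- function(draws, density_fun, breaks) {
  emp <- empirical_density(draws, breaks = breaks)
  reps <- length(draws)
  expected <- vapply(seq_len(length(breaks) - 1L), function(k) {
    integrate(density_fun, breaks[k], breaks[k + 1L],
              rel.tol = 1e-9, abs.tol = 1e-12)$value
  }, numeric(1))
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / reps)
  z <- abs(emp$mass - expected) / se
  expect_lte(sum(z > 3), 2)
  expect_lt(max(z), 6)
  invisible(z)
}
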