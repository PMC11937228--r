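test_that("switch-count weights match closed forms and quadrature oracles", {
  expect_equal(no_switch_weight(1, 0.1), exp(-0.1))
  expect_equal(no_switch_weight(10, 0.1), exp(-1))
  expect_equal(no_switch_weight(1, 0), 1)
  expect_error(no_switch_weight(-1, 1), class = "vjump_error_input")

  m_eq <- two_state(rates = c(1, 1))
  m_uneq <- two_state(rates = c(1, 2))
  expect_equal(one_switch_weight(1, 2, m_eq, 1), exp(-1))  # Poisson(1) at 1
  # frozen from the quadrature oracle of the defining double integral
  expect_equal(one_switch_weight(1, 2, m_uneq, 1), 0.2325442,
               tolerance = 1e-6)
  expect_equal(one_switch_weight(1, 2, m_uneq, 1),
               one_switch_weight_quadrature(1, 2, 1), tolerance = 1e-10)
  expect_lt(one_switch_weight(1, 2, m_uneq, 1e-9), 1e-8)

  expect_equal(two_plus_switch_weight(1, 2, m_eq, 1), 1 - 2 * exp(-1))
  expect_equal(two_plus_switch_weight(1, 2, m_uneq, 1), 0.3995764,
               tolerance = 1e-6)
  expect_equal(two_plus_switch_weight(1, 2, m_uneq, 1),
               two_plus_weight_quadrature(1, 2, 1), tolerance = 1e-10)
  expect_error(one_switch_weight(1, 1, m_eq, 1), class = "vjump_error_input")
})

test_that("no-switch + one-switch + two-plus-switch weights partition unity", {
  set.seed(21)
  for (i in 1:100) {
    lam <- runif(2, 0.01, 10)
    dt <- runif(1, 0.01, 5)
    m <- two_state(rates = lam)
    total <- no_switch_weight(lam[1], dt) + one_switch_weight(1, 2, m, dt) +
      two_plus_switch_weight(1, 2, m, dt)
    expect_equal(total, 1, tolerance = 1e-12)
  }
  # near-equal rates go through the limit branch and still partition
  m <- two_state(rates = c(1, 1 + 1e-10))
  expect_equal(no_switch_weight(1, 1) + one_switch_weight(1, 2, m, 1) +
                 two_plus_switch_weight(1, 2, m, 1), 1, tolerance = 1e-10)
})

test_that("zero-switch density is the Gaussian at the state's displacement", {
  m <- two_state()
  sch <- vj_scheme(1, sigma = sqrt(0.005))   # 2 sigma^2 = 0.01
  expect_equal(zero_switch_density(1, 1, m, sch), 1 / sqrt(2 * pi * 0.01),
               tolerance = 1e-6)
  d <- 0.37
  expect_equal(zero_switch_density(1 + d, 1, m, sch),
               zero_switch_density(1 - d, 1, m, sch))
  expect_equal(integrate(function(z) zero_switch_density(z, 1, m, sch),
                         -Inf, Inf)$value, 1, tolerance = 1e-10)
  expect_error(zero_switch_density(0, 1, m, vj_scheme(1, 0)),
               class = "vjump_error_degenerate")
})

test_that("exact one-switch density is the truncated-exponential change of variables", {
  m_eq <- two_state(rates = c(1, 1))
  # equal rates: switching time uniform, density constant 1/(|v1-v2| dt)
  grid <- seq(-0.99, 0.99, length.out = 21)
  expect_equal(one_switch_exact_density(grid, 1, 2, m_eq, 1),
               rep(0.5, 21))
  expect_equal(one_switch_exact_density(c(-1.01, 1.01), 1, 2, m_eq, 1),
               c(0, 0))
  m <- two_state(rates = c(1, 3))
  expect_equal(integrate(function(u) one_switch_exact_density(u, 1, 2, m, 1),
                         -1, 1, rel.tol = 1e-12)$value, 1,
               tolerance = 1e-10)
  tie <- vj_model(c(1, 1), c(1, 2), matrix(c(0, 1, 1, 0), 2))
  expect_error(one_switch_exact_density(0, 1, 2, tie, 1),
               class = "vjump_error_degenerate")
})

test_that("one-switch exact density matches the rejection-sampling oracle", {
  m <- two_state(rates = c(1, 3))
  draws <- conditional_increment_oracle(m, 1, c(1L, 2L), reps = 1e5,
                                        seed = 22)
  expect_histogram_consistent(
    draws, function(u) one_switch_exact_density(u, 1, 2, m, 1),
    breaks = seq(-1, 1, length.out = 41))
})

test_that("one-switch noisy closed form equals adaptive quadrature of the convolution", {
  cases <- list(
    list(m = two_state(rates = c(1, 1)), sigma = 0.1),
    list(m = two_state(rates = c(1, 3)), sigma = 0.05),
    list(m = two_state(v = c(0.3, 1.7), rates = c(4, 0.2)), sigma = 0.2)
  )
  for (cs in cases) {
    sch <- vj_scheme(1, cs$sigma)
    v <- cs$m$velocities
    a <- min(v); b <- max(v)
    grid <- seq(a - 4 * cs$sigma * sqrt(2), b + 4 * cs$sigma * sqrt(2),
                length.out = 101)
    cf <- one_switch_noisy_density(grid, 1, 2, cs$m, sch)
    qd <- one_switch_noisy_density(grid, 1, 2, cs$m, sch,
                                   method = "quadrature")
    expect_lt(max(abs(cf - qd)), 1e-8)
    expect_equal(attr(cf, "branch"), "closed_form")
    expect_equal(
      integrate(function(z) one_switch_noisy_density(z, 1, 2, cs$m, sch),
                -Inf, Inf)$value, 1, tolerance = 1e-8)
  }
})

test_that("one-switch noisy density handles ties and the small-noise limit", {
  tie <- vj_model(c(1, 1), c(1, 2), matrix(c(0, 1, 1, 0), 2))
  sch <- vj_scheme(1, 0.1)
  grid <- seq(0.5, 1.5, length.out = 11)
  expect_equal(as.numeric(one_switch_noisy_density(grid, 1, 2, tie, sch)),
               zero_switch_density(grid, 1, tie, sch))

  m <- two_state(rates = c(1, 3))
  span <- 2                      # b - a for v = (1, -1), dt = 1
  sch_small <- vj_scheme(1, 1e-4 * span)
  mid <- 0
  expect_equal(as.numeric(one_switch_noisy_density(mid, 1, 2, m, sch_small)),
               one_switch_exact_density(mid, 1, 2, m, 1),
               tolerance = 1e-3)
})

test_that("two-switch exact density has the right support and normalization", {
  m <- three_state_full(v = c(1, 0, -1), rates = c(1, 2, 0.5))
  expect_equal(two_switch_exact_density(c(-1.01, 1.01), 1, 2, 3, m, 1),
               c(0, 0), ignore_attr = TRUE)
  combos <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(1, 2, 1), c(3, 2, 3))
  for (s in combos) {
    nn <- integrate(function(u) {
      two_switch_exact_density(u, s[1], s[2], s[3], m, 1)
    }, -1, 1, rel.tol = 1e-10, subdivisions = 400)$value
    expect_equal(nn, 1, tolerance = 1e-8)
  }
  expect_error(two_switch_exact_density(0, 1, 1, 2, m, 1),
               class = "vjump_error_input")
  all_tied <- vj_model(c(1, 1, 1), c(1, 2, 3),
                       matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3,
                              byrow = TRUE))
  expect_error(two_switch_exact_density(0, 1, 2, 3, all_tied, 1),
               class = "vjump_error_degenerate")
})

test_that("two-switch exact density matches the sifting-form quadrature oracle", {
  m <- three_state_full(v = c(1, 0, -1), rates = c(1, 2, 0.5))
  dt <- 1
  oracle <- function(dx, s) {
    l <- m$rates[s]; v <- m$velocities[s]
    z <- integrate(Vectorize(function(t1) {
      exp(-(l[1] - l[3]) * t1) *
        integrate(function(t2) exp(-(l[2] - l[3]) * t2), 0, dt - t1)$value
    }), 0, dt, rel.tol = 1e-12)$value
    vapply(dx, function(x) {
      integrate(Vectorize(function(t1) {
        t2 <- ((v[1] - v[3]) * t1 + v[3] * dt - x) / (v[3] - v[2])
        ifelse(t2 >= 0 & t2 <= dt - t1,
               exp(-(l[1] - l[3]) * t1 - (l[2] - l[3]) * t2), 0) /
          abs(v[3] - v[2]) / z
      }), 0, dt, rel.tol = 1e-10, subdivisions = 400)$value
    }, numeric(1))
  }
  xs <- seq(-0.9, 0.9, length.out = 13)
  expect_equal(
    as.numeric(two_switch_exact_density(xs, 1, 2, 3, m, dt)),
    oracle(xs, c(1, 2, 3)), tolerance = 1e-8)
  expect_equal(
    as.numeric(two_switch_exact_density(xs, 2, 1, 3, m, dt)),
    oracle(xs, c(2, 1, 3)), tolerance = 1e-8)
})

test_that("two-switch exact density matches the rejection oracle, incl. s3 = s1", {
  cases <- list(
    list(m = three_state_full(v = c(1, 0, -1), rates = c(1, 1, 1)),
         s = c(1L, 2L, 3L)),                                   # equal rates
    list(m = three_state_full(v = c(1, 0, -1), rates = c(1, 2, 0.5)),
         s = c(1L, 2L, 3L)),                                   # unequal rates
    list(m = two_state(rates = c(1, 3)), s = c(1L, 2L, 1L))    # s3 = s1
  )
  for (cs in cases) {
    draws <- conditional_increment_oracle(cs$m, 1, cs$s, reps = 1e5,
                                          seed = 23)
    expect_histogram_consistent(
      draws,
      function(u) two_switch_exact_density(u, cs$s[1], cs$s[2], cs$s[3],
                                           cs$m, 1),
      breaks = seq(-1, 1, length.out = 41))
  }
})

test_that("two-switch noisy density equals the defining double-integral quadrature", {
  m <- three_state_full(v = c(1, 0, -1), rates = c(1, 2, 0.5))
  sch <- vj_scheme(1, 0.08)
  s <- sqrt(2) * sch$sigma
  # independent oracle: integrate the joint switching-time density times the
  # Gaussian noise kernel over the triangle
  oracle <- function(dy) {
    l <- m$rates; v <- m$velocities
    z <- integrate(Vectorize(function(t1) {
      exp(-(l[1] - l[3]) * t1) *
        integrate(function(t2) exp(-(l[2] - l[3]) * t2), 0, 1 - t1)$value
    }), 0, 1, rel.tol = 1e-12)$value
    vapply(dy, function(y) {
      integrate(Vectorize(function(t1) {
        integrate(function(t2) {
          dx <- v[1] * t1 + v[2] * t2 + v[3] * (1 - t1 - t2)
          exp(-(l[1] - l[3]) * t1 - (l[2] - l[3]) * t2) / z *
            dnorm(y - dx, sd = s)
        }, 0, 1 - t1, rel.tol = 1e-10)$value
      }), 0, 1, rel.tol = 1e-9, subdivisions = 400)$value
    }, numeric(1))
  }
  ys <- seq(-1.1, 1.1, length.out = 9)
  expect_lt(max(abs(as.numeric(two_switch_noisy_density(ys, 1, 2, 3, m, sch)) -
                      oracle(ys))), 1e-6)
  expect_equal(
    integrate(function(z) two_switch_noisy_density(z, 1, 2, 3, m, sch),
              -2, 2, subdivisions = 400)$value, 1, tolerance = 1e-6)
})

test_that("two-switch noisy density tends to a Gaussian when noise dominates", {
  m <- three_state_full(v = c(1, 0, -1), rates = c(1, 2, 0.5))
  span <- 2
  sigma <- 100 * span
  sch <- vj_scheme(1, sigma)
  mu <- integrate(function(u) u * two_switch_exact_density(u, 1, 2, 3, m, 1),
                  -1, 1, subdivisions = 400)$value
  ys <- seq(-2 * sigma, 2 * sigma, length.out = 21)
  ref <- dnorm(ys, mean = mu, sd = sqrt(2) * sigma)
  expect_lt(max(abs(as.numeric(two_switch_noisy_density(ys, 1, 2, 3, m, sch)) -
                      ref)), 1e-3)
})

test_that("marginal densities normalize, are symmetric when the model is, and nest", {
  net <- example_network("three_state")
  m <- net$model
  sch <- vj_scheme(1, 0.05)
  for (ord in 1:2) {
    nn <- integrate(function(z) marginal_density(z, m, sch, ord),
                    -1.5, 1.5, subdivisions = 500)$value
    expect_equal(nn, 1, tolerance = 1e-6)
  }
  # symmetric two-state model: even density
  ms <- two_state(rates = c(0.5, 0.5))
  g <- seq(0.05, 1.4, length.out = 15)
  for (ord in 1:2) {
    expect_equal(marginal_density(g, ms, sch, ord),
                 marginal_density(-g, ms, sch, ord), tolerance = 1e-12)
  }
  # order 2 with the two-switch weight folded back reproduces order 1
  g2 <- seq(-1.3, 1.3, length.out = 31)
  expect_equal(marginal_density(g2, m, sch, 2, collapse_two_switch = TRUE),
               marginal_density(g2, m, sch, 1), tolerance = 1e-14)
  expect_error(marginal_density(0, m, sch, order = 3),
               class = "vjump_error_input")
})

test_that("the order-1 marginal tends to the switch-free Gaussian mixture at low rates", {
  m <- three_state_full(rates = c(1e-4, 1e-4, 1e-4))
  sch <- vj_scheme(1, 0.25)   # O(1) peak heights, so 1e-4 is an O(lambda dt) bound
  g <- seq(-1.3, 1.3, length.out = 61)
  pi0 <- stationary_distribution(m)$pi
  mixture <- rowSums(vapply(1:3, function(s) {
    pi0[s] * dnorm(g, m$velocities[s], sqrt(2) * sch$sigma)
  }, numeric(length(g))))
  expect_lt(max(abs(marginal_density(g, m, sch, 1) - mixture)), 1e-4)
})

test_that("density profiles are tidy and plottable", {
  net <- example_network("two_state")
  prof <- density_profile(net$model, net$scheme, orders = 1:2)
  expect_s3_class(prof, "vj_density_profile")
  expect_named(prof, c("dy", "order", "density"))
  expect_true(all(prof$density >= 0))
  p <- autoplot(prof)
  expect_s3_class(p, "ggplot")
})
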