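#' Maximum-likelihood fitting of a velocity-jump model to noisy tracks
#'
#' Maximizes the forward-filter log density summed over tracks by bounded-free
#' numerical optimization in a transformed parameter space: raw velocities,
#' log switching rates, optionally log measurement noise, and (for rows of
#' the transition topology with three or more successors) multinomial-logit
#' free entries. The topology (pattern of allowed transitions) is taken from
#' `model` and is not itself estimated. Multiple restarts with perturbed
#' starting points guard against local optima across state relabelings;
#' reported states are sorted by fitted velocity.
#'
#' @param tracks Tibble with columns `track_id`, `frame`, `y`.
#' @param model A validated `vj_model` providing the topology and the
#'   starting values for velocities, rates and transition probabilities.
#' @param scheme A `vj_scheme`; its `sigma` is the starting value when
#'   `fit_sigma = TRUE`, otherwise it is held fixed.
#' @param fit_sigma Estimate the measurement noise s.d.? Default `TRUE`.
#' @param fit_velocities Estimate the velocities? With `FALSE` they are held
#'   at the values in `model`.
#' @param fit_transitions Estimate free transition probabilities (only
#'   meaningful when some row has three or more successors)? Default `FALSE`.
#' @param restarts Number of optimizer restarts (the first starts at the
#'   supplied values, the rest at perturbed points).
#' @param seed Optional integer seed controlling the restart perturbations.
#' @param control Passed to [stats::optim()] (Nelder-Mead), after defaults.
#' @return An object of class `vj_fit`: list with `model` (fitted
#'   `vj_model`), `sigma`, `scheme`, `log_lik`, `convergence`,
#'   `n_increments`, `restarts` and the per-restart log-likelihoods.
#' @export
fit_mle <- function(tracks, model, scheme, fit_sigma = TRUE,
                    fit_velocities = TRUE, fit_transitions = FALSE,
                    restarts = 5L, seed = NULL, control = list()) {
  inc_list <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(inc = list(diff(.data$y)), .groups = "drop") |>
    dplyr::pull(.data$inc)
  if (length(inc_list) == 0) {
    stop_vjump("need at least one track", "vjump_error_input")
  }
  n <- model$n
  topo <- model$transition_probs > 0
  free_rows <- if (fit_transitions) which(rowSums(topo) >= 2L) else integer(0)

  nv <- if (fit_velocities) n else 0L
  pack <- function(v, lam, P, sigma) {
    th <- c(if (fit_velocities) v, log(lam))
    for (s in free_rows) {
      p <- P[s, topo[s, ]]
      th <- c(th, log(p[-1] / p[1]))
    }
    if (fit_sigma) th <- c(th, log(sigma))
    th
  }
  unpack <- function(th) {
    v <- if (fit_velocities) th[seq_len(n)] else model$velocities
    lam <- exp(th[nv + seq_len(n)])
    k <- nv + n
    P <- model$transition_probs
    for (s in free_rows) {
      idx <- which(topo[s, ])
      nfree <- length(idx) - 1L
      logit <- th[k + seq_len(nfree)]
      k <- k + nfree
      w <- c(1, exp(logit))
      P[s, ] <- 0
      P[s, idx] <- w / sum(w)
    }
    sigma <- if (fit_sigma) exp(th[k + 1L]) else scheme$sigma
    list(v = v, lam = lam, P = P, sigma = sigma)
  }

  negll <- function(th) {
    par <- unpack(th)
    if (any(!is.finite(par$lam)) || par$sigma <= 0 ||
        any(par$lam <= 0) || any(par$lam > 1e6)) {
      return(1e10)
    }
    mod <- structure(list(n = n, velocities = par$v, rates = par$lam,
                          transition_probs = par$P,
                          state_names = model$state_names),
                     class = "vj_model")
    sch <- vj_scheme(scheme$dt, par$sigma,
                     n_increments = scheme$n_increments)
    val <- tryCatch(
      -sum(vapply(inc_list, function(z) forward_filter(z, mod, sch)$log_lik,
                  numeric(1))),
      error = function(e) 1e10
    )
    if (!is.finite(val)) 1e10 else val
  }

  th0 <- pack(model$velocities, model$rates, model$transition_probs,
              scheme$sigma)
  control <- modifyList(list(maxit = 2000L, reltol = 1e-10), control)
  fits <- with_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      start <- if (r == 1L) th0 else th0 + rnorm(length(th0), sd = 0.3)
      optim(start, negll, method = "Nelder-Mead", control = control)
    })
  })
  values <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(values)]]
  par <- unpack(best$par)
  # canonical state ordering: sort by fitted velocity
  ord <- order(par$v)
  fitted_model <- vj_model(par$v[ord], par$lam[ord],
                           par$P[ord, ord, drop = FALSE],
                           model$state_names[ord])
  structure(
    list(
      model = fitted_model,
      sigma = par$sigma,
      scheme = vj_scheme(scheme$dt, par$sigma, scheme$n_increments),
      log_lik = -best$value,
      convergence = best$convergence,
      hit_bound = any(par$lam > 1e5),
      n_tracks = length(inc_list),
      n_increments = sum(lengths(inc_list)),
      restarts = restarts,
      restart_loglik = -values
    ),
    class = "vj_fit"
  )
}

#' @export
print.vj_fit <- function(x, ...) {
  cat(sprintf("<vj_fit> %d tracks, %d increments, log-likelihood %.3f\n",
              x$n_tracks, x$n_increments, x$log_lik))
  if (x$convergence != 0) cat("  warning: optimizer did not report convergence\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy parameter estimates from a fit
#'
#' @param x A `vj_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (velocities and rates
#'   per state, plus `sigma`).
#' @export
tidy.vj_fit <- function(x, ...) {
  m <- x$model
  tibble::tibble(
    term = c(paste0("v[", m$state_names, "]"),
             paste0("lambda[", m$state_names, "]"), "sigma"),
    estimate = c(m$velocities, m$rates, x$sigma)
  )
}

#' One-row fit summary
#'
#' @param x A `vj_fit`.
#' @param ... Unused.
#' @return A tibble with `log_lik`, `convergence`, `n_tracks`,
#'   `n_increments`, `restarts`.
#' @export
glance.vj_fit <- function(x, ...) {
  tibble::tibble(
    log_lik = x$log_lik,
    convergence = x$convergence,
    n_tracks = x$n_tracks,
    n_increments = x$n_increments,
    restarts = x$restarts
  )
}
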