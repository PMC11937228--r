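#' Define an n-state velocity-jump model
#'
#' A velocity-jump model describes an agent that moves at a constant,
#' state-specific velocity and switches state according to a continuous-time
#' Markov chain (CTMC): the holding time in state `s` is exponential with rate
#' `lambda_s`, and on leaving `s` the next state is drawn from row `s` of the
#' embedded transition matrix `P` (zero diagonal, rows summing to one).
#'
#' @param velocities Numeric vector of per-state velocities (length/time).
#' @param rates Numeric vector of positive switching rates `lambda_s` (1/time).
#' @param transition_probs `n x n` matrix of embedded transition probabilities
#'   `p_su` with zero diagonal and unit row sums.
#' @param state_names Optional character vector of state labels (defaults to
#'   `S1, S2, ...`).
#'
#' @return A validated object of class `vj_model` with elements `n`,
#'   `velocities`, `rates`, `transition_probs`, `state_names`.
#' @examples
#' m <- vj_model(velocities = c(1, -1), rates = c(0.2, 0.2),
#'               transition_probs = matrix(c(0, 1, 1, 0), 2, byrow = TRUE),
#'               state_names = c("F", "B"))
#' stationary_distribution(m)
#' @export
vj_model <- function(velocities, rates, transition_probs,
                     state_names = NULL) {
  n <- length(velocities)
  if (is.null(state_names)) state_names <- paste0("S", seq_len(n))
  P <- as.matrix(transition_probs)
  if (all(dim(P) == c(n, n))) dimnames(P) <- list(state_names, state_names)
  model <- structure(
    list(
      n = n,
      velocities = as.numeric(velocities),
      rates = as.numeric(rates),
      transition_probs = P,
      state_names = as.character(state_names)
    ),
    class = "vj_model"
  )
  validate_model(model)
}

#' @export
print.vj_model <- function(x, ...) {
  cat(sprintf("<vj_model> %d states\n", x$n))
  print(tidy(x))
  invisible(x)
}

#' Tidy summary of a velocity-jump model
#'
#' @param x A `vj_model`.
#' @param ... Unused.
#' @return A tibble with one row per state: name, velocity, switching rate,
#'   mean holding time and stationary probability.
#' @export
tidy.vj_model <- function(x, ...) {
  tibble::tibble(
    state = x$state_names,
    velocity = x$velocities,
    rate = x$rates,
    mean_holding = 1 / x$rates,
    stationary_prob = stationary_distribution(x)$pi
  )
}

#' Validate a velocity-jump model
#'
#' Checks every structural invariant of the model: matching dimensions,
#' strictly positive rates, a zero diagonal and stochastic rows in the
#' embedded transition matrix, probabilities in `[0, 1]`, and irreducibility
#' (strong connectivity of the directed graph of positive transition
#' probabilities).
#'
#' @param model A `vj_model` (or a bare list with the same fields).
#' @return The validated model, invisibly classed as `vj_model`.
#' @export
validate_model <- function(model) {
  n <- model$n
  P <- model$transition_probs
  if (length(model$velocities) != n || length(model$rates) != n ||
      !all(dim(P) == c(n, n)) || length(model$state_names) != n) {
    stop_vjump("model fields have mismatched dimensions",
               "vjump_error_dimension")
  }
  if (!all(is.finite(model$velocities))) {
    stop_vjump("velocities must be finite", "vjump_error_dimension")
  }
  if (any(!is.finite(model$rates)) || any(model$rates <= 0)) {
    stop_vjump("every switching rate must be a positive finite number",
               "vjump_error_rate")
  }
  if (any(diag(P) != 0)) {
    stop_vjump("embedded transition matrix must have a zero diagonal",
               "vjump_error_diagonal")
  }
  if (any(P < 0) || any(P > 1)) {
    stop_vjump("transition probabilities must lie in [0, 1]",
               "vjump_error_stochastic")
  }
  bad <- which(abs(rowSums(P) - 1) > 1e-12)
  if (length(bad) > 0) {
    stop_vjump(
      sprintf("non-stochastic row(s) in transition matrix: %s",
              paste(model$state_names[bad], collapse = ", ")),
      "vjump_error_stochastic"
    )
  }
  # Irreducibility: strong connectivity of {p_su > 0}, exact zero threshold.
  g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
  if (igraph::count_components(g, mode = "strong") != 1L) {
    stop_vjump("reducible chain: transition graph is not strongly connected",
               "vjump_error_reducible")
  }
  invisible(structure(model, class = "vj_model"))
}

#' Transition-rate (generator) matrix of the CTMC
#'
#' Off-diagonal entries are `q_su = lambda_s * p_su`; diagonal entries are
#' `-lambda_s`, so every row sums to zero.
#'
#' @param model A validated `vj_model`.
#' @return An `n x n` numeric matrix with state names on both dimensions.
#' @export
rate_matrix <- function(model) {
  q <- model$rates * model$transition_probs
  diag(q) <- -model$rates
  dimnames(q) <- list(model$state_names, model$state_names)
  q
}

#' Stationary distribution of the CTMC
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by taking the null space of `t(Q)` from a
#' singular-value decomposition. The kernel must be one-dimensional (it is,
#' for an irreducible chain); a second near-zero singular value triggers a
#' "degenerate kernel" error.
#'
#' @param model A validated `vj_model`.
#' @return A tibble with columns `state` and `pi`.
#' @export
stationary_distribution <- function(model) {
  q <- rate_matrix(model)
  sv <- svd(t(q))
  d <- sv$d
  scale <- max(d)
  if (model$n > 1 && d[model$n - 1] < 1e-8 * scale) {
    stop_vjump("degenerate kernel: stationary distribution is not unique",
               "vjump_error_degenerate_kernel")
  }
  v <- sv$v[, model$n]
  v <- v / sum(v)
  if (any(v < -1e-12)) {
    stop_vjump("stationary solve produced negative probabilities",
               "vjump_error_degenerate_kernel")
  }
  v <- pmax(v, 0)
  v <- v / sum(v)
  tibble::tibble(state = model$state_names, pi = v)
}

# Bare numeric stationary vector, used internally.
stationary_vector <- function(model) stationary_distribution(model)$pi
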