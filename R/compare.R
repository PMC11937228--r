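# Comparison of analytic approximations with Monte-Carlo empirical densities:
# the machinery behind accuracy assessments of the up-to-m-switch marginals
# and of the joint two-increment surface versus the independence baseline.

#' Compare marginal approximations with an empirical density
#'
#' Simulates noisy increments (consecutive increments of long tracks by
#' default, or independent stationary intervals), bins them with
#' [density_breaks()], evaluates the requested up-to-m-switch approximations
#' at the bin midpoints, and reports L1 and sup-norm error for each order.
#'
#' @param model A validated `vj_model`.
#' @param scheme A `vj_scheme` with `sigma > 0`.
#' @param reps Number of simulated increments.
#' @param orders Approximation orders to evaluate (subset of `c(1, 2)`).
#' @param mode `"stationary"` for independent single intervals,
#'   `"tracks"` for consecutive increments of long tracks (same marginal
#'   law).
#' @param seed Optional integer seed.
#' @param n_bins Histogram bins.
#' @return A list with `grid` (tibble: `dy`, `empirical`, one column per
#'   order) and `errors` (tibble: `order`, `l1`, `sup`).
#' @export
compare_marginal <- function(model, scheme, reps, orders = 1,
                             mode = c("stationary", "tracks"), seed = NULL,
                             n_bins = 200L) {
  mode <- match.arg(mode)
  dy <- simulate_increments(model, scheme, reps, mode, seed)
  breaks <- density_breaks(model, scheme, n_bins)
  emp <- empirical_density(dy, breaks = breaks)
  widths <- diff(breaks)
  grid <- tibble::tibble(dy = emp$mid, empirical = emp$density)
  errors <- purrr::map_dfr(orders, function(ord) {
    approx <- marginal_density(emp$mid, model, scheme, order = ord)
    grid[[paste0("p", ord)]] <<- approx
    tibble::tibble(
      order = as.integer(ord),
      l1 = sum(abs(approx - emp$density) * widths),
      sup = max(abs(approx - emp$density))
    )
  })
  list(grid = grid, errors = errors, reps = reps, mode = mode)
}

# Noisy increments either as iid stationary intervals or as consecutive
# increments of long simulated tracks (chunked for memory).
simulate_increments <- function(model, scheme, reps,
                                mode = c("stationary", "tracks"),
                                seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "stationary") {
    return(draw_stationary_increments(model, scheme, reps, seed)$dy)
  }
  with_seed(seed, {
    per_track <- min(reps, 10000L)
    n_tracks <- ceiling(reps / per_track)
    sch <- vj_scheme(scheme$dt, scheme$sigma, per_track)
    unlist(lapply(seq_len(n_tracks), function(i) {
      path <- sample_state_path(model, sch$total_time)
      diff(observe_track(path, sch, model$velocities)$y)
    }))[seq_len(reps)]
  })
}

#' Compare the joint two-increment approximation with its baselines
#'
#' Simulates pairs of subsequent noisy increments from long tracks, bins them
#' in 2-D, and compares the up-to-one-switch joint approximation and the
#' naive independent product against the empirical density in L1 norm.
#'
#' @inheritParams compare_marginal
#' @param n_bins Bins per axis.
#' @return A list with `errors` (tibble: `method`, `l1`) and `reps`.
#' @export
compare_joint <- function(model, scheme, reps, seed = NULL, n_bins = 60L) {
  pairs <- with_seed(seed, {
    per_track <- min(reps + 1L, 10001L)
    n_tracks <- ceiling((reps + 1L) / (per_track - 1L))
    sch <- vj_scheme(scheme$dt, scheme$sigma, per_track - 1L)
    res <- lapply(seq_len(n_tracks), function(i) {
      path <- sample_state_path(model, sch$total_time)
      dy <- diff(observe_track(path, sch, model$velocities)$y)
      cbind(dy[-length(dy)], dy[-1])
    })
    do.call(rbind, res)
  })
  pairs <- pairs[seq_len(min(nrow(pairs), reps)), , drop = FALSE]
  breaks <- density_breaks(model, scheme, n_bins)
  emp <- empirical_density2(pairs[, 1], pairs[, 2],
                            breaks_x = breaks, breaks_y = breaks)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  surf <- joint_pair_density(mids, mids, model, scheme)
  cell <- mean(diff(breaks))^2
  errors <- tibble::tibble(
    method = c("joint", "product"),
    l1 = c(sum(abs(surf$joint - emp$density) * cell),
           sum(abs(surf$product - emp$density) * cell))
  )
  list(errors = errors, grid = dplyr::mutate(surf, empirical = emp$density),
       reps = nrow(pairs))
}
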