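#' Define a data-collection (observation) scheme
#'
#' Locations are recorded every `dt` time units with additive Gaussian
#' measurement noise of standard deviation `sigma`; a track of `n_increments`
#' increments has `n_increments + 1` recorded locations. A noisy increment
#' `dy_j = y_j - y_{j-1}` has conditional law `Normal(dx_j, 2 sigma^2)`
#' because the two endpoint errors are independent.
#'
#' @param dt Positive frame interval (time).
#' @param sigma Non-negative measurement-noise standard deviation (length).
#' @param n_increments Positive integer number of increments per track.
#' @return An object of class `vj_scheme`.
#' @export
vj_scheme <- function(dt, sigma, n_increments = 1L) {
  if (!is_scalar_number(dt) || dt <= 0) {
    stop_vjump("dt must be a positive number", "vjump_error_scheme")
  }
  if (!is_scalar_number(sigma) || sigma < 0) {
    stop_vjump("sigma must be non-negative", "vjump_error_scheme")
  }
  n_increments <- as.integer(n_increments)
  if (is.na(n_increments) || n_increments < 1L) {
    stop_vjump("n_increments must be a positive integer", "vjump_error_scheme")
  }
  structure(
    list(dt = dt, sigma = sigma, n_increments = n_increments,
         total_time = n_increments * dt),
    class = "vj_scheme"
  )
}

#' @export
print.vj_scheme <- function(x, ...) {
  cat(sprintf("<vj_scheme> dt = %g, sigma = %g, N = %d (T = %g)\n",
              x$dt, x$sigma, x$n_increments, x$total_time))
  invisible(x)
}
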