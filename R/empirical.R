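#' Default histogram breaks for increment densities
#'
#' 200 uniform bins spanning all Gaussian peaks of the approximations:
#' `[min(v) * dt - 5 * sigma * sqrt(2), max(v) * dt + 5 * sigma * sqrt(2)]`.
#'
#' @param model A `vj_model`.
#' @param scheme A `vj_scheme`.
#' @param n_bins Number of bins.
#' @return Numeric vector of `n_bins + 1` break points.
#' @export
density_breaks <- function(model, scheme, n_bins = 200L) {
  pad <- 5 * scheme$sigma * sqrt(2)
  lo <- min(model$velocities) * scheme$dt - pad
  hi <- max(model$velocities) * scheme$dt + pad
  if (hi <= lo) { # all velocities equal and sigma = 0
    lo <- lo - 0.5
    hi <- hi + 0.5
  }
  seq(lo, hi, length.out = n_bins + 1L)
}

#' Binned empirical density estimate (1-D)
#'
#' Histogram normalized so the bin masses sum to one; the density in each bin
#' is its mass divided by the bin width. Samples outside the break range are
#' dropped (their count is reported in the `"n_dropped"` attribute).
#'
#' @param samples Numeric vector of observations (at least one).
#' @param breaks Numeric vector of bin edges; defaults to 200 uniform bins
#'   over the sample range.
#' @param n_bins Number of bins when `breaks` is not supplied.
#' @return A tibble with columns `mid`, `density`, `mass`; bin edges are in
#'   the `"breaks"` attribute.
#' @export
empirical_density <- function(samples, breaks = NULL, n_bins = 200L) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) {
    stop_vjump("empty sample", "vjump_error_input")
  }
  if (is.null(breaks)) {
    rng <- range(samples)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  idx <- findInterval(samples, breaks, rightmost.closed = TRUE)
  inside <- idx >= 1L & idx <= length(breaks) - 1L
  counts <- tabulate(idx[inside], nbins = length(breaks) - 1L)
  mass <- counts / sum(counts)
  widths <- diff(breaks)
  out <- tibble::tibble(
    mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    density = mass / widths,
    mass = mass
  )
  attr(out, "breaks") <- breaks
  attr(out, "n_dropped") <- sum(!inside)
  out
}

#' Binned empirical density estimate (2-D)
#'
#' Two-dimensional analogue of [empirical_density()] for pairs such as two
#' subsequent noisy increments.
#'
#' @param x,y Paired numeric vectors.
#' @param breaks_x,breaks_y Bin edges for each axis.
#' @param n_bins Bins per axis when edges are not supplied.
#' @return A tibble with columns `mid_x`, `mid_y`, `density`, `mass`.
#' @export
empirical_density2 <- function(x, y, breaks_x = NULL, breaks_y = NULL,
                               n_bins = 100L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop_vjump("empty sample", "vjump_error_input")
  mk <- function(z) {
    rng <- range(z)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  if (is.null(breaks_x)) breaks_x <- mk(x)
  if (is.null(breaks_y)) breaks_y <- mk(y)
  ix <- findInterval(x, breaks_x, rightmost.closed = TRUE)
  iy <- findInterval(y, breaks_y, rightmost.closed = TRUE)
  nx <- length(breaks_x) - 1L
  ny <- length(breaks_y) - 1L
  inside <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  counts <- matrix(tabulate((iy[inside] - 1L) * nx + ix[inside],
                            nbins = nx * ny), nrow = nx)
  mass <- counts / sum(counts)
  wx <- diff(breaks_x)
  wy <- diff(breaks_y)
  area <- outer(wx, wy)
  midx <- (breaks_x[-1] + breaks_x[-length(breaks_x)]) / 2
  midy <- (breaks_y[-1] + breaks_y[-length(breaks_y)]) / 2
  out <- tibble::tibble(
    mid_x = rep(midx, times = ny),
    mid_y = rep(midy, each = nx),
    density = as.vector(mass / area),
    mass = as.vector(mass)
  )
  attr(out, "breaks_x") <- breaks_x
  attr(out, "breaks_y") <- breaks_y
  attr(out, "n_dropped") <- sum(!inside)
  out
}
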