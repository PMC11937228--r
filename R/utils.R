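# Internal numerical helpers.

# P(lo < Z < hi) for standard normal, stable in both tails.
pnorm_diff <- function(lo, hi) {
  # When both endpoints are in the far upper tail, work on the survival side.
  upper <- (lo + hi) > 0
  out <- numeric(length(lo))
  out[upper] <- pnorm(lo[upper], lower.tail = FALSE) -
    pnorm(hi[upper], lower.tail = FALSE)
  out[!upper] <- pnorm(hi[!upper]) - pnorm(lo[!upper])
  pmax(out, 0)
}

# Run an expression with a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Numerically stable (1 - exp(-x)) / x with the x -> 0 limit.
expm1_ratio <- function(x) {
  out <- ifelse(abs(x) < 1e-8, 1 - x / 2, -expm1(-x) / x)
  out
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_vjump <- function(msg, class) {
  abort(msg, class = c(class, "vjump_error"))
}
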