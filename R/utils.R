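## Internal numerical helpers shared across modules.

## Linear (zero-padded) autocovariance sums via FFT:
## returns S[l+1] = sum_{t=1}^{n-l} x[t] * x[t+l], l = 0..n-1.
acf_sums_fft <- function(x) {
  n <- length(x)
  m <- stats::nextn(2L * n, 2L)
  fx <- stats::fft(c(x, rep(0, m - n)))
  s <- Re(stats::fft(fx * Conj(fx), inverse = TRUE)) / m
  s[seq_len(n)]
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## row-wise Euclidean norms of an n x 3 matrix
row_norms <- function(x) sqrt(rowSums(x * x))

## mass-weighted centre of mass of coordinates x (n x 3)
centre_of_mass <- function(x, mass) {
  m <- sum(mass)
  if (m <= 0) stop("total mass must be positive", call. = FALSE)
  colSums(x * mass) / m
}

## clamp into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_uniform_times <- function(times, tol = 1e-6) {
  if (length(times) < 2L) return(TRUE)
  dt <- diff(times)
  all(abs(dt - dt[1]) <= tol * max(abs(dt[1]), 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
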