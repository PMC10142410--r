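# Independent oracles for the coupling solve and the agreement statistics.
# These recompute everything from the model definitions in a second code
# path; they never call the package's solver internals.

# Coupling residual written directly from the model equations.
oracle_residual <- function(x, pad, pes, et, pep) {
  (pad / pes) * (1 + 0.53 * x^0.51 * (et / pep)) - 1 - x
}

# Bracketed bisection for the physiological coupling root: scan (lo, hi) on a
# log grid, take the LAST +/- sign change (the decreasing-branch root), and
# bisect it down. Returns NA when the residual never becomes positive.
oracle_bisect <- function(pad, pes, et, pep, lo = 1e-6, hi = 100) {
  grid <- exp(seq(log(lo), log(hi), length.out = 500))
  fg <- oracle_residual(grid, pad, pes, et, pep)
  idx <- which(fg[-length(fg)] > 0 & fg[-1] <= 0)
  if (length(idx) == 0) return(NA_real_)
  a <- grid[max(idx)]
  b <- grid[max(idx) + 1]
  for (i in 1:200) {
    m <- (a + b) / 2
    if (oracle_residual(m, pad, pes, et, pep) > 0) a <- m else b <- m
    if ((b - a) < 1e-14 * m) break
  }
  (a + b) / 2
}

# Random admissible solver inputs: pad in [50, 100] mmHg, pes in [pad, 130]
# mmHg, ET/PEP in [1, 6] (PEP fixed at 100 ms so the ratio is the draw).
random_admissible_inputs <- function(n) {
  pad <- stats::runif(n, 50, 100)
  pes <- stats::runif(n, pad, 130)
  ratio <- stats::runif(n, 1, 6)
  data.frame(pad = pad, pes = pes, et = ratio * 100, pep = 100)
}

# Agreement statistics recomputed from first principles (explicit sums).
oracle_agreement <- function(reference, test, m = 2) {
  n <- length(reference)
  d <- reference - test
  bias <- sum(d) / n
  sd_diff <- sqrt(sum((d - bias)^2) / (n - 1))
  mean_ref <- sum(reference) / n
  sxx <- sum((reference - mean_ref)^2)
  sxy <- sum((reference - mean_ref) * (test - sum(test) / n))
  slope <- sxy / sxx
  intercept <- sum(test) / n - slope * mean_ref
  r2 <- sxy^2 / (sxx * sum((test - sum(test) / n)^2))
  list(
    bias = bias, sd_diff = sd_diff,
    loa_lower = bias - m * sd_diff, loa_upper = bias + m * sd_diff,
    percentage_error = 100 * m * sd_diff / mean_ref,
    slope = slope, intercept = intercept, r_squared = r2
  )
}
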