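# Independent oracles used across the suite.  These are deliberately
# written as plain, direct transcriptions of the definitions, separate from
# the package's implementations.

# Brute-force normalized delayed correlation: C_SZ(tau)/sqrt(C_SS * C_ZZ)
# with full-series means/variances and lagged products over the overlap.
bf_ccf <- function(S, Z, taus) {
  Z <- as.numeric(Z)
  n <- length(S)
  mS <- mean(S); mZ <- mean(Z)
  vS <- mean((S - mS)^2); vZ <- mean((Z - mZ)^2)
  vapply(taus, function(tt) {
    idx <- seq_len(n - tt)
    mean((S[idx + tt] - mS) * (Z[idx] - mZ)) / sqrt(vS * vZ)
  }, numeric(1))
}

# Analytic piecewise derivative of the full map F(z) + K u(z).
branch_slope <- function(z, p, fb = feedback_params(), sigma = NULL) {
  if (is.null(sigma)) sigma <- if (is.null(fb$sigma)) 1 / p$a else fb$sigma
  sl <- p$a * (abs(z) < 1 / p$a) - p$k * p$b * (abs(z) < 1 / p$b)
  if (fb$K != 0) {
    dz <- z - fb$z_d
    sl <- sl + fb$K * (-exp(-dz^2 / (2 * sigma^2)) * (1 - dz^2 / sigma^2))
  }
  sl
}

# Orbit-average log absolute slope: the closed-form Lyapunov exponent of a
# noise-free 1-D map, evaluated on the same orbit the estimator uses.
oracle_lyapunov <- function(p, fb = feedback_params(), z0 = 0.1,
                            M = 2e4, transient = 1e4) {
  tr <- simulate_map(p, fb, drive_params(), z0 = z0, T = M,
                     transient = transient)
  mean(log(abs(branch_slope(tr$z, p, fb))))
}

# Dense-scan location of the first parameter value satisfying a condition.
dense_scan_first <- function(cond, grid) {
  ok <- vapply(grid, cond, logical(1))
  grid[which(ok)[1L]]
}

default_p <- function(a = 5.96) map_params(a)
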