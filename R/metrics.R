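#' Delayed cross-correlation between drive and binarized response
#'
#' Computes the normalized correlation
#' `C(tau) = C_SZ(tau) / sqrt(C_SS * C_ZZ)` with
#' `C_SZ(tau) = <(S(t+tau) - <S>)(Z(t) - <Z>)>`, the signal-response index:
#' its maximum over delays measures how well the sign changes of the
#' effective neural potential lock to the weak sinusoidal input.  Means and
#' variances are taken over the full retained window; the lagged product is
#' averaged over the overlap.
#'
#' @param S Drive series (numeric).
#' @param Z Binarized response series (same length).
#' @param tau_grid Integer delays (>= 0).  `NULL` (default) takes `n_tau`
#'   evenly spaced integer delays spanning one drive period `[0, 1/Omega)`,
#'   which requires `Omega`.
#' @param Omega Drive frequency used to build the default delay grid.
#' @param n_tau Number of delays in the default grid.
#' @return An object of class `"correlation_result"`: list with `tau`,
#'   `C`, `max_C` and `argmax_tau`.
#' @section Errors: a constant `S` or `Z` (zero variance, e.g. no
#'   intermittency at all) signals a condition of class
#'   `"rro_undefined_correlation"`.
#' @export
cross_correlation <- function(S, Z, tau_grid = NULL, Omega = NULL,
                              n_tau = 64) {
  if (inherits(S, "trajectory")) {
    tr <- S
    if (is.null(Omega)) Omega <- tr$params$drive$Omega
    S <- tr$S
    Z <- tr$Z
  }
  stopifnot(is.numeric(S), is.numeric(Z), length(S) == length(Z))
  if (var(S) == 0 || var(as.numeric(Z)) == 0)
    stop(errorCondition(
      "cross_correlation: zero variance in S or Z (constant series)",
      class = "rro_undefined_correlation"))
  if (is.null(tau_grid)) {
    if (is.null(Omega) || Omega <= 0)
      stop("cross_correlation: need tau_grid, or Omega > 0 for the ",
           "default one-period grid")
    period <- 1 / Omega
    tau_grid <- unique(as.integer(round(
      seq(0, period, length.out = n_tau + 1)[-(n_tau + 1)])))
  }
  tau_grid <- as.integer(tau_grid)
  if (any(tau_grid < 0)) stop("cross_correlation: delays must be >= 0")
  if (length(S) <= max(tau_grid) + 1L)
    stop("cross_correlation: series shorter than the largest delay")
  C <- ccf_core(as.numeric(S), as.numeric(Z), tau_grid)
  i <- which.max(C)
  structure(list(tau = tau_grid, C = C,
                 max_C = C[i], argmax_tau = tau_grid[i]),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d delays in [%d, %d]; max C = %.4f at tau = %d\n",
              length(x$tau), min(x$tau), max(x$tau), x$max_C, x$argmax_tau))
  invisible(x)
}

#' @importFrom stats var
NULL

# max-over-delay response of a trajectory; NA when correlation undefined
max_signal_response <- function(tr, tau_grid = NULL) {
  tryCatch(cross_correlation(tr, tau_grid = tau_grid)$max_C,
           rro_undefined_correlation = function(e) NA_real_)
}

#' Lyapunov exponent by orbit perturbation
#'
#' Estimates `lambda = 1/(tau M) * sum_k ln(d_k(tau) / d0)`: along one base
#' orbit, at `M` restart points spaced `tau` iterations apart, the state is
#' cloned, offset by `d0`, and both copies are evolved `tau` steps under
#' the identical drive and noise realization (common-noise convention, so
#' the exponent measures state-space divergence only), accumulating the log
#' separation growth.  For `tau = 1` in the noise-free map this equals the
#' orbit average of `ln |slope|` over the map's piecewise branches.
#'
#' @inheritParams simulate_map
#' @param d0 Initial perturbation magnitude (> 0).
#' @param tau Growth horizon in iterations (>= 1).
#' @param M Number of perturbed restarts (>= 1).
#' @return The estimated Lyapunov exponent (per iteration).
#' @examples
#' \donttest{lyapunov_exponent(map_params(5.96), M = 1e4)  # positive: chaos}
#' @export
lyapunov_exponent <- function(p, fb = feedback_params(),
                              drive = drive_params(), z0 = 0.1,
                              d0 = 1e-8, tau = 1, M = 1e5,
                              transient = 1e4, seed = drive$seed) {
  assert_params(p, fb, drive)
  stopifnot(d0 > 0, tau >= 1, M >= 1, transient >= 0,
            is.finite(z0))
  if (!is.null(seed)) set.seed(seed)
  sigma <- resolve_sigma(fb, p)
  res <- lyap_core(z0, as.integer(transient), as.integer(M),
                   as.integer(tau), d0, p$a, p$b, p$k,
                   fb$K, fb$z_d, sigma, drive$A, drive$Omega, drive$D)
  if (res$n_floored > 0)
    warning(sprintf(paste0("lyapunov_exponent: %d of %d separations ",
                           "collapsed to zero (flat map branch) and were ",
                           "floored at d0 * machine epsilon"),
                    res$n_floored, as.integer(M)))
  res$lambda
}
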