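#' Parameters of the excitatory-inhibitory neural map
#'
#' The discrete neural system couples an excitatory unit `x(t)` and an
#' inhibitory unit `y(t)` through piecewise-linear activations with gains
#' `a` and `b`.  Under the weight-ratio constraint
#' `w_EI / w_EE = w_II / w_IE = k` the pair reduces to the one-dimensional
#' effective neural potential `z(t) = x(t) - k * y(t)` with
#' `z(t+1) = F_a(z) - k * F_b(z)`.
#'
#' @param a Excitatory gain (> 0); `1/a` is the excitatory activation
#'   threshold.  The studied chaotic regime lies around `a = 5.95`-`6.03`.
#' @param b Inhibitory gain (> 0).
#' @param k Inhibition ratio (> 0).
#' @param w_EE,w_EI,w_IE,w_II Optional synaptic weights.  Either give all
#'   four or none; they must satisfy the reduction constraint
#'   `w_EI/w_EE = w_II/w_IE = k` to within a relative tolerance of 1e-12.
#'   The defaults `w_EE = w_IE = 1`, `w_EI = w_II = k` make the
#'   two-dimensional system reduce exactly to the one-dimensional map.
#'
#' @return An object of class `"map_params"`.
#' @examples
#' p <- map_params(5.96)
#' map_f(0.1, p)
#' @export
map_params <- function(a, b = 3.42, k = 1.3811,
                       w_EE = NULL, w_EI = NULL, w_IE = NULL, w_II = NULL) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (a <= 0 || b <= 0 || k <= 0)
    stop("map_params: a, b and k must all be positive")
  w <- list(w_EE, w_EI, w_IE, w_II)
  given <- !vapply(w, is.null, logical(1))
  if (any(given) && !all(given))
    stop("map_params: give all four synaptic weights or none")
  if (all(given)) {
    w <- as.numeric(w)
    if (any(!is.finite(w)) || w[1] == 0 || w[3] == 0)
      stop("map_params: invalid synaptic weights")
    r1 <- w[2] / w[1]
    r2 <- w[4] / w[3]
    if (abs(r1 - k) > 1e-12 * max(abs(k), 1) ||
        abs(r2 - k) > 1e-12 * max(abs(k), 1))
      stop("map_params: weights violate the reduction constraint ",
           "w_EI/w_EE = w_II/w_IE = k")
  } else {
    w <- c(1, k, 1, k)
  }
  structure(list(a = a, b = b, k = k,
                 w_EE = w[1], w_EI = w[2], w_IE = w[3], w_II = w[4]),
            class = "map_params")
}

#' @export
print.map_params <- function(x, ...) {
  cat(sprintf("<map_params> a = %g, b = %g, k = %g\n", x$a, x$b, x$k))
  cat(sprintf("  weights: w_EE = %g, w_EI = %g, w_IE = %g, w_II = %g\n",
              x$w_EE, x$w_EI, x$w_IE, x$w_II))
  invisible(x)
}

#' Reduced-region-of-orbit (RRO) feedback parameters
#'
#' The RRO feedback term `K * u(z)` with
#' `u(z) = -(z - z_d) * exp(-(z - z_d)^2 / (2 sigma^2))` deforms the map
#' around the merging point `z_d` of the two chaotic sub-attractors.
#' Positive `K` shrinks the map's local extrema (separating a merged
#' attractor); negative `K` enlarges them (merging a separated attractor).
#'
#' @param K Feedback strength (any sign; `K = 0` disables feedback).
#' @param z_d Merging point of the attractors; 0 for the symmetric map.
#' @param sigma Width of the feedback region (> 0).  `NULL` (the default)
#'   means "use `1/a` of the map it is applied to", the distance from the
#'   merging point to the map's local extremum.
#'
#' @return An object of class `"feedback_params"`.
#' @export
feedback_params <- function(K = 0, z_d = 0, sigma = NULL) {
  stopifnot(is.numeric(K), length(K) == 1L, is.finite(K),
            is.numeric(z_d), length(z_d) == 1L, is.finite(z_d))
  if (!is.null(sigma)) {
    stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
    if (sigma <= 0) stop("feedback_params: sigma must be positive")
  }
  structure(list(K = K, z_d = z_d, sigma = sigma),
            class = "feedback_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat(sprintf("<feedback_params> K = %g, z_d = %g, sigma = %s\n",
              x$K, x$z_d,
              if (is.null(x$sigma)) "1/a (map default)" else format(x$sigma)))
  invisible(x)
}

#' Sinusoidal drive and additive-noise parameters
#'
#' @param A Amplitude of the weak sinusoidal signal `S(t) = A sin(2 pi
#'   Omega t)` (>= 0, state units).
#' @param Omega Signal frequency in cycles per iteration; must satisfy
#'   `0 <= Omega < 0.5` (below the map's Nyquist frequency).
#' @param D Strength of the additive zero-mean unit-variance Gaussian
#'   noise (>= 0).
#' @param seed Optional integer RNG seed recorded with trajectories.
#'
#' @return An object of class `"drive_params"`.
#' @export
drive_params <- function(A = 0, Omega = 0, D = 0, seed = NULL) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(Omega), length(Omega) == 1L, is.finite(Omega),
            is.numeric(D), length(D) == 1L, is.finite(D))
  if (A < 0) stop("drive_params: A must be non-negative")
  if (D < 0) stop("drive_params: D must be non-negative")
  if (Omega < 0 || Omega >= 0.5)
    stop("drive_params: Omega must lie in [0, 0.5)")
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    seed <- as.integer(seed)
  }
  structure(list(A = A, Omega = Omega, D = D, seed = seed),
            class = "drive_params")
}

#' @export
print.drive_params <- function(x, ...) {
  cat(sprintf("<drive_params> A = %g, Omega = %g, D = %g, seed = %s\n",
              x$A, x$Omega, x$D,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}

# sigma defaults to 1/a when unset on the feedback object
resolve_sigma <- function(fb, p) {
  if (is.null(fb$sigma)) 1 / p$a else fb$sigma
}

assert_params <- function(p, fb = NULL, drive = NULL) {
  if (!inherits(p, "map_params")) stop("expected a 'map_params' object")
  if (!is.null(fb) && !inherits(fb, "feedback_params"))
    stop("expected a 'feedback_params' object")
  if (!is.null(drive) && !inherits(drive, "drive_params"))
    stop("expected a 'drive_params' object")
  invisible(TRUE)
}
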