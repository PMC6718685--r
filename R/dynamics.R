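#' One synchronous step of the two-dimensional neuron pair
#'
#' Updates the excitatory/inhibitory states per
#' `x(t+1) = F_a(w_EE x - w_EI y)`, `y(t+1) = F_b(w_IE x - w_II y)`.
#' Under the weight-ratio constraint built into [map_params()], the reduced
#' coordinate `z = x - k y` evolves exactly by the one-dimensional map:
#' `x' - k y'` after one step equals `map_f(x - k y, p)`.
#'
#' @param x,y Current excitatory and inhibitory states (scalars).
#' @param p A [map_params()] object (its weights are used).
#' @return Named numeric vector `c(x = , y = )` with the next states.
#' @export
step_2d <- function(x, y, p) {
  assert_params(p)
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x),
            is.numeric(y), length(y) == 1L, is.finite(y))
  c(x = activation(p$w_EE * x - p$w_EI * y, p$a),
    y = activation(p$w_IE * x - p$w_II * y, p$b))
}

#' Simulate the driven, noisy, feedback-controlled map
#'
#' Iterates `z(t+1) = F(z(t)) + K u(z(t)) + S(t) + D xi(t)` with
#' `S(t) = A sin(2 pi Omega t)` and i.i.d. standard Gaussian `xi(t)`,
#' discards a transient, and returns the retained window together with the
#' binarized series `Z(t)` (+1 where `z >= 0`, -1 otherwise) and the
#' aligned drive `S(t)`.  The drive phase uses the absolute iteration index
#' starting at 0, before transient removal, so drive and state share one
#' clock.
#'
#' The default initial state `z0 = 0.1` lies inside the basin of the
#' chaotic attractor, which occupies `|z|` up to about `1 - kb/a` (about
#' 0.21 for the default parameters).  States beyond the inhibitory
#' threshold `1/b` land on the map's saturated branches, which carry a
#' superstable alternating period-2 cycle at `|z| = k - 1`; initial values
#' there never reach the chaotic attractor.
#'
#' @param p A [map_params()] object.
#' @param fb A [feedback_params()] object.
#' @param drive A [drive_params()] object.
#' @param z0 Initial effective neural potential.
#' @param T Number of retained iterations (> 0).
#' @param transient Number of discarded initial iterations (>= 0).
#' @param seed RNG seed; defaults to `drive$seed`.  `NULL` leaves the RNG
#'   state alone.
#' @return An object of class `"trajectory"`: list with numeric `z`,
#'   integer `Z` (+/-1), numeric `S`, integer time index `t`, the transient
#'   length `t0`, `T`, and `params` (full provenance).
#' @examples
#' tr <- simulate_map(map_params(5.96), T = 1000, transient = 100)
#' all(tr$Z == 1)  # trapped in the positive region
#' @export
simulate_map <- function(p, fb = feedback_params(), drive = drive_params(),
                         z0 = 0.1, T = 2e5, transient = 1e4,
                         seed = drive$seed) {
  assert_params(p, fb, drive)
  stopifnot(is.numeric(z0), length(z0) == 1L, is.finite(z0),
            T >= 1, transient >= 0)
  T <- as.integer(T); transient <- as.integer(transient)
  if (!is.null(seed)) set.seed(seed)
  sigma <- resolve_sigma(fb, p)
  z <- sim_core(z0, T, transient, p$a, p$b, p$k,
                fb$K, fb$z_d, sigma, drive$A, drive$Omega, drive$D)
  t_idx <- transient + seq_len(T) - 1L
  S <- drive$A * sin(2 * pi * drive$Omega * t_idx)
  structure(list(z = z, Z = binarize(z), S = S, t = t_idx,
                 t0 = transient, T = T,
                 params = list(map = p, feedback = fb, drive = drive,
                               z0 = z0, seed = seed)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> T = %d retained after transient %d\n",
              x$T, x$t0))
  cat(sprintf("  z range [%.4f, %.4f]; P_t = %.4g\n",
              min(x$z), max(x$z), intermittency_probability(x)))
  invisible(x)
}

#' Binarize an effective-potential series
#'
#' `Z(t) = 1` where `z(t) >= 0` and `-1` otherwise (zero maps to +1).
#'
#' @param z Numeric series (finite).
#' @return Integer vector of +/-1, same length.
#' @export
binarize <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("binarize: z must be finite numeric")
  2L * as.integer(z >= 0) - 1L
}

#' Occurrence probability of chaos-chaos intermittency
#'
#' `P_t = f_cc / T`, where `f_cc` counts the iterations at which the
#' binarized state changes sign between consecutive retained samples, i.e.
#' the orbit hops between the positive and negative sub-attractors.
#'
#' @param x A `"trajectory"` object or a +/-1 series of length >= 2.
#' @return `P_t` in `[0, 1)`.
#' @export
intermittency_probability <- function(x) {
  Z <- if (inherits(x, "trajectory")) x$Z else x
  if (!is.numeric(Z) || length(Z) < 2L)
    stop("intermittency_probability: need a series of length >= 2")
  n <- length(Z)
  sum(Z[-1L] != Z[-n]) / n
}
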