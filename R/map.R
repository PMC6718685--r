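#' Piecewise-linear activation function
#'
#' `F_gain(x)` saturates at -1 for `x < -1/gain`, is linear `gain * x` on
#' `[-1/gain, 1/gain]`, and saturates at +1 above; `1/gain` is the
#' activation threshold.  Odd in `x` and bounded in `[-1, 1]`.
#'
#' @param x State input (numeric vector, finite).
#' @param gain Activation gain (> 0, scalar).
#' @return Activation values, same length as `x`.
#' @examples
#' activation(0.1, 5.96)  # linear branch: 0.596
#' @export
activation <- function(x, gain) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("activation: x must be finite numeric")
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stop("activation: gain must be a positive finite scalar")
  pmax(pmin(gain * x, 1), -1)
}

#' The reduced one-dimensional neural map F(z)
#'
#' `F(z) = F_a(z) - k * F_b(z)`: the deterministic map of the effective
#' neural potential obtained from the excitatory-inhibitory pair under the
#' weight-ratio constraint.  Odd in `z` and bounded by `1 + k`.
#'
#' @param z Effective neural potential (numeric vector).
#' @param p A [map_params()] object.
#' @return `F(z)`, same length as `z`.
#' @export
map_f <- function(z, p) {
  assert_params(p)
  activation(z, p$a) - p$k * activation(z, p$b)
}

#' RRO feedback term u(z)
#'
#' `u(z) = -(z - z_d) * exp(-(z - z_d)^2 / (2 sigma^2))`: a Gaussian-shaped
#' odd deformation about the merging point `z_d`, with extrema at
#' `z_d +/- sigma` of magnitude `sigma * exp(-1/2)`.
#'
#' @param z Effective neural potential (numeric vector).
#' @param fb A [feedback_params()] object; `sigma` must be set (there is no
#'   map here to supply the `1/a` default).
#' @return `u(z)`, same length as `z` (the feedback applied to the map is
#'   `K * u(z)`; `K` is not included here).
#' @export
rro_u <- function(z, fb) {
  if (!inherits(fb, "feedback_params"))
    stop("expected a 'feedback_params' object")
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("rro_u: z must be finite numeric")
  if (is.null(fb$sigma))
    stop("rro_u: sigma is unset; supply it or call full_map(), ",
         "which defaults sigma to 1/a")
  dz <- z - fb$z_d
  -dz * exp(-dz^2 / (2 * fb$sigma^2))
}

#' The full iterated map F(z) + K u(z)
#'
#' The map actually iterated under RRO feedback.  With `z_d = 0` it is odd.
#'
#' @inheritParams map_f
#' @param fb A [feedback_params()] object; an unset `sigma` defaults to
#'   `1/a`.
#' @return Map values, same length as `z`.
#' @export
full_map <- function(z, p, fb = feedback_params()) {
  assert_params(p, fb)
  v <- map_f(z, p)
  if (fb$K != 0) {
    fb2 <- fb
    fb2$sigma <- resolve_sigma(fb, p)
    v <- v + fb$K * rro_u(z, fb2)
  }
  v
}

#' Local extrema of the full map and their images
#'
#' Locates the interior local maximum of `F + K u` on the positive half of
#' the search interval `[-(1+k), 1+k]` and the interior local minimum on
#' the negative half (dense grid followed by golden-section refinement).
#' `f_max` and `f_min` are the local maximum and minimum *values* of the
#' map; because the extremum value is itself the next iterate of the orbit,
#' the attractor-merging condition examines the map's value *at* these
#' points: `value_at_max = full_map(f_max)` and
#' `value_at_min = full_map(f_min)`.
#'
#' @inheritParams full_map
#' @param n_grid Number of dense-grid points per half-axis.
#' @param tol Refinement tolerance on the extremum location.
#' @return An object of class `"extrema_result"`: a list with `z_max`,
#'   `z_min` (extremum locations), `f_max`, `f_min` (extremum values), and
#'   `value_at_max`, `value_at_min` (map images of the extremum values).
#' @export
find_extrema <- function(p, fb = feedback_params(),
                         n_grid = 1e4, tol = 1e-10) {
  assert_params(p, fb)
  L <- 1 + p$k
  f <- function(z) full_map(z, p, fb)

  refine <- function(lo, hi, maximum) {
    optimize(f, interval = c(lo, hi), maximum = maximum, tol = tol)
  }
  interior_extremum <- function(zs, maximum) {
    v <- f(zs)
    i <- if (maximum) which.max(v) else which.min(v)
    if (i == 1L || i == length(zs))
      stop("find_extrema: no interior extremum on the search interval ",
           "(degenerate parameters)")
    refine(zs[i - 1L], zs[i + 1L], maximum)
  }

  pos <- seq(L / n_grid, L, length.out = n_grid)
  neg <- seq(-L, -L / n_grid, length.out = n_grid)
  mx <- interior_extremum(pos, maximum = TRUE)
  mn <- interior_extremum(neg, maximum = FALSE)

  f_max <- mx$objective
  f_min <- mn$objective
  structure(list(z_max = mx$maximum, z_min = mn$minimum,
                 f_max = f_max, f_min = f_min,
                 value_at_max = f(f_max), value_at_min = f(f_min)),
            class = "extrema_result")
}

#' @export
print.extrema_result <- function(x, ...) {
  cat(sprintf("<extrema_result>\n  f_max = %.6f at z = %.6f; map(f_max) = %.6f\n",
              x$f_max, x$z_max, x$value_at_max))
  cat(sprintf("  f_min = %.6f at z = %.6f; map(f_min) = %.6f\n",
              x$f_min, x$z_min, x$value_at_min))
  invisible(x)
}

#' Analytic attractor-merging condition
#'
#' Attractor merging (chaos-chaos intermittency) occurs when the image of
#' the map's local maximum falls below zero and the image of its local
#' minimum rises above zero, so that the highest point of the positive
#' sub-attractor maps into the negative region and vice versa.
#'
#' @inheritParams find_extrema
#' @return `TRUE` if the two sub-attractors are merged, `FALSE` if the
#'   orbit stays trapped on one side.
#' @examples
#' merging_condition(map_params(6.03))                     # TRUE
#' merging_condition(map_params(5.96))                     # FALSE
#' merging_condition(map_params(5.96), feedback_params(-0.1))  # TRUE
#' @export
merging_condition <- function(p, fb = feedback_params(), ...) {
  ex <- find_extrema(p, fb, ...)
  ex$value_at_max < 0 && ex$value_at_min > 0
}

bisect_flip <- function(cond, interval, tol) {
  lo <- interval[1]; hi <- interval[2]
  c_lo <- cond(lo); c_hi <- cond(hi)
  if (identical(c_lo, c_hi))
    stop("bisection: condition does not flip over the interval ",
         sprintf("[%g, %g]", lo, hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(cond(mid), c_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Critical excitatory gain for attractor merging
#'
#' Bisects the gain `a` for the flip of [merging_condition()] at fixed
#' feedback strength.  With no feedback (`K = 0`) the onset lies at
#' `a = (k b)^2 / (k b - 1)`, approximately 5.99 for the default `b`, `k`.
#'
#' @param K Feedback strength held fixed during the scan.
#' @param interval Bracketing interval for `a` (condition must differ at
#'   its two ends).
#' @param tol Bisection tolerance.
#' @param b,k,z_d Remaining map and feedback parameters.
#' @param sigma Feedback width; `NULL` tracks `1/a` as `a` varies.
#' @return The critical gain `a*`.
#' @export
critical_a <- function(K = 0, interval = c(5.9, 6.1), tol = 1e-6,
                       b = 3.42, k = 1.3811, z_d = 0, sigma = NULL) {
  cond <- function(a)
    merging_condition(map_params(a, b, k), feedback_params(K, z_d, sigma))
  bisect_flip(cond, interval, tol)
}

#' Critical RRO feedback strength for attractor merging
#'
#' Bisects the feedback strength `K` for the flip of
#' [merging_condition()] at fixed map parameters.  For a separated
#' attractor (`a` below the merging onset of about 5.99) the flip occurs at
#' a negative `K`, with larger `|K|` required the further `a` lies below
#' the onset.
#'
#' @param p A [map_params()] object.
#' @param interval Bracketing interval for `K`.
#' @param tol Bisection tolerance.
#' @param z_d,sigma Feedback geometry (defaults: `z_d = 0`,
#'   `sigma = 1/a`).
#' @return The critical feedback strength `K*` (signed).
#' @examples
#' \donttest{critical_K(map_params(5.96))  # about -0.051}
#' @export
critical_K <- function(p, interval = c(-0.15, 0), tol = 1e-6,
                       z_d = 0, sigma = NULL) {
  assert_params(p)
  cond <- function(K)
    merging_condition(p, feedback_params(K, z_d, sigma))
  bisect_flip(cond, interval, tol)
}
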