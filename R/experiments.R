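#' @name sweeps
#' @title Parameter sweeps and response surfaces
#'
#' @description
#' Drivers that scan one model parameter (or a parameter pair) and collect
#' per-grid-point metrics: attractor samples, the intermittency probability
#' `P_t`, the Lyapunov exponent, the analytic merging margins, and the
#' trial-averaged delay-maximized signal response `max_tau C(tau)`.  All
#' randomness is derived from one base seed, and every result carries full
#' provenance (grids, seeds, parameters).
NULL

# random initial state inside the chaotic basin, either sign
draw_z0 <- function() sample(c(-1, 1), 1L) * runif(1L, 0.1, 0.2)

set_param <- function(name, value, p, fb, drive) {
  switch(name,
         a = { p$a <- value },
         K = { fb$K <- value },
         D = { drive$D <- value },
         A = { drive$A <- value },
         Omega = { drive$Omega <- value },
         stop("unknown sweep parameter: ", name))
  list(p = p, fb = fb, drive = drive)
}

new_sweep <- function(kind, param, grid, summary, param2 = NULL,
                      grid2 = NULL, surface = NULL, trials_df = NULL,
                      attractors = NULL, merged_nodrive = NULL,
                      trials = NA_integer_, seed = NULL, provenance = list()) {
  structure(list(kind = kind, param = param, grid = grid,
                 param2 = param2, grid2 = grid2, summary = summary,
                 surface = surface, trials_df = trials_df,
                 attractors = attractors, merged_nodrive = merged_nodrive,
                 trials = trials, seed = seed, provenance = provenance),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over %s (%d points%s)\n", x$kind, x$param,
              length(x$grid),
              if (!is.null(x$param2))
                sprintf(" x %s (%d points)", x$param2, length(x$grid2))
              else ""))
  if (!is.null(x$summary)) print(utils::head(x$summary, 8))
  invisible(x)
}

provenance_of <- function(p, fb, drive, extra = list()) {
  c(list(map = unclass(p), feedback = unclass(fb), drive = unclass(drive)),
    extra)
}

#' Bifurcation scan over an internal parameter, feedback strength, or noise
#'
#' For each grid value of `a`, `K` or `D`, runs the undriven map from one
#' negative and one positive initial value, and records sampled attractor
#' points (the last `n_attractor` retained states of each run), the
#' intermittency probability `P_t` (the larger of the two runs), the
#' Lyapunov exponent, and the analytic merging margins
#' `value_at_max`/`value_at_min`.  Failures at single grid points are
#' recorded (as `NA` plus a message) rather than aborting the scan.
#'
#' @param param One of `"a"`, `"K"`, `"D"`.
#' @param grid Numeric grid of parameter values.
#' @param p,fb,drive Base parameter objects; the swept field is overridden
#'   per grid point.
#' @param T,transient Retained and discarded iterations per run.
#' @param z0 Magnitude of the two initial values (`-z0` and `+z0`); keep it
#'   inside the chaotic basin (below about 0.21 for the defaults).
#' @param n_attractor Attractor samples kept per initial value.
#' @param lyap_M Restarts for the Lyapunov estimate.
#' @param seed Base seed for the scan.
#' @return A `"sweep_result"` with a `summary` data frame (columns `value`,
#'   `P_t`, `P_t_neg`, `P_t_pos`, `lambda`, `value_at_max`, `value_at_min`,
#'   `error`) and `attractors`, a list of per-point sample data frames.
#' @export
bifurcation_scan <- function(param = c("a", "K", "D"), grid,
                             p = map_params(5.96),
                             fb = feedback_params(),
                             drive = drive_params(),
                             T = 1e5, transient = 1e4, z0 = 0.1,
                             n_attractor = 200, lyap_M = 1e5, seed = 1) {
  param <- match.arg(param)
  assert_params(p, fb, drive)
  drive$A <- 0  # undriven scan
  set.seed(seed)
  point_seeds <- sample.int(2^31 - 2, length(grid))
  n <- length(grid)
  out <- data.frame(value = grid, P_t = NA_real_, P_t_neg = NA_real_,
                    P_t_pos = NA_real_, lambda = NA_real_,
                    value_at_max = NA_real_, value_at_min = NA_real_,
                    error = NA_character_)
  attractors <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      st <- set_param(param, grid[i], p, fb, drive)
      ex <- find_extrema(st$p, st$fb)
      pt <- list(value_at_max = ex$value_at_max,
                 value_at_min = ex$value_at_min)
      samples <- list()
      for (s in c(-1, 1)) {
        tr <- simulate_map(st$p, st$fb, st$drive, z0 = s * z0,
                           T = T, transient = transient,
                           seed = point_seeds[i] + (s + 1) / 2)
        pt[[if (s < 0) "P_t_neg" else "P_t_pos"]] <-
          intermittency_probability(tr)
        samples[[length(samples) + 1L]] <-
          data.frame(z0_sign = s, z = utils::tail(tr$z, n_attractor))
      }
      pt$lambda <- suppressWarnings(
        lyapunov_exponent(st$p, st$fb, st$drive, z0 = z0,
                          M = lyap_M, transient = transient,
                          seed = point_seeds[i]))
      pt$samples <- do.call(rbind, samples)
      pt
    }, error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$error)) {
      out$error[i] <- res$error
    } else {
      out$P_t_neg[i] <- res$P_t_neg
      out$P_t_pos[i] <- res$P_t_pos
      out$P_t[i] <- max(res$P_t_neg, res$P_t_pos)
      out$lambda[i] <- res$lambda
      out$value_at_max[i] <- res$value_at_max
      out$value_at_min[i] <- res$value_at_min
      attractors[[i]] <- res$samples
    }
  }
  new_sweep("bifurcation", param, grid, out, attractors = attractors,
            trials = 2L, seed = seed,
            provenance = provenance_of(p, fb, drive,
                                       list(T = T, transient = transient,
                                            z0 = z0, lyap_M = lyap_M,
                                            point_seeds = point_seeds)))
}

#' Signal-response curve over feedback strength or noise strength
#'
#' For each grid value of `K` (chaotic resonance) or `D` (stochastic
#' resonance), runs `trials` driven trajectories with independent seeds and
#' random initial values (random sign, magnitude uniform in the chaotic
#' basin), and records the mean and standard deviation over trials of
#' `max_tau C(tau)`.  Grid points where the correlation is undefined in
#' every trial (no intermittency: the binarized state never changes sign)
#' are recorded as missing.
#'
#' @param param `"K"` or `"D"`.
#' @param grid Numeric grid.
#' @param p,fb,drive Base parameters; `drive` must have `A > 0` and
#'   `Omega > 0`.
#' @param trials Trajectories per grid point.
#' @param T,transient Iterations per trajectory.
#' @param seed Base seed.
#' @return A `"sweep_result"` with `summary` (columns `value`, `maxC_mean`,
#'   `maxC_sd`, `n_valid`) and the long per-trial table in `trials_df`.
#' @export
response_curve <- function(param = c("K", "D"), grid,
                           p = map_params(5.96),
                           fb = feedback_params(),
                           drive = drive_params(A = 1e-2, Omega = 1e-4),
                           trials = 10, T = 2e5, transient = 1e4,
                           seed = 1) {
  param <- match.arg(param)
  assert_params(p, fb, drive)
  if (drive$A <= 0 || drive$Omega <= 0)
    stop("response_curve: drive must have A > 0 and Omega > 0")
  set.seed(seed)
  run_seeds <- matrix(sample.int(2^31 - 1, length(grid) * trials),
                      nrow = length(grid))
  rows <- vector("list", length(grid) * trials)
  r <- 0L
  for (i in seq_along(grid)) {
    st <- set_param(param, grid[i], p, fb, drive)
    for (j in seq_len(trials)) {
      set.seed(run_seeds[i, j])
      z0 <- draw_z0()
      tr <- simulate_map(st$p, st$fb, st$drive, z0 = z0,
                         T = T, transient = transient, seed = NULL)
      r <- r + 1L
      rows[[r]] <- data.frame(value = grid[i], trial = j,
                              seed = run_seeds[i, j], z0 = z0,
                              max_C = max_signal_response(tr))
    }
  }
  trials_df <- do.call(rbind, rows)
  agg <- split(trials_df$max_C, factor(trials_df$value, levels = grid))
  summary <- data.frame(
    value = grid,
    maxC_mean = vapply(agg, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE), 0),
    maxC_sd = vapply(agg, function(v)
      if (sum(!is.na(v)) < 2L) NA_real_ else sd(v, na.rm = TRUE), 0),
    n_valid = vapply(agg, function(v) sum(!is.na(v)), 0L))
  rownames(summary) <- NULL
  new_sweep("curve", param, grid, summary, trials_df = trials_df,
            trials = as.integer(trials), seed = seed,
            provenance = provenance_of(p, fb, drive,
                                       list(T = T, transient = transient,
                                            run_seeds = run_seeds)))
}

#' Two-dimensional response surface over (K, D or Omega) x amplitude
#'
#' Computes the trial-mean `max_tau C(tau)` on a 2-D grid with the signal
#' amplitude `A` on the second axis, and annotates each first-axis value
#' with whether attractor merging occurs *without* the drive (analytically
#' via [merging_condition()] for `K` and `Omega` axes; by an undriven noisy
#' run from both initial signs for the `D` axis).
#'
#' @param axis1 `"K"`, `"D"` or `"Omega"`.
#' @param grid1 Grid for `axis1`.
#' @param grid2 Grid of signal amplitudes `A`.
#' @param p,fb,drive Base parameters (`drive$Omega` must be > 0 unless
#'   `axis1 = "Omega"`).
#' @param trials,T,transient,seed As in [response_curve()].
#' @return A `"sweep_result"` whose `surface` is the
#'   `length(grid1) x length(grid2)` matrix of trial means; `summary`
#'   holds the long table, and `merged_nodrive` the per-`axis1` flags.
#' @export
response_surface <- function(axis1 = c("K", "D", "Omega"), grid1, grid2,
                             p = map_params(5.96),
                             fb = feedback_params(),
                             drive = drive_params(A = 1e-2, Omega = 1e-4),
                             trials = 10, T = 2e5, transient = 1e4,
                             seed = 1) {
  axis1 <- match.arg(axis1)
  assert_params(p, fb, drive)
  n1 <- length(grid1); n2 <- length(grid2)
  set.seed(seed)
  run_seeds <- array(sample.int(2^31 - 1, n1 * n2 * trials),
                     dim = c(n1, n2, trials))
  surface <- matrix(NA_real_, n1, n2,
                    dimnames = list(format(grid1), format(grid2)))
  rows <- vector("list", n1 * n2)
  merged <- logical(n1)
  for (i in seq_len(n1)) {
    st1 <- set_param(axis1, grid1[i], p, fb, drive)
    merged[i] <- if (axis1 == "D" && grid1[i] > 0) {
      any(vapply(c(-1, 1), function(s) {
        dd <- st1$drive; dd$A <- 0
        tr <- simulate_map(st1$p, st1$fb, dd, z0 = s * 0.1,
                           T = 1e5, transient = transient,
                           seed = run_seeds[i, 1, 1])
        intermittency_probability(tr) > 0
      }, logical(1)))
    } else {
      merging_condition(st1$p, st1$fb)
    }
    for (j in seq_len(n2)) {
      st <- set_param("A", grid2[j], st1$p, st1$fb, st1$drive)
      if (st$drive$Omega <= 0)
        stop("response_surface: drive frequency must be positive")
      vals <- numeric(trials)
      for (m in seq_len(trials)) {
        set.seed(run_seeds[i, j, m])
        z0 <- draw_z0()
        tr <- simulate_map(st$p, st$fb, st$drive, z0 = z0,
                           T = T, transient = transient, seed = NULL)
        vals[m] <- max_signal_response(tr)
      }
      surface[i, j] <- if (all(is.na(vals))) NA_real_
                       else mean(vals, na.rm = TRUE)
      rows[[(i - 1L) * n2 + j]] <-
        data.frame(value1 = grid1[i], value2 = grid2[j],
                   maxC_mean = surface[i, j],
                   maxC_sd = if (sum(!is.na(vals)) < 2L) NA_real_
                             else sd(vals, na.rm = TRUE),
                   n_valid = sum(!is.na(vals)),
                   merged_nodrive = merged[i])
    }
  }
  new_sweep("surface", axis1, grid1, do.call(rbind, rows),
            param2 = "A", grid2 = grid2, surface = surface,
            merged_nodrive = merged, trials = as.integer(trials),
            seed = seed,
            provenance = provenance_of(p, fb, drive,
                                       list(T = T, transient = transient)))
}

#' Onset threshold along a sweep
#'
#' Returns the first grid value at which `metric > threshold` holds,
#' assuming a monotone onset.  Errors if the predicate never holds or holds
#' already at the first grid point; warns (and returns the first onset) if
#' the predicate flips more than once.
#'
#' @param sweep A `"sweep_result"`.
#' @param metric Summary column to threshold (default `"P_t"`).
#' @param threshold Numeric threshold (default 0, i.e. predicate
#'   `P_t > 0`).
#' @return The grid value at onset.
#' @export
find_threshold <- function(sweep, metric = "P_t", threshold = 0) {
  stopifnot(inherits(sweep, "sweep_result"))
  v <- sweep$summary[[metric]]
  if (is.null(v)) stop("find_threshold: no metric column '", metric, "'")
  ok <- !is.na(v) & v > threshold
  if (!any(ok)) stop("find_threshold: predicate never holds (no threshold)")
  if (ok[1L]) stop("find_threshold: predicate already holds at the first ",
                   "grid point (no onset)")
  if (sum(diff(ok) != 0) > 1L)
    warning("find_threshold: predicate flips more than once; ",
            "returning the first onset")
  sweep$grid[which(ok)[1L]]
}

#' Peak of a response curve or surface
#'
#' Grid argmax of the trial-mean `max_tau C(tau)`.  Ties are broken toward
#' the parameter value of smallest magnitude (the weakest control).
#'
#' @param sweep A `"sweep_result"` from [response_curve()] or
#'   [response_surface()].
#' @return For a curve, `list(param, value)`; for a surface,
#'   `list(param, param2, value)`.
#' @export
find_peak <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (sweep$kind == "surface") {
    if (all(is.na(sweep$surface))) stop("find_peak: all metrics missing")
    m <- max(sweep$surface, na.rm = TRUE)
    idx <- which(sweep$surface == m, arr.ind = TRUE)
    i <- idx[which.min(abs(sweep$grid[idx[, 1]])), , drop = FALSE]
    return(list(param = sweep$grid[i[1, 1]],
                param2 = sweep$grid2[i[1, 2]], value = m))
  }
  v <- sweep$summary$maxC_mean
  if (is.null(v) || all(is.na(v))) stop("find_peak: all metrics missing")
  if (length(v[!is.na(v)]) < 3L)
    stop("find_peak: need at least 3 valid grid points")
  m <- max(v, na.rm = TRUE)
  cand <- which(!is.na(v) & v == m)
  i <- cand[which.min(abs(sweep$grid[cand]))]
  list(param = sweep$grid[i], value = m)
}
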