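#' Write results to delimited tables plus a JSON provenance record
#'
#' Trajectories become a four-column `(t, z, Z, S)` CSV; sweep results
#' become a long-form CSV (one row per grid point, or per grid point and
#' trial when per-trial values exist) plus a summary CSV.  Every write also
#' emits a JSON sidecar embedding the full parameter set, seeds and grids,
#' sufficient to regenerate the result.  Reals are written with 17
#' significant digits so the matching readers round-trip bit-exactly.
#'
#' @param x A `"trajectory"` or `"sweep_result"` object.
#' @param dir Output directory (created if needed).
#' @param name Basename for the files.
#' @return Invisibly, the character vector of paths written.
#' @export
write_results <- function(x, dir, name) UseMethod("write_results")

fmt_num <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

write_num_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

write_provenance <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

pkg_version <- function() {
  as.character(utils::packageVersion("rrochaos"))
}

#' @rdname write_results
#' @export
write_results.trajectory <- function(x, dir, name = "trajectory") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  js <- file.path(dir, paste0(name, ".json"))
  write_num_csv(data.frame(t = x$t, z = x$z, Z = x$Z, S = x$S), csv)
  write_provenance(list(type = "trajectory", version = pkg_version(),
                        T = x$T, transient = x$t0,
                        params = lapply(x$params, unclass)), js)
  invisible(c(csv, js))
}

#' @rdname write_results
#' @export
write_results.sweep_result <- function(x, dir, name = "sweep") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(x$trials_df)) {
    p1 <- file.path(dir, paste0(name, "_trials.csv"))
    write_num_csv(x$trials_df, p1)
    paths <- c(paths, p1)
  }
  p2 <- file.path(dir, paste0(name, "_summary.csv"))
  write_num_csv(x$summary, p2)
  js <- file.path(dir, paste0(name, ".json"))
  write_provenance(list(type = "sweep_result", version = pkg_version(),
                        kind = x$kind, param = x$param, grid = x$grid,
                        param2 = x$param2, grid2 = x$grid2,
                        trials = x$trials, seed = x$seed,
                        merged_nodrive = x$merged_nodrive,
                        provenance = x$provenance), js)
  invisible(c(paths, p2, js))
}

#' Read back a trajectory written by [write_results()]
#'
#' @param dir Directory holding the files.
#' @param name Basename used at write time.
#' @return A `"trajectory"` object (provenance restored from the JSON
#'   sidecar).
#' @export
read_trajectory <- function(dir, name = "trajectory") {
  df <- read.csv(file.path(dir, paste0(name, ".csv")))
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  pm <- meta$params
  p <- do.call(map_params, pm$map[c("a", "b", "k")])
  fb <- feedback_params(pm$feedback$K, pm$feedback$z_d, pm$feedback$sigma)
  dr <- drive_params(pm$drive$A, pm$drive$Omega, pm$drive$D, pm$drive$seed)
  structure(list(z = df$z, Z = as.integer(df$Z), S = df$S,
                 t = as.integer(df$t), t0 = meta$transient, T = meta$T,
                 params = list(map = p, feedback = fb, drive = dr,
                               z0 = pm$z0, seed = pm$seed)),
            class = "trajectory")
}

#' Read back a sweep summary written by [write_results()]
#'
#' @inheritParams read_trajectory
#' @return A `"sweep_result"` carrying the summary table, per-trial table
#'   (when present) and provenance; attractor samples and surfaces are not
#'   round-tripped.
#' @export
read_sweep <- function(dir, name = "sweep") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  summary <- read.csv(file.path(dir, paste0(name, "_summary.csv")))
  tf <- file.path(dir, paste0(name, "_trials.csv"))
  trials_df <- if (file.exists(tf)) read.csv(tf) else NULL
  new_sweep(meta$kind, meta$param, meta$grid, summary,
            param2 = meta$param2, grid2 = meta$grid2,
            trials_df = trials_df, merged_nodrive = meta$merged_nodrive,
            trials = meta$trials, seed = meta$seed,
            provenance = meta$provenance)
}

#' Deterministic toy fixtures for the metric implementations
#'
#' Generates small series with known metric values: a sinusoid with its
#' aligned binarization (for the correlation index), a constant-sign series
#' (`P_t = 0`, correlation undefined for the binarized channel), a strictly
#' alternating series (`P_t = (T-1)/T`), and an orbit of a linearly
#' contracting map (negative Lyapunov exponent, analytically
#' `ln |a - k b|`).
#'
#' @param seed RNG seed (the fixtures are fully deterministic; the seed
#'   only fixes the phase-jittered copy of the sinusoid).
#' @param n Length of the periodic fixtures.
#' @return Named list: `sinusoid` (data frame `t`, `S`, `Z`), `constant`,
#'   `alternating` (integer series), `contracting` (list with the orbit
#'   `z`, its parameters and the analytic exponent `lambda`).
#' @export
make_fixtures <- function(seed = 1, n = 2000) {
  set.seed(seed)
  Omega <- 5e-3
  tt <- 0:(n - 1)
  S <- sin(2 * pi * Omega * tt)
  sinusoid <- data.frame(t = tt, S = S, Z = binarize(S))
  p <- map_params(4.0)  # |a - k b| < 1: contraction on the linear branch
  tr <- simulate_map(p, z0 = 0.01, T = 100, transient = 0, seed = seed)
  list(sinusoid = sinusoid,
       constant = rep(1L, 100),
       alternating = rep(c(1L, -1L), length.out = 100),
       contracting = list(z = tr$z, a = p$a, b = p$b, k = p$k,
                          lambda = log(abs(p$a - p$k * p$b))))
}
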