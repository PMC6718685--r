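test_that("a bifurcation scan over a locates the merging onset", {
  grid <- c(5.95, 5.97, 6.00, 6.02)
  sw <- bifurcation_scan("a", grid, T = 3e4, transient = 5e3,
                         lyap_M = 2e4, seed = 4)
  expect_s3_class(sw, "sweep_result")
  expect_equal(sw$summary$value, grid)
  # separated below the onset, merged above; lambda positive throughout
  expect_equal(sw$summary$P_t[1:2], c(0, 0))
  expect_true(all(sw$summary$P_t[3:4] > 0))
  expect_true(all(sw$summary$lambda > 0))
  # P_t onset brackets the analytic merging boundary within one grid step
  th <- find_threshold(sw)
  a_star <- critical_a()
  expect_lt(abs(th - a_star), 0.02 + 1e-9)
  # analytic margins flip sign across the onset
  expect_gt(sw$summary$value_at_max[1], 0)
  expect_lt(sw$summary$value_at_max[4], 0)
  # attractor samples recorded for both initial signs
  expect_equal(nrow(sw$attractors[[1]]), 400)
})

test_that("a feedback scan finds the intermittency onset at the critical K", {
  grid <- seq(-0.08, -0.02, by = 0.01)
  sw <- bifurcation_scan("K", grid, T = 3e4, transient = 5e3,
                         lyap_M = 2e4, seed = 5)
  # scanning toward more negative K, onset occurs below K*
  K_star <- critical_K(map_params(5.96))
  merged <- sw$summary$value[sw$summary$P_t > 0]
  expect_true(all(merged < K_star + 0.01 + 1e-9))
  expect_true(all(sw$summary$P_t[sw$summary$value > K_star + 0.01] == 0))
})

test_that("find_threshold validates its monotone-onset contract", {
  sw <- bifurcation_scan("a", c(6.0, 6.03), T = 1e4, transient = 2e3,
                         lyap_M = 1e4, seed = 6)
  expect_error(find_threshold(sw), "first grid point")
  sw2 <- bifurcation_scan("a", c(5.9, 5.95), T = 1e4, transient = 2e3,
                          lyap_M = 1e4, seed = 6)
  expect_error(find_threshold(sw2), "never")
})

test_that("response curves average trials and record undefined points as missing", {
  p <- map_params(5.96)
  # A well below margin/(1 + kb): the drive alone cannot reach z = 0 at the
  # separated point, so its correlation is undefined there
  sw <- response_curve("K", c(-0.06, -0.02), p = p,
                       drive = drive_params(A = 1e-3, Omega = 1e-3),
                       trials = 4, T = 2e4, transient = 2e3, seed = 8)
  expect_equal(nrow(sw$trials_df), 8L)
  expect_equal(sw$summary$n_valid[1], 4L)
  expect_equal(sw$summary$n_valid[2], 0L)
  expect_true(is.na(sw$summary$maxC_mean[2]))
  expect_false(is.na(sw$summary$maxC_sd[1]))
  # reproducible from the base seed
  sw2 <- response_curve("K", c(-0.06, -0.02), p = p,
                        drive = drive_params(A = 1e-3, Omega = 1e-3),
                        trials = 4, T = 2e4, transient = 2e3, seed = 8)
  expect_identical(sw$summary, sw2$summary)
  expect_error(response_curve("K", c(-0.06), drive = drive_params(A = 0)),
               "A > 0")
})

test_that("response surfaces annotate the no-drive merging boundary", {
  sw <- response_surface("K", c(-0.07, -0.03), c(5e-3, 2e-2),
                         drive = drive_params(A = 1e-2, Omega = 1e-3),
                         trials = 2, T = 2e4, transient = 2e3, seed = 9)
  expect_equal(dim(sw$surface), c(2L, 2L))
  expect_identical(sw$merged_nodrive, c(TRUE, FALSE))
  pk <- find_peak(sw)
  expect_true(pk$param %in% sw$grid && pk$param2 %in% sw$grid2)
  expect_equal(pk$value, max(sw$surface, na.rm = TRUE))
})

test_that("find_peak breaks ties toward the weakest control", {
  sw <- structure(list(kind = "curve", param = "D",
                       grid = c(-0.1, -0.05, 0.02),
                       summary = data.frame(value = c(-0.1, -0.05, 0.02),
                                            maxC_mean = c(0.5, 0.5, 0.5))),
                  class = "sweep_result")
  expect_equal(find_peak(sw)$param, 0.02)
  sw$summary$maxC_mean <- rep(NA_real_, 3)
  expect_error(find_peak(sw), "missing")
})
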