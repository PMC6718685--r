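test_that("activation follows the three-branch rule and rejects bad input", {
  expect_equal(activation(0, 5.96), 0)
  expect_equal(activation(2, 5.96), 1)          # saturated: 2 > 1/5.96
  expect_equal(activation(-2, 5.96), -1)
  expect_equal(activation(0.1, 5.96), 0.596)    # linear branch
  # vectorized, bounded, odd
  z <- seq(-3, 3, length.out = 201)
  v <- activation(z, 3.42)
  expect_true(all(v >= -1 & v <= 1))
  expect_equal(activation(-z, 3.42), -v)
  expect_error(activation(0.5, 0), "gain")
  expect_error(activation(0.5, -2), "gain")
  expect_error(activation(NaN, 2), "finite")
})

test_that("the reduced map matches hand-evaluated branch values", {
  p <- default_p()
  expect_equal(map_f(0, p), 0)
  expect_equal(map_f(2, p), 1 - p$k)            # both activations saturated
  expect_equal(map_f(1 / p$a, p), 1 - p$k * p$b / p$a)  # ~0.2075
  expect_equal(map_f(-1 / p$a, p), -(1 - p$k * p$b / p$a))
})

test_that("map_f and full_map are odd and bounded by 1 + k", {
  p <- default_p()
  fb <- feedback_params(K = -0.1)
  z <- runif(500, -2.5, 2.5)
  expect_equal(map_f(-z, p), -map_f(z, p))
  expect_equal(full_map(-z, p, fb), -full_map(z, p, fb))
  expect_true(all(abs(map_f(z, p)) <= 1 + p$k + 1e-12))
})

test_that("the RRO feedback term is odd about z_d with known extrema", {
  fb <- feedback_params(K = -0.1, z_d = 0.2, sigma = 0.3)
  expect_equal(rro_u(fb$z_d, fb), 0)
  x <- runif(100, -1, 1)
  expect_equal(rro_u(fb$z_d + x, fb), -rro_u(fb$z_d - x, fb))
  # extrema at z_d +/- sigma with magnitude sigma * exp(-1/2)
  expect_equal(rro_u(fb$z_d + fb$sigma, fb), -fb$sigma * exp(-0.5))
  expect_equal(rro_u(fb$z_d - fb$sigma, fb), fb$sigma * exp(-0.5))
  expect_error(rro_u(0.1, feedback_params(K = 1)), "sigma")
})

test_that("full_map reduces to map_f at K = 0 and feedback deforms extrema", {
  p <- default_p()
  z <- seq(-2, 2, length.out = 101)
  expect_equal(full_map(z, p, feedback_params(0)), map_f(z, p))
  # negative K enlarges the local extrema; positive K shrinks them
  ex0 <- find_extrema(p)
  exn <- find_extrema(p, feedback_params(-0.1))
  exp_ <- find_extrema(p, feedback_params(0.1))
  expect_gt(exn$f_max, ex0$f_max)
  expect_lt(exp_$f_max, ex0$f_max)
  expect_lt(exn$f_min, ex0$f_min)
})

test_that("find_extrema agrees with a dense-grid oracle and is symmetric", {
  for (K in c(0, -0.1, 0.1)) {
    p <- default_p()
    fb <- feedback_params(K)
    ex <- find_extrema(p, fb)
    L <- 1 + p$k
    zs <- seq(1e-6, L, length.out = 1e5)
    v <- full_map(zs, p, fb)
    expect_lt(abs(ex$z_max - zs[which.max(v)]), L / 1e5 * 2)
    expect_gte(ex$f_max, max(v))  # refinement can only improve on the grid
    # odd map: f_min = -f_max, value_at_min = -value_at_max
    expect_equal(ex$f_min, -ex$f_max, tolerance = 1e-9)
    expect_equal(ex$value_at_min, -ex$value_at_max, tolerance = 1e-9)
    expect_equal(ex$value_at_max, full_map(ex$f_max, p, fb))
  }
})

test_that("the attractor-merging condition reproduces the known regimes", {
  expect_true(merging_condition(map_params(6.03)))
  expect_false(merging_condition(map_params(6.03), feedback_params(0.1)))
  expect_false(merging_condition(map_params(5.96)))
  expect_true(merging_condition(map_params(5.96), feedback_params(-0.1)))
  # separated regime: image of the maximum still positive
  ex <- find_extrema(map_params(5.96))
  expect_gt(ex$value_at_max, 0)
  expect_lt(ex$value_at_min, 0)
  ex2 <- find_extrema(map_params(6.03))
  expect_lt(ex2$value_at_max, 0)
  expect_gt(ex2$value_at_min, 0)
})

test_that("critical_a matches the dense-scan oracle and the closed form", {
  a_star <- critical_a()
  # closed form at K = 0: image of the peak value crosses zero at
  # a = (k b)^2 / (k b - 1)
  kb <- 1.3811 * 3.42
  expect_equal(a_star, kb^2 / (kb - 1), tolerance = 1e-4)
  scan <- dense_scan_first(function(a) merging_condition(map_params(a)),
                           seq(5.985, 5.995, by = 1e-4))
  expect_lt(abs(a_star - scan), 2e-4)
  # tolerance-independence at 2 decimals
  expect_equal(round(critical_a(tol = 1e-8), 2), round(a_star, 2))
  # positive feedback shrinks the extrema, postponing the onset
  expect_gt(critical_a(K = 0.1), a_star)
})

test_that("critical_K matches the dense-scan oracle and shrinks toward the onset", {
  Ks <- vapply(c(5.95, 5.96, 5.97),
               function(a) critical_K(map_params(a)), numeric(1))
  # scan from weak toward strong feedback: first K satisfying merging
  scan <- dense_scan_first(
    function(K) merging_condition(map_params(5.96), feedback_params(K)),
    seq(-0.04, -0.06, by = -1e-4))
  expect_lt(abs(Ks[2] - scan), 2e-4)
  # |K*| decreases monotonically as a rises toward the merging onset
  expect_true(all(diff(abs(Ks)) < 0))
})

test_that("bisection reports a bracketing failure when the condition never flips", {
  expect_error(critical_a(interval = c(6.0, 6.1)), "flip")
  expect_error(critical_K(map_params(5.96), interval = c(-0.02, 0)), "flip")
})
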