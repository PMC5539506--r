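calib_fix <- calibrate(make_color_captures())

test_that("an exact curve point is recovered with near-zero cost", {
  for (p in c(7.0, 3.4, 0.0, 14.0)) {
    i <- which.min(abs(calib_fix$grid - p))
    tgt <- t(vapply(1:4, function(k) calib_fix$curves[[k]][i, ], numeric(2)))
    est <- measure(measurement_capture(calib_fix$pivot_reference, tgt),
                   calib_fix)
    expect_equal(est$ph, p, tolerance = 1e-9)
    if (p == 7.0) expect_lt(est$match_cost, 1e-8)
  }
})

test_that("a known camera distortion is inverted before matching", {
  set.seed(41)
  fm <- random_poly_model()
  i <- which.min(abs(calib_fix$grid - 10.2))
  tgt <- t(vapply(1:4, function(k) calib_fix$curves[[k]][i, ], numeric(2)))
  cap <- measurement_capture(apply_color_model(fm, calib_fix$pivot_reference),
                             apply_color_model(fm, tgt))
  est <- measure(cap, calib_fix)
  expect_equal(est$ph, 10.2, tolerance = 1e-9)
})

test_that("the estimate is the global argmin of the cost profile", {
  set.seed(42)
  for (rep in 1:5) {
    p <- sample(calib_fix$grid, 1)
    i <- which.min(abs(calib_fix$grid - p))
    tgt <- t(vapply(1:4, function(k) calib_fix$curves[[k]][i, ],
                    numeric(2))) +
      matrix(rnorm(8, 0, 0.003), ncol = 2)
    est <- measure(measurement_capture(calib_fix$pivot_reference, tgt),
                   calib_fix)
    expect_equal(est$ph, est$grid[which.min(est$cost_profile)])
    expect_equal(est$match_cost, min(est$cost_profile))
    expect_equal(sum(est$per_patch_cost), est$match_cost, tolerance = 1e-12)
  }
})

test_that("ties break toward the lowest pH on the grid", {
  flat <- calib_fix
  for (k in 1:4) flat$curves[[k]] <- matrix(0.3, 141, 2)
  tgt <- matrix(0.31, 4, 2)
  est <- measure(measurement_capture(flat$pivot_reference, tgt), flat)
  expect_equal(est$ph, 0)
})

test_that("a uniform u' offset of the whole capture leaves the estimate alone", {
  i <- which.min(abs(calib_fix$grid - 5.6))
  tgt <- t(vapply(1:4, function(k) calib_fix$curves[[k]][i, ], numeric(2)))
  shift <- function(m, du) cbind(m[, 1] + du, m[, 2])
  est <- measure(measurement_capture(shift(calib_fix$pivot_reference, 0.02),
                                     shift(tgt, 0.02)), calib_fix)
  expect_equal(est$ph, 5.6, tolerance = 1e-9)
})

test_that("optional parabolic refinement stays within one grid step", {
  i <- which.min(abs(calib_fix$grid - 8.3))
  tgt <- t(vapply(1:4, function(k) calib_fix$curves[[k]][i, ], numeric(2)))
  est <- measure(measurement_capture(calib_fix$pivot_reference, tgt),
                 calib_fix, refine = TRUE)
  expect_lt(abs(est$ph_refined - est$ph), 0.1)
})

test_that("replicate statistics follow the population convention", {
  expect_equal(summarize_replicates(c(1.5, 1.5, 1.5, 1.5), 1.68),
               c(avg_abs_error = 0.18, std_dev = 0.00))
  expect_equal(summarize_replicates(c(12.6, 12.5, 12.5, 12.0), 12.46),
               c(avg_abs_error = 0.17, std_dev = 0.23))
  expect_equal(summarize_replicates(c(4.1, 4.1, 4.2, 4.2), 4.01),
               c(avg_abs_error = 0.14, std_dev = 0.05))
  x <- 6.4
  expect_equal(summarize_replicates(rep(x, 4), x),
               c(avg_abs_error = 0, std_dev = 0))
  expect_error(summarize_replicates(numeric(0), 7), "at least one")
})

test_that("half-up rounding handles exact decimal halves", {
  expect_equal(round_half_up(0.075, 2), 0.08)
  expect_equal(round_half_up(0.105, 2), 0.11)
  expect_equal(round_half_up(-0.075, 2), -0.08)
  expect_equal(round_half_up(0.074, 2), 0.07)
})

test_that("the bundled replicate table loads with 24 rows", {
  tab <- buffer_replicates()
  expect_equal(nrow(tab), 24L)
  expect_true(all(c("phone", "ideal_ph", "rep1", "rep4",
                    "avg_abs_err", "std_dev") %in% names(tab)))
})

test_that("capture containers validate their shapes", {
  expect_error(measurement_capture(test_palette$reference_uv[1:100, ],
                                   matrix(0.3, 4, 2)), "216")
  expect_error(measurement_capture(test_palette$reference_uv,
                                   matrix(0.3, 3, 2)), "4")
  expect_error(chart_capture(15, test_palette$reference_uv,
                             matrix(0.3, 4, 2)))
})
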