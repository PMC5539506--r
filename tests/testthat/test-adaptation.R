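test_that("design rows list the ten monomials in the fixed order", {
  expect_equal(drop(uv_design(c(0, 0))), c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(drop(uv_design(c(1, 1))), rep(1, 10), ignore_attr = TRUE)
  expect_equal(drop(uv_design(c(0.2, 0.5))),
               c(0.2, 0.5, 1, 0.04, 0.25, 0.1, 0.008, 0.125, 0.02, 0.05),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a model has exactly 20 parameters and the identity is exact", {
  m <- identity_color_model()
  expect_length(c(m$a_u, m$a_v), 20L)
  expect_equal(drop(apply_color_model(m, c(0.2, 0.5))), c(u = 0.2, v = 0.5))
  zero <- poly_color_model(rep(0, 10), rep(0, 10))
  expect_equal(drop(apply_color_model(zero, c(0.3, 0.4))), c(u = 0, v = 0))
  expect_error(poly_color_model(1:9, 1:10), "20 coefficients")
  expect_error(poly_color_model(c(NA, 1:9), 1:10), "finite")
})

test_that("fitting src == dst recovers the identity map", {
  m <- fit_color_model(test_palette$reference_uv, test_palette$reference_uv)
  pred <- apply_color_model(m, test_palette$reference_uv)
  expect_lt(max(abs(pred - test_palette$reference_uv)), 1e-8)
})

test_that("a noise-free third-order map is recovered to 1e-6", {
  set.seed(21)
  truth <- random_poly_model()
  src <- test_palette$reference_uv
  dst <- apply_color_model(truth, src)
  fit <- fit_color_model(src, dst)
  expect_equal(fit$a_u, truth$a_u, tolerance = 1e-6)
  expect_equal(fit$a_v, truth$a_v, tolerance = 1e-6)
  # held-out point matches the generator
  held <- c(0.21, 0.47)
  expect_equal(drop(apply_color_model(fit, held)),
               drop(apply_color_model(truth, held)), tolerance = 1e-6)
})

test_that("the L1 fit resists gross outliers better than least squares", {
  set.seed(22)
  truth <- random_poly_model()
  src <- test_palette$reference_uv
  dst <- apply_color_model(truth, src)
  n <- nrow(src)
  bad <- sample(n, round(0.1 * n))
  dst_corrupt <- dst
  dst_corrupt[bad, ] <- dst_corrupt[bad, ] +
    matrix(runif(length(bad) * 2, -0.3, 0.3), ncol = 2)
  l1 <- fit_color_model(src, dst_corrupt)
  ols <- fit_color_model(src, dst_corrupt, method = "ols")
  clean <- setdiff(seq_len(n), bad)
  err_l1 <- abs(apply_color_model(l1, src)[clean, ] - dst[clean, ])
  err_ols <- abs(apply_color_model(ols, src)[clean, ] - dst[clean, ])
  expect_lt(median(err_l1), median(err_ols))
})

test_that("the final L1 cost never exceeds the first-iteration cost", {
  set.seed(23)
  for (rep in 1:5) {
    truth <- random_poly_model(0.1)
    src <- test_palette$reference_uv
    dst <- apply_color_model(truth, src) +
      matrix(rnorm(216 * 2, 0, 0.01), ncol = 2)
    c1 <- model_l1_cost(fit_color_model(src, dst,
                                        irls_config(iterations = 1)),
                        src, dst)
    c20 <- model_l1_cost(fit_color_model(src, dst), src, dst)
    expect_lte(c20, c1 + 1e-12)
  }
})

test_that("IRLS reaches the true LAD minimum on reduced instances", {
  # degree-1 model with 3 basis terms, n = 12; the enumeration oracle gives
  # the exact minimum. delta is set below the residual scale of these
  # instances so the clamp does not bias the comparison of the solver
  # against the true minimum.
  set.seed(24)
  cfg <- irls_config(delta = 1e-4, iterations = 50)
  for (rep in 1:5) {
    X <- cbind(runif(12), runif(12), 1)
    y <- drop(X %*% rnorm(3)) + rnorm(12, 0, 0.1)
    a <- phstrip:::.irls_lad(X, y, cfg)
    expect_lt(sum(abs(y - X %*% a)), 1.01 * lad_cost_oracle(X, y))
  }
})

test_that("degenerate inputs raise informative errors", {
  uv10 <- test_palette$reference_uv[1:10, ]
  expect_error(fit_color_model(uv10[1:9, ], uv10[1:9, ]), "at least 10")
  same <- matrix(rep(c(0.2, 0.4), each = 12), ncol = 2)
  expect_error(fit_color_model(same, same), "rank deficient")
  bad <- uv10; bad[1, 1] <- NA
  expect_error(fit_color_model(bad, uv10), "finite")
})

test_that("models serialize to JSON and back unchanged", {
  set.seed(25)
  m <- random_poly_model()
  m2 <- model_from_json(model_to_json(m))
  # text round trip is exact to one ulp (decimal representation)
  expect_equal(m2$a_u, m$a_u, tolerance = 1e-14)
  expect_equal(m2$a_v, m$a_v, tolerance = 1e-14)
  tf <- tempfile(fileext = ".json")
  model_to_json(m, tf)
  expect_equal(model_from_json(tf)$a_v, m$a_v, tolerance = 1e-14)
  # serialization itself is deterministic
  expect_identical(model_to_json(m), model_to_json(m))
  expect_error(model_from_json('{"a_u":[1],"a_v":[1],"basis":"other"}'),
               "basis")
})
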