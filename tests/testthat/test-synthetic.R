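test_that("the default palette is deterministic and well spread", {
  p1 <- default_palette(3)
  p2 <- default_palette(3)
  expect_identical(p1$reference_uv, p2$reference_uv)
  expect_false(identical(p1$reference_uv, default_palette(4)$reference_uv))
  expect_gt(min(dist(p1$reference_uv)), 0.01)
  expect_true(all(uv_in_gamut(p1$reference_uv, p1$luminance)))
})

test_that("the strip model is smooth and continuous in pH", {
  p <- seq(0, 13.9, by = 0.1)
  cols <- vapply(p, function(x) strip_colors(test_palette, x), numeric(8))
  step <- abs(cols[, -1] - cols[, -ncol(cols)])
  expect_lt(max(step), 0.02)
  # anchors are reproduced at integer pH
  expect_equal(strip_colors(test_palette, 5),
               do.call(rbind, lapply(test_palette$anchors,
                                     function(a) a[6, ])),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("renders are deterministic under a fixed seed", {
  cam <- camera_model(noise_sigma = 3)
  set.seed(9); a <- render_chart_capture(test_palette, cam, 7)
  set.seed(9); b <- render_chart_capture(test_palette, cam, 7)
  expect_identical(a$image, b$image)
})

test_that("ground-truth colors equal the drawn pixels", {
  sc <- render_chart_capture(test_palette, camera_model(), 4)
  pos <- round(sc$truth$upper_positions)
  for (i in c(1, 50, 108)) {
    px <- sc$image[pos[i, 2] + 1, pos[i, 1] + 1, ]
    expect_equal(drop(rgb_to_uv(matrix(px, 1))),
                 drop(sc$truth$reference_uv_post[i, ]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # identity camera: post-distortion truth matches the palette to 8-bit
  # quantization accuracy (~1.2e-3 in u'v' at the render luminance)
  expect_lt(max(abs(sc$truth$reference_uv_post - sc$truth$reference_uv)),
            1.5e-3)
})

test_that("off-image geometry is rejected", {
  expect_error(render_chart_capture(test_palette,
                                    camera_model(translation = c(300, 0)),
                                    7),
               "off the image")
  expect_error(render_measurement_capture(test_palette, camera_model(), 15))
})

test_that("pose bookkeeping matches the applied transform", {
  cam <- camera_model(rotation_deg = 5, translation = c(7, -4), scale = 0.97)
  sc <- render_chart_capture(test_palette, cam, 7)
  sc0 <- render_chart_capture(test_palette, camera_model(), 7)
  th <- 5 * pi / 180
  ctr <- c((960 - 1) / 2, (720 - 1) / 2)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  manual <- sweep(sweep(sc0$truth$upper_positions, 2, ctr) %*% t(R) * 0.97,
                  2, ctr + c(7, -4), `+`)
  expect_equal(sc$truth$upper_positions, manual, tolerance = 1e-9)
})

test_that("the out-of-family RGB camera mode renders and differs", {
  cam <- camera_model(mode = "rgb",
                      rgb_matrix = matrix(c(1.05, 0.02, 0, 0.01, 0.97, 0.02,
                                            0, 0.03, 1.02), 3, 3,
                                          byrow = TRUE),
                      rgb_gamma = c(1.04, 1, 0.96))
  sc <- render_chart_capture(test_palette, cam, 7)
  sc0 <- render_chart_capture(test_palette, camera_model(), 7)
  expect_gt(max(abs(sc$truth$reference_uv_post -
                      sc0$truth$reference_uv_post)), 1e-3)
})

test_that("random cameras stay within their stated envelopes", {
  set.seed(10)
  for (i in 1:20) {
    cam <- random_camera()
    expect_lte(max(abs(c(cam$distortion$a_u - identity_color_model()$a_u,
                         cam$distortion$a_v - identity_color_model()$a_v))),
               0.05)
    expect_lte(abs(cam$rotation_deg), 4)
    expect_lte(max(abs(cam$translation)), 12)
  }
})
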