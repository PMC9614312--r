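test_that("Sobel gradients match a hand-convolution oracle", {
  cm <- radiograph(matrix(0.7, 12, 12))
  g <- sobel_gradients(cm)
  expect_true(all(abs(g$magnitude) < 1e-12))

  # vertical step: horizontal gradient, maximal on the step columns
  m <- matrix(0, 12, 12); m[, 7:12] <- 1
  g <- sobel_gradients(radiograph(m))
  expect_true(all(g$magnitude[, c(6, 7)] > 0))
  expect_true(all(abs(g$magnitude[, c(1:4, 9:12)]) < 1e-12))
  dir_on_step <- g$direction[, 6]
  expect_true(all(abs(dir_on_step) < 1e-9 | abs(abs(dir_on_step) - pi) < 1e-9))

  # random 8x8 grid vs explicit loop convolution of the Sobel kernels
  set.seed(21)
  m <- matrix(runif(64), 8, 8)
  g <- sobel_gradients(radiograph(m))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- filter_sym_oracle(m, kx)
  gy <- filter_sym_oracle(m, t(kx))
  expect_equal(g$magnitude, sqrt(gx^2 + gy^2), tolerance = 1e-12)
  expect_equal(g$direction, atan2(gy, gx), tolerance = 1e-12)
})

test_that("non-maximum suppression keeps ridges and resolves plateaus by the >= rule", {
  H <- 9; W <- 9
  dir0 <- matrix(0, H, W)  # gradient along columns

  ridge <- matrix(0, H, W); ridge[, 5] <- 1
  expect_identical(non_maximum_suppression(ridge, dir0), ridge)

  # 3-wide plateau perpendicular to the gradient: >= keeps all three
  plateau <- matrix(0, H, W); plateau[, 4:6] <- 0.8
  out <- non_maximum_suppression(plateau, dir0)
  expect_identical(out, plateau)

  # off-center maximum within the plateau: single winner survives
  ramp <- matrix(0, H, W); ramp[, 4] <- 0.5; ramp[, 5] <- 0.9; ramp[, 6] <- 0.5
  out <- non_maximum_suppression(ramp, dir0)
  expect_true(all(out[, 5] == 0.9) && all(out[, c(4, 6)] == 0))

  expect_true(all(non_maximum_suppression(matrix(0, H, W), dir0) == 0))

  # output support is a subset of the input support
  set.seed(5)
  mag <- matrix(runif(81), 9, 9)
  dir <- matrix(runif(81, -pi, pi), 9, 9)
  thin <- non_maximum_suppression(mag, dir)
  expect_true(all(thin[thin > 0] == mag[thin > 0]))
})

test_that("hysteresis equals a flood-fill oracle on random grids", {
  expect_error(hysteresis_threshold(matrix(1, 5, 5), 2, 1), "low")

  all_strong <- matrix(0.9, 6, 6)
  expect_true(all(hysteresis_threshold(all_strong, 0.1, 0.5)$edges == 1))

  # weak pixel kept iff 8-connected to a strong one
  m <- matrix(0, 7, 7)
  m[3, 3] <- 1; m[4, 4] <- 0.3   # diagonal neighbor of the seed
  m[1, 7] <- 0.3                 # isolated weak pixel
  e <- hysteresis_threshold(m, 0.2, 0.8)
  expect_equal(e$edges[3, 3], 1)
  expect_equal(e$edges[4, 4], 1)
  expect_equal(e$edges[1, 7], 0)
  expect_equal(e$n_edge_pixels, 2)

  set.seed(99)
  for (rep in 1:20) {
    thin <- matrix(runif(144), 12, 12) * (runif(144) < 0.6)
    got <- hysteresis_threshold(thin, 0.35, 0.75)
    want <- hysteresis_oracle(thin, 0.35, 0.75)
    expect_identical(got$edges, want)
  }
})

test_that("canny traces the phantom bone contour and behaves monotonically in thresholds", {
  expect_warning(e0 <- canny(radiograph(matrix(0.5, 20, 20))), "degenerate")
  expect_equal(e0$n_edge_pixels, 0)

  # bare straight bone on air: detected edges hug the analytic capsule outline
  spec <- small_phantom_spec(soft_tissue = FALSE)
  ph <- generate_phantom(spec)
  e <- canny(ph$image, abs_canny())
  expect_gt(e$n_edge_pixels, 300)
  idx <- which(e$edges == 1, arr.ind = TRUE)
  hw <- spec$bone_halfwidth
  d_axis <- pmin(
    seg_dist_points(idx, spec$femur_axis$hip, spec$femur_axis$knee),
    seg_dist_points(idx, spec$tibia_axis$knee, spec$tibia_axis$ankle))
  expect_lt(max(abs(d_axis - hw)), 2)

  # every sampled point of the analytic contour has a detected edge
  # nearby (the contour is closed and fully traced)
  tt <- seq(0.05, 0.95, length.out = 60)
  for (seg in list(c(spec$femur_axis$hip, spec$femur_axis$knee),
                   c(spec$tibia_axis$knee, spec$tibia_axis$ankle))) {
    p <- seg[1:2]; q <- seg[3:4]
    u <- (q - p) / sqrt(sum((q - p)^2))
    perp <- c(-u[2], u[1])
    for (side in c(-1, 1)) {
      pts <- outer(tt, q - p) + rep(1, 60) %o% p +
        rep(1, 60) %o% (side * hw * perp)
      dmin <- apply(pts, 1, function(z)
        min(sqrt((idx[, 1] - z[1])^2 + (idx[, 2] - z[2])^2)))
      expect_lt(max(dmin), 2.5)
    }
  }

  # raising the high percentile never adds edge pixels
  ph2 <- generate_phantom(small_phantom_spec(noise_sd = 0.02))
  counts <- vapply(c(0.80, 0.90, 0.97), function(q)
    canny(ph2$image, canny_config(high_quantile = q))$n_edge_pixels, 1)
  expect_true(all(diff(counts) <= 0))

  # absolute thresholds: raising either one never adds edge pixels
  e_lo <- canny(ph$image, canny_config("absolute", low = 0.1, high = 0.4))
  e_hi <- canny(ph$image, canny_config("absolute", low = 0.3, high = 0.6))
  expect_lte(e_hi$n_edge_pixels, e_lo$n_edge_pixels)
  expect_true(all(e_lo$edges[e_hi$edges == 1] == 1))
})
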