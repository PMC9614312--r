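test_that("wavelet blending is a convex combination with perfect reconstruction", {
  set.seed(12)
  for (fam in c("haar", "db2")) {
    i1 <- matrix(runif(24 * 40), 24, 40)
    i2 <- matrix(runif(24 * 40), 24, 40)

    b1 <- wavelet_blend(i1, i2, blend_config(fam, levels = 3, theta = 1))
    expect_lt(sqrt(mean((b1 - i1)^2)), 1e-6)
    b0 <- wavelet_blend(i1, i2, blend_config(fam, levels = 3, theta = 0))
    expect_lt(sqrt(mean((b0 - i2)^2)), 1e-6)

    bs <- wavelet_blend(i1, i1, blend_config(fam, levels = 2, theta = 0.3))
    expect_lt(sqrt(mean((bs - i1)^2)), 1e-6)

    # uniform theta: linearity makes the blend a per-pixel average
    bh <- wavelet_blend(i1, i2, blend_config(fam, levels = 3, theta = 0.5))
    expect_lt(sqrt(mean((bh - (i1 + i2) / 2)^2)), 1e-6)
  }
})

test_that("blending handles awkward strip shapes and preserves range", {
  set.seed(2)
  # odd dimensions force symmetric padding
  i1 <- matrix(runif(17 * 33), 17, 33)
  i2 <- matrix(runif(17 * 33), 17, 33)
  b <- wavelet_blend(i1, i2, blend_config("db2", levels = 3, theta = 0.5))
  expect_equal(dim(b), c(17L, 33L))
  expect_lt(max(abs(b - (i1 + i2) / 2)), 1e-6)
  expect_true(all(b >= 0 & b <= 1))

  # strips thinner than 2^levels fall back to fewer levels
  i1 <- matrix(runif(5 * 64), 5, 64)
  i2 <- matrix(runif(5 * 64), 5, 64)
  b <- wavelet_blend(i1, i2, blend_config("haar", levels = 3, theta = 0.25))
  expect_equal(dim(b), c(5L, 64L))
  expect_lt(max(abs(b - (0.25 * i1 + 0.75 * i2))), 1e-6)

  # per-scale theta stays within the convex hull of the inputs
  b <- wavelet_blend(i1, i2, blend_config("haar", levels = 2,
                                          theta = c(1, 0)))
  expect_true(all(b >= 0 & b <= 1))

  expect_error(wavelet_blend(i1, matrix(0.5, 6, 64)), "shape")
  expect_error(blend_config(theta = 1.4), "theta")
  expect_error(blend_config(wavelet = "sym8"), "family")
})

test_that("composition tiles the canvas with verbatim rows outside blended overlaps", {
  ph <- generate_phantom(small_phantom_spec(varus_valgus_deg = -4))
  td <- tile_phantom(ph$image, ph$truth, 50, 64)
  out <- compose_canvas(td$tiles, make_reg(0, 50), make_reg(0, 64))

  hh <- vapply(td$tiles, function(t) nrow(t$pixels), 1L)
  expect_equal(unname(out$report$canvas["height"]),
               unname(sum(hh) - 50 - 64))
  # composition with true offsets inverts the tiling
  expect_lt(sqrt(mean((out$stitched$pixels - ph$image$pixels)^2)), 1e-6)

  # rows outside the overlaps are bit-identical to their source tiles
  h1 <- hh[1]
  expect_identical(out$stitched$pixels[1:(h1 - 50), ],
                   td$tiles$hip$pixels[1:(h1 - 50), ])
  tail_rows <- (nrow(out$stitched$pixels) - 20):nrow(out$stitched$pixels)
  h3 <- hh[3]
  expect_identical(out$stitched$pixels[tail_rows, ],
                   td$tiles$ankle$pixels[(h3 - 20):h3, ])

  # horizontal shifts widen the canvas and flag zero-filled padding
  td2 <- tile_phantom(ph$image, ph$truth, 50, 64, dx_12 = 5, dx_23 = -2)
  out2 <- compose_canvas(td2$tiles, make_reg(5, 50), make_reg(-2, 64))
  expect_true(out2$report$padding)
  expect_equal(unname(out2$report$canvas["width"]),
               ncol(td2$tiles$hip$pixels) + 5)

  expect_error(compose_canvas(td$tiles, make_reg(0, 170), make_reg(0, 160)),
               "overlap|exhaust")
})
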