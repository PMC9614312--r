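test_that("distance maps are exact Euclidean and Lipschitz", {
  E0 <- matrix(0, 8, 8); E0[1, 1] <- 1
  d <- distance_map(edge_map(E0))
  expect_equal(d[1, 1], 0)
  expect_equal(d[4, 5], 5)   # 3-4-5 triangle from (1,1)

  set.seed(17)
  for (rep in 1:5) {
    E <- random_edge_matrix(20, 20, 0.06)
    d <- unclass(distance_map(edge_map(E)))
    expect_equal(d, edt_bruteforce(E), tolerance = 1e-9)
    expect_true(all(d[E == 1] == 0))
  }

  # 1-Lipschitz under the Euclidean metric at random pixel pairs
  E <- random_edge_matrix(32, 32, 0.03)
  d <- unclass(distance_map(edge_map(E)))
  set.seed(4)
  i1 <- sample(32, 10000, TRUE); j1 <- sample(32, 10000, TRUE)
  i2 <- sample(32, 10000, TRUE); j2 <- sample(32, 10000, TRUE)
  lhs <- abs(d[cbind(i1, j1)] - d[cbind(i2, j2)])
  rhs <- sqrt((i1 - i2)^2 + (j1 - j2)^2)
  expect_true(all(lhs <= rhs + 1e-9))

  expect_error(distance_map(edge_map(matrix(0, 8, 8))), "no edges")
})

test_that("the matching distance follows the symmetric formula", {
  # identical non-empty maps match perfectly
  E <- random_edge_matrix(15, 15, 0.1)
  d <- unclass(distance_map(edge_map(E)))
  expect_equal(matching_distance(E, d, E, d), 0)

  # 3x3 worked case: single edges at opposite corners
  e1 <- matrix(0, 3, 3); e1[1, 1] <- 1
  e2 <- matrix(0, 3, 3); e2[3, 3] <- 1
  a <- matching_distance(e1, unclass(distance_map(edge_map(e1))),
                         e2, unclass(distance_map(edge_map(e2))))
  expect_equal(a, 2 * sqrt(8), tolerance = 1e-9)

  # random pairs vs the literal per-pixel oracle; symmetry
  set.seed(31)
  for (rep in 1:10) {
    E1 <- random_edge_matrix(10, 14, 0.12)
    E2 <- random_edge_matrix(10, 14, 0.12)
    D1 <- unclass(distance_map(edge_map(E1)))
    D2 <- unclass(distance_map(edge_map(E2)))
    a <- matching_distance(E1, D1, E2, D2)
    expect_equal(a, matching_distance_oracle(E1, D1, E2, D2),
                 tolerance = 1e-12)
    expect_equal(a, matching_distance(E2, D2, E1, D1), tolerance = 1e-12)
    expect_gte(a, 0)
    if (!identical(E1, E2)) expect_gt(a, 0)
  }

  expect_error(matching_distance(matrix(0, 5, 5), matrix(0, 5, 5),
                                 E1, D1[1:5, 1:5]), "shape|empty")
  empty <- matrix(0, 10, 14)
  expect_error(matching_distance(empty, D1, E2, D2), "empty")
})

test_that("exhaustive search recovers a constructed offset, fft and direct agree", {
  set.seed(57)
  canvasE <- random_edge_matrix(110, 48, 0.04)
  upper <- edge_map(canvasE[1:70, ])
  lower <- edge_map(canvasE[46:110, ])   # true dy = 25, dx = 0
  sr <- offset_search(dy_min = 10, dy_max = 40, dx_max = 4)

  rf <- find_offset(upper, lower, sr, method = "fft")
  rd <- find_offset(upper, lower, sr, method = "direct")
  expect_equal(rf$dx, 0); expect_equal(rf$dy, 25)
  expect_equal(rf$matching_distance, 0)
  expect_equal(rd[c("dx", "dy", "matching_distance")],
               rf[c("dx", "dy", "matching_distance")])
  expect_equal(rf$search_evaluations, 31 * 9)

  # optimality: no candidate on the grid beats the returned one
  D_up <- unclass(distance_map(upper)); D_lo <- unclass(distance_map(lower))
  for (dy in seq(10, 40, by = 3)) {
    for (dx in -4:4) {
      c1 <- (max(0, dx) + 1):(48 + min(0, dx))
      e1 <- upper$edges[(70 - dy + 1):70, c1]
      e2 <- lower$edges[1:dy, c1 - dx]
      if (sum(e1) == 0 || sum(e2) == 0) next
      a <- matching_distance(e1, D_up[(70 - dy + 1):70, c1],
                             e2, D_lo[1:dy, c1 - dx])
      expect_gte(a + 1e-9, rf$matching_distance)
    }
  }
})

test_that("search with a horizontal shift and restricted ranges behaves as specified", {
  set.seed(8)
  canvasE <- random_edge_matrix(120, 60, 0.04)
  upper <- edge_map(canvasE[1:75, 1:52])
  lower <- edge_map(canvasE[51:120, 4:55])   # dy = 25, dx = 3
  sr <- offset_search(dy_min = 12, dy_max = 38, dx_max = 6)
  r <- find_offset(upper, lower, sr)
  expect_equal(c(r$dx, r$dy), c(3, 25))
  expect_equal(r$matching_distance, 0)

  # excluding the true dy returns the in-range minimizer with A > 0
  sr2 <- offset_search(dy_min = 8, dy_max = 15, dx_max = 6)
  r2 <- find_offset(upper, lower, sr2, quality_ceiling = 1e6)
  expect_lte(r2$dy, 15)
  expect_gt(r2$matching_distance, 0)

  # warning when the best in-range cost exceeds the quality ceiling
  expect_warning(find_offset(upper, lower, sr2, quality_ceiling = 1e-4),
                 "quality ceiling")
})

test_that("strip-consistent overlap quality is exactly zero for identical anatomy", {
  ph <- generate_phantom(small_phantom_spec(varus_valgus_deg = 3))
  td <- tile_phantom(ph$image, ph$truth, 45, 50, dx_12 = 2)
  q <- overlap_quality(td$tiles$hip, td$tiles$knee, 2, 45, abs_canny())
  expect_identical(q, 0)
  # misaligned by one row: strictly positive
  q1 <- overlap_quality(td$tiles$hip, td$tiles$knee, 2, 46, abs_canny())
  expect_gt(q1, 0)
})
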