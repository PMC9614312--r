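test_that("the HKA angle honors the straight-leg and sign conventions", {
  expect_equal(hka_angle(c(0, 0), c(10, 0), c(20, 0)), 180)

  # rotated straight legs still read 180
  rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                          sin(a) * p[1] + cos(a) * p[2])
  for (a in c(0.3, 1.2, 2.5, -0.7)) {
    expect_equal(hka_angle(rot(c(0, 0), a), rot(c(5, 0.5), a),
                           rot(c(10, 1), a)),
                 180, tolerance = 1e-9)
  }

  # mirroring about a vertical axis maps 180 + d to 180 - d
  hip <- c(0, 5); knee <- c(10, 4); ankle <- c(20, 6)
  a <- hka_angle(hip, knee, ankle)
  am <- hka_angle(hip * c(1, -1), knee * c(1, -1), ankle * c(1, -1))
  expect_equal(a - 180, 180 - am, tolerance = 1e-9)

  expect_error(hka_angle(c(1, 1), c(1, 1), c(5, 5)), "coincident|zero-length")
})

test_that("HKA is invariant under rigid motion and uniform scaling", {
  set.seed(44)
  for (rep in 1:25) {
    hip <- runif(2, 0, 100); knee <- runif(2, 0, 100); ankle <- runif(2, 0, 100)
    if (isTRUE(all.equal(hip, knee)) || isTRUE(all.equal(ankle, knee))) next
    base <- hka_angle(hip, knee, ankle)
    th <- runif(1, -pi, pi); shift <- runif(2, -50, 50); s <- runif(1, 0.1, 8)
    tf <- function(p) {
      q <- s * p
      c(cos(th) * q[1] - sin(th) * q[2], sin(th) * q[1] + cos(th) * q[2]) + shift
    }
    expect_equal(hka_angle(tf(hip), tf(knee), tf(ankle)), base,
                 tolerance = 1e-9)
  }
})

test_that("phantom truth landmarks reproduce the programmed deviation", {
  for (vv in seq(-10, 10, by = 2.5)) {
    tr <- generate_phantom(small_phantom_spec(varus_valgus_deg = vv))$truth
    expect_equal(hka_angle(tr$hip_center, tr$knee_center, tr$ankle_center),
                 180 + vv, tolerance = 1e-6)
  }
})

test_that("angle-set comparison matches the textbook t statistics", {
  set.seed(9)
  a <- rnorm(12, 186, 1.1)
  b <- rnorm(12, 185.6, 1.4)

  # paired t: direct formula oracle
  cmp <- compare_angle_sets(a, b, paired = TRUE)
  d <- a - b
  t_ref <- mean(d) / (sd(d) / sqrt(length(d)))
  p_ref <- 2 * pt(-abs(t_ref), df = length(d) - 1)
  expect_equal(cmp$t, t_ref, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_ref, tolerance = 1e-12)
  expect_equal(cmp$mean_difference, mean(d), tolerance = 1e-12)
  expect_equal(cmp$sd_a, sd(a))

  # Welch two-sample oracle
  cmpw <- compare_angle_sets(a, b, paired = FALSE)
  se <- sqrt(var(a) / 12 + var(b) / 12)
  tw <- (mean(a) - mean(b)) / se
  dfw <- se^4 / ((var(a) / 12)^2 / 11 + (var(b) / 12)^2 / 11)
  expect_equal(cmpw$t, tw, tolerance = 1e-12)
  expect_equal(cmpw$p_value, 2 * pt(-abs(tw), dfw), tolerance = 1e-12)

  # shifting one set moves the mean difference by the constant (and a
  # constant difference is itself a zero-variance comparison)
  expect_warning(cmp2 <- compare_angle_sets(b + 0.7, b, paired = TRUE),
                 "zero-variance")
  expect_equal(cmp2$mean_difference, 0.7, tolerance = 1e-12)

  # zero-variance convention: identical sets give p = 1, never NaN
  expect_warning(cmp0 <- compare_angle_sets(a, a, paired = TRUE),
                 "zero-variance")
  expect_equal(cmp0$p_value, 1)
  expect_equal(cmp0$mean_difference, 0)

  expect_error(compare_angle_sets(1, 2), "at least two")
  expect_error(compare_angle_sets(a, b[1:5], paired = TRUE), "equal-length")
})
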