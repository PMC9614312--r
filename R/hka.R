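#' Hip-knee-ankle (HKA) angle from three landmark points
#'
#' The angle at the knee between the vectors knee-to-hip and
#' knee-to-ankle, reported so that a straight leg reads exactly 180
#' degrees: the returned value is the signed angle from the femoral to
#' the tibial vector, mapped into `(0, 360)`. The sign of the 2-D cross
#' product of (knee->hip, knee->ankle) decides whether a deviation
#' `delta` is reported as `180 + delta` or `180 - delta`; mirroring the
#' landmarks about a vertical axis swaps the two. The measure is
#' invariant under global translation, rotation and uniform scaling of
#' the three points.
#'
#' @param hip,knee,ankle Landmark points as `(row, col)` pairs in a
#'   common (e.g. stitched-canvas) coordinate frame; the three points
#'   must be pairwise distinct.
#' @return The HKA angle in degrees, in `(0, 360)`.
#' @export
#' @examples
#' hka_angle(c(0, 0), c(10, 0), c(20, 0))   # straight leg: 180
hka_angle <- function(hip, knee, ankle) {
  pts <- list(hip = hip, knee = knee, ankle = ankle)
  for (nm in names(pts))
    if (!is.numeric(pts[[nm]]) || length(pts[[nm]]) != 2L ||
        anyNA(pts[[nm]]))
      stopf("`%s` must be a numeric (row, col) pair", nm)
  v1 <- hip - knee
  v2 <- ankle - knee
  if (sum(v1^2) == 0 || sum(v2^2) == 0)
    stopf("coincident landmarks: zero-length femoral or tibial vector")
  if (all(hip == ankle)) stopf("hip and ankle landmarks coincide")
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  dot <- sum(v1 * v2)
  ang <- atan2(cross, dot) * 180 / pi
  ang %% 360
}

#' Compare two sets of HKA angles
#'
#' Summary comparison of angle measurements from two stitching sources:
#' per-set mean and sample standard deviation (n-1 denominator), the
#' mean difference, and a t test (paired, or Welch two-sample). A
#' paired comparison with zero-variance differences (e.g. identical
#' sets) reports `p = 1` with a warning rather than `NaN`.
#'
#' @param a,b Numeric vectors of angles in degrees (`n >= 2`; equal
#'   lengths when `paired`).
#' @param paired Use a paired t test (default `TRUE`, matching a
#'   per-subject comparison of two stitching methods).
#' @return A list: `n`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `mean_difference`, `t`, `p_value`, `paired`.
#' @export
compare_angle_sets <- function(a, b, paired = TRUE) {
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b))
    stopf("angle sets must be numeric with no missing values")
  if (length(a) < 2L || length(b) < 2L)
    stopf("each angle set needs at least two values")
  if (paired && length(a) != length(b))
    stopf("paired comparison requires equal-length sets")

  out <- list(n = c(length(a), length(b)),
              mean_a = mean(a), sd_a = stats::sd(a),
              mean_b = mean(b), sd_b = stats::sd(b),
              mean_difference = mean(a) - mean(b),
              paired = paired)
  if (paired) out$mean_difference <- mean(a - b)

  zero_var <- if (paired) stats::sd(a - b) == 0 else
    (stats::sd(a) == 0 && stats::sd(b) == 0)
  if (zero_var) {
    warnf("zero-variance comparison: reporting p = 1 by convention")
    out$t <- 0
    out$p_value <- 1
    return(out)
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
  out$t <- unname(tt$statistic)
  out$p_value <- tt$p.value
  out
}
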