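# Periodized orthogonal 2-D discrete wavelet transform. No wavelet
# package ships with the R stack this package targets, so the transform
# is implemented here: analysis/synthesis with orthonormal filter pairs
# under periodic extension, which gives exact perfect reconstruction for
# any even signal length.

wavelet_filters <- function(family) {
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    stopf("unknown wavelet family '%s' (available: haar, db2)", family))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # quadrature mirror highpass
  list(h = h, g = g)
}

# One analysis level along the rows of X (column-major matrix): returns
# the lowpass and highpass halves, each nrow(X)/2 rows.
dwt_step_rows <- function(X, h, g) {
  N <- nrow(X)
  if (N %% 2L != 0L) stopf("signal length must be even")
  N2 <- N %/% 2L
  A <- matrix(0, N2, ncol(X))
  D <- matrix(0, N2, ncol(X))
  base <- 2L * (seq_len(N2) - 1L)
  for (n in seq_along(h)) {
    rows <- (base + (n - 1L)) %% N + 1L
    A <- A + h[n] * X[rows, , drop = FALSE]
    D <- D + g[n] * X[rows, , drop = FALSE]
  }
  list(A = A, D = D)
}

idwt_step_rows <- function(A, D, h, g) {
  N2 <- nrow(A)
  N <- 2L * N2
  Y <- matrix(0, N, ncol(A))
  base <- 2L * (seq_len(N2) - 1L)
  for (n in seq_along(h)) {
    rows <- (base + (n - 1L)) %% N + 1L
    Y[rows, ] <- Y[rows, , drop = FALSE] + h[n] * A
    Y[rows, ] <- Y[rows, , drop = FALSE] + g[n] * D
  }
  Y
}

dwt2_level <- function(X, h, g) {
  r <- dwt_step_rows(X, h, g)
  a <- dwt_step_rows(t(r$A), h, g)
  d <- dwt_step_rows(t(r$D), h, g)
  list(LL = t(a$A), LH = t(a$D), HL = t(d$A), HH = t(d$D))
}

idwt2_level <- function(cf, h, g) {
  A <- t(idwt_step_rows(t(cf$LL), t(cf$LH), h, g))
  D <- t(idwt_step_rows(t(cf$HL), t(cf$HH), h, g))
  idwt_step_rows(A, D, h, g)
}

# Multilevel decomposition: list of per-level detail triples (fine to
# coarse) plus the final approximation.
dwt2_multilevel <- function(X, levels, h, g) {
  details <- vector("list", levels)
  cur <- X
  for (l in seq_len(levels)) {
    cf <- dwt2_level(cur, h, g)
    details[[l]] <- cf[c("LH", "HL", "HH")]
    cur <- cf$LL
  }
  list(details = details, approx = cur)
}

idwt2_multilevel <- function(pyr, h, g) {
  cur <- pyr$approx
  for (l in rev(seq_along(pyr$details))) {
    cf <- pyr$details[[l]]
    cur <- idwt2_level(list(LL = cur, LH = cf$LH, HL = cf$HL, HH = cf$HH),
                       h, g)
  }
  cur
}

# Symmetric padding of a matrix up to target dimensions (padding split
# between the leading and trailing sides).
pad_to <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  ext <- function(n, n2) {
    extra <- n2 - n
    lo <- extra %/% 2L
    hi <- extra - lo
    # mirrored indices; repeats are fine because lo, hi <= n here
    c(rev(seq_len(lo)), seq_len(n), n + 1L - seq_len(hi))
  }
  m[ext(H, H2), ext(W, W2), drop = FALSE]
}

#' Wavelet blending configuration
#'
#' Settings for overlap fusion: the orthonormal wavelet family, the
#' number of decomposition levels, and the blending weight theta. With a
#' single theta the blend of coefficients equals (by linearity of the
#' transform) the per-pixel convex combination `theta*i1 + (1-theta)*i2`
#' regardless of family; a per-scale theta vector (one entry per level,
#' fine to coarse; the approximation band uses the last entry) lets the
#' fusion favor one tile at selected scales.
#'
#' @param wavelet `"haar"` (default) or `"db2"`.
#' @param levels Number of decomposition levels (>= 1, default 3);
#'   automatically reduced for strips smaller than `2^levels`.
#' @param theta Blend weight(s) in `[0, 1]`: scalar or one value per
#'   level.
#' @return An object of class `blend_config`.
#' @export
blend_config <- function(wavelet = "haar", levels = 3, theta = 0.5) {
  wavelet_filters(wavelet)  # validates the family
  assert_scalar_number(levels, "levels", lo = 1)
  if (!is.numeric(theta) || length(theta) < 1L ||
      any(theta < 0) || any(theta > 1))
    stopf("`theta` entries must lie in [0, 1]")
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 theta = as.numeric(theta)),
            class = "blend_config")
}

#' Blend two aligned overlap strips in the wavelet domain
#'
#' Both strips are symmetrically padded to dimensions divisible by
#' `2^levels`, decomposed with the configured multilevel orthonormal
#' DWT, combined coefficient-by-coefficient as
#' `W = theta * W1 + (1 - theta) * W2` at each scale, inverse
#' transformed, cropped back to the strip shape and clipped to `[0, 1]`.
#' Strips smaller than `2^levels` in either dimension are blended with
#' correspondingly fewer levels (down to a plain pixel blend).
#'
#' @param i1,i2 Numeric matrices (or [radiograph()]s) of identical
#'   shape, intensities in `[0, 1]`.
#' @param cfg A [blend_config()].
#' @return The blended strip as a numeric matrix.
#' @export
wavelet_blend <- function(i1, i2, cfg = blend_config()) {
  m1 <- if (inherits(i1, "radiograph")) i1$pixels else i1
  m2 <- if (inherits(i2, "radiograph")) i2$pixels else i2
  if (!identical(dim(m1), dim(m2)))
    stopf("overlap strips must share the same shape")
  stopifnot(inherits(cfg, "blend_config"))
  H <- nrow(m1); W <- ncol(m1)

  J <- min(cfg$levels, floor(log2(H)), floor(log2(W)))
  if (J < 1L) {
    th <- cfg$theta[1]
    return(clip01(th * m1 + (1 - th) * m2))
  }
  th <- cfg$theta
  if (length(th) == 1L) th <- rep(th, J)
  if (length(th) < J)
    stopf("`theta` must be scalar or supply one value per level (%d)", J)
  th <- th[seq_len(J)]

  f <- wavelet_filters(cfg$wavelet)
  H2 <- as.integer(ceiling(H / 2^J) * 2^J)
  W2 <- as.integer(ceiling(W / 2^J) * 2^J)
  p1 <- dwt2_multilevel(pad_to(m1, H2, W2), J, f$h, f$g)
  p2 <- dwt2_multilevel(pad_to(m2, H2, W2), J, f$h, f$g)

  blended <- p1
  for (l in seq_len(J)) {
    blended$details[[l]] <- Map(function(a, b) th[l] * a + (1 - th[l]) * b,
                                p1$details[[l]], p2$details[[l]])
  }
  blended$approx <- th[J] * p1$approx + (1 - th[J]) * p2$approx

  out <- idwt2_multilevel(blended, f$h, f$g)
  r0 <- (H2 - H) %/% 2L
  c0 <- (W2 - W) %/% 2L
  clip01(out[r0 + seq_len(H), c0 + seq_len(W), drop = FALSE])
}

#' Compose three registered tiles into a full-length canvas
#'
#' Places the hip, knee and ankle tiles on a shared canvas using the
#' two registration results: the canvas height is
#' `h1 + h2 + h3 - dy12 - dy23` and the width is the union of the
#' horizontally shifted tile extents (columns covered by no tile are
#' zero-filled and flagged as padding in the report). Rows outside the
#' overlaps are copied verbatim from their source tile; each overlap's
#' column intersection is replaced by the wavelet blend of the two
#' aligned strips, and columns covered by only one tile keep that
#' tile's pixels.
#'
#' @param tiles List of three [radiograph()]s in hip, knee, ankle order.
#' @param reg12,reg23 `registration_result`s for the hip-knee and
#'   knee-ankle pairs (see [find_offset()]).
#' @param cfg A [blend_config()].
#' @return List with `stitched` (a [radiograph()]) and `report` (class
#'   `stitch_report`): offsets, matching distances, canvas dimensions,
#'   blend settings, tile placements and warnings.
#' @export
compose_canvas <- function(tiles, reg12, reg23, cfg = blend_config()) {
  if (length(tiles) != 3L || !all(vapply(tiles, inherits, TRUE, "radiograph")))
    stopf("`tiles` must be a list of three radiographs (hip, knee, ankle)")
  stopifnot(inherits(reg12, "registration_result"),
            inherits(reg23, "registration_result"))
  px <- lapply(tiles, `[[`, "pixels")
  hh <- vapply(px, nrow, 1L)
  ww <- vapply(px, ncol, 1L)
  dy12 <- reg12$dy; dy23 <- reg23$dy
  if (dy12 >= min(hh[1], hh[2]) || dy23 >= min(hh[2], hh[3]))
    stopf("overlap height equals or exceeds a tile height")
  if (dy12 + dy23 >= hh[2])
    stopf("the two overlaps exhaust the middle tile (%d + %d >= %d rows)",
          dy12, dy23, hh[2])

  # tile placements (0-based offsets on the canvas)
  row0 <- c(0L, hh[1] - dy12, hh[1] - dy12 + hh[2] - dy23)
  colr <- c(0L, reg12$dx, reg12$dx + reg23$dx)
  col0 <- colr - min(colr)
  Hc <- sum(hh) - dy12 - dy23
  Wc <- max(col0 + ww)

  canvas <- matrix(0, Hc, Wc)
  covered <- matrix(FALSE, Hc, Wc)
  for (i in 1:3) {
    rows <- row0[i] + seq_len(hh[i])
    cols <- col0[i] + seq_len(ww[i])
    canvas[rows, cols] <- px[[i]]
    covered[rows, cols] <- TRUE
  }

  blend_overlap <- function(upper, lower, dy, up_idx, lo_idx) {
    # column intersection in canvas coordinates
    clo <- max(col0[up_idx], col0[lo_idx]) + 1L
    chi <- min(col0[up_idx] + ww[up_idx], col0[lo_idx] + ww[lo_idx])
    if (chi < clo) return(invisible(NULL))
    rows <- row0[lo_idx] + seq_len(dy)
    s_up <- upper[(hh[up_idx] - dy + 1L):hh[up_idx],
                  (clo - col0[up_idx]):(chi - col0[up_idx]), drop = FALSE]
    s_lo <- lower[seq_len(dy),
                  (clo - col0[lo_idx]):(chi - col0[lo_idx]), drop = FALSE]
    canvas[rows, clo:chi] <<- wavelet_blend(s_up, s_lo, cfg)
    invisible(NULL)
  }
  blend_overlap(px[[1]], px[[2]], dy12, 1L, 2L)
  blend_overlap(px[[2]], px[[3]], dy23, 2L, 3L)

  warnings <- character(0)
  if (reg12$low_confidence)
    warnings <- c(warnings, "hip-knee registration is low confidence")
  if (reg23$low_confidence)
    warnings <- c(warnings, "knee-ankle registration is low confidence")

  report <- structure(
    list(offsets = list(
           hip_knee = c(dx = reg12$dx, dy = reg12$dy),
           knee_ankle = c(dx = reg23$dx, dy = reg23$dy)),
         matching_distances = c(hip_knee = reg12$matching_distance,
                                knee_ankle = reg23$matching_distance),
         canvas = c(height = Hc, width = Wc),
         blend = unclass(cfg),
         placements = data.frame(tile = c("hip", "knee", "ankle"),
                                 row0 = row0, col0 = col0,
                                 height = hh, width = ww),
         padding = any(!covered),
         warnings = warnings),
    class = "stitch_report")

  list(stitched = radiograph(clip01(canvas), part_label = "stitched"),
       report = report)
}
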