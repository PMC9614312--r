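#' Edge map objects
#'
#' Binary bone-edge maps: an `H x W` grid with 1 marking an edge pixel
#' and 0 a non-edge pixel, plus the resolved hysteresis thresholds that
#' produced it.
#'
#' @param edges Numeric/integer matrix of 0/1 values.
#' @param low_threshold,high_threshold Gradient-magnitude thresholds,
#'   `0 <= low <= high`.
#' @return An object of class `edge_map` with fields `edges`,
#'   `low_threshold`, `high_threshold`, `n_edge_pixels`.
#' @export
edge_map <- function(edges, low_threshold = 0, high_threshold = 0) {
  if (!is.matrix(edges)) stopf("`edges` must be a matrix")
  if (!all(edges %in% c(0, 1))) stopf("edge map values must be 0 or 1")
  if (low_threshold < 0 || low_threshold > high_threshold)
    stopf("thresholds must satisfy 0 <= low <= high")
  e <- matrix(as.numeric(edges), nrow(edges), ncol(edges))
  structure(list(edges = e,
                 low_threshold = low_threshold,
                 high_threshold = high_threshold,
                 n_edge_pixels = sum(e)),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %d x %d, %d edge pixels, thresholds [%.4g, %.4g]\n",
              nrow(x$edges), ncol(x$edges), x$n_edge_pixels,
              x$low_threshold, x$high_threshold))
  invisible(x)
}

#' Sobel gradient magnitude and direction
#'
#' 3x3 Sobel responses under symmetric borders. `gx` responds to
#' intensity change along columns and `gy` along rows; the magnitude is
#' the Euclidean norm of the pair and the direction `atan2(gy, gx)` lies
#' in `(-pi, pi]`.
#'
#' @param r A (smoothed) [radiograph()].
#' @return List with matrices `magnitude` and `direction`.
#' @export
sobel_gradients <- function(r) {
  stopifnot(inherits(r, "radiograph"))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dcol
  ky <- t(kx)                                                 # d/drow
  gx <- filter2_sym(r$pixels, kx)
  gy <- filter2_sym(r$pixels, ky)
  list(magnitude = sqrt(gx^2 + gy^2), direction = atan2(gy, gx))
}

#' Non-maximum suppression of a gradient field
#'
#' Thins the gradient magnitude to ridge pixels: each pixel is kept only
#' if its magnitude is `>=` both of its neighbors along the gradient
#' direction, quantized to the nearest of four bins (0, 45, 90, 135
#' degrees). The `>=` tie rule keeps every genuine maximum on plateaus;
#' duplicate plateau pixels are tolerated downstream. Neighbors outside
#' the image count as zero.
#'
#' @param magnitude,direction Matrices from [sobel_gradients()].
#' @return The thinned magnitude matrix (suppressed pixels set to 0).
#' @export
non_maximum_suppression <- function(magnitude, direction) {
  if (!identical(dim(magnitude), dim(direction)))
    stopf("`magnitude` and `direction` must share a shape")
  H <- nrow(magnitude); W <- ncol(magnitude)

  shift <- function(m, dr, dc) {
    # value of m at (r + dr, c + dc), zero outside
    out <- matrix(0, H, W)
    rs <- max(1L, 1L + dr):min(H, H + dr)
    cs <- max(1L, 1L + dc):min(W, W + dc)
    out[rs - dr, cs - dc] <- m[rs, cs]
    out
  }

  # quantize direction (mod 180 deg) into 4 bins
  ang <- direction * 180 / pi
  ang <- ang %% 180
  bin <- integer(length(ang))
  bin[(ang < 22.5) | (ang >= 157.5)] <- 0L   # gradient along columns
  bin[ang >= 22.5 & ang < 67.5]  <- 1L       # diagonal (down-right)
  bin[ang >= 67.5 & ang < 112.5] <- 2L       # gradient along rows
  bin[ang >= 112.5 & ang < 157.5] <- 3L      # diagonal (down-left)
  bin <- matrix(bin, H, W)

  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  pairs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (b in 0:3) {
    d <- pairs[[as.character(b)]]
    sel <- bin == b
    if (!any(sel)) next
    a <- shift(magnitude, d[1], d[2])
    z <- shift(magnitude, -d[1], -d[2])
    n1[sel] <- a[sel]
    n2[sel] <- z[sel]
  }
  keep <- (magnitude >= n1) & (magnitude >= n2) & (magnitude > 0)
  out <- magnitude
  out[!keep] <- 0
  out
}

#' Double-threshold hysteresis
#'
#' Pixels with thinned magnitude `>= high` are strong seeds; pixels in
#' `[low, high)` are kept only when 8-connected (transitively) to a
#' seed. The connected sweep is a frontier BFS over the weak mask.
#'
#' @param thinned Thinned magnitude matrix from
#'   [non_maximum_suppression()].
#' @param low,high Thresholds, `0 <= low <= high`.
#' @return An [edge_map()].
#' @export
hysteresis_threshold <- function(thinned, low, high) {
  if (!is.matrix(thinned)) stopf("`thinned` must be a matrix")
  if (low > high) stopf("`low` must not exceed `high`")
  if (low < 0) stopf("thresholds must be nonnegative")
  H <- nrow(thinned); W <- ncol(thinned)
  weak <- thinned >= low & thinned > 0
  keep <- thinned >= high & thinned > 0

  frontier <- which(keep)
  while (length(frontier)) {
    r <- (frontier - 1L) %% H + 1L
    c <- (frontier - 1L) %/% H + 1L
    nxt <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nr <- r + dr; nc <- c + dc
      ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
      if (!any(ok)) next
      idx <- (nc[ok] - 1L) * H + nr[ok]
      idx <- idx[weak[idx] & !keep[idx]]
      if (length(idx)) {
        keep[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  edge_map(matrix(as.numeric(keep), H, W),
           low_threshold = low, high_threshold = high)
}

#' Canny configuration
#'
#' Threshold resolution for [canny()]. In `"percentile"` mode (the
#' default) the high threshold is a quantile of the nonzero thinned
#' gradient magnitudes and the low threshold a fixed fraction of it,
#' which keeps the detector robust to exposure differences between
#' tiles; `"absolute"` mode takes both thresholds in gradient-magnitude
#' units.
#'
#' @param threshold_mode `"percentile"` or `"absolute"`.
#' @param high_quantile Quantile (0-1) defining the high threshold in
#'   percentile mode; default 0.9 (the 90th percentile).
#' @param low_fraction Low threshold as a fraction of the high one in
#'   percentile mode; default 0.4.
#' @param low,high Absolute thresholds (required in absolute mode).
#' @param sigma Gaussian smoothing sigma passed to [gaussian_smooth()].
#' @param exclude_bright_quantile Optional intensity quantile (0-1):
#'   pixels whose smoothed intensity exceeds it are barred from being
#'   edge pixels (a guard against saturated bright regions far from
#'   bone contours); `NULL` (default) disables the mask.
#' @return An object of class `canny_config`.
#' @export
canny_config <- function(threshold_mode = c("percentile", "absolute"),
                         high_quantile = 0.9, low_fraction = 0.4,
                         low = NULL, high = NULL, sigma = 1,
                         exclude_bright_quantile = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  assert_scalar_number(high_quantile, "high_quantile", lo = 0, hi = 1)
  assert_scalar_number(low_fraction, "low_fraction", lo = 0, hi = 1)
  assert_scalar_number(sigma, "sigma")
  if (sigma <= 0) stopf("`sigma` must be positive")
  if (threshold_mode == "absolute") {
    if (is.null(low) || is.null(high))
      stopf("absolute mode requires `low` and `high`")
    if (low > high || low < 0) stopf("need 0 <= low <= high")
  }
  if (!is.null(exclude_bright_quantile))
    assert_scalar_number(exclude_bright_quantile, "exclude_bright_quantile",
                         lo = 0, hi = 1)
  structure(list(threshold_mode = threshold_mode,
                 high_quantile = high_quantile, low_fraction = low_fraction,
                 low = low, high = high, sigma = sigma,
                 exclude_bright_quantile = exclude_bright_quantile),
            class = "canny_config")
}

#' Canny edge detection
#'
#' Full bone-edge extraction chain: 5x5 Gaussian smoothing, Sobel
#' gradients, non-maximum suppression, double-threshold hysteresis.
#' Thresholds are resolved from the configuration (percentile mode uses
#' the nonzero thinned magnitudes) and recorded in the returned edge
#' map. A degenerate image with zero gradient everywhere yields an empty
#' edge map with a warning rather than an error.
#'
#' @param r A [radiograph()] (unsmoothed; smoothing is applied here).
#' @param config A [canny_config()].
#' @return An [edge_map()].
#' @export
canny <- function(r, config = canny_config()) {
  stopifnot(inherits(r, "radiograph"), inherits(config, "canny_config"))
  sm <- gaussian_smooth(r, config$sigma)
  g <- sobel_gradients(sm)
  thin <- non_maximum_suppression(g$magnitude, g$direction)
  # convolution arithmetic leaves O(eps) residue on flat regions; such
  # pixels are not gradients and must not enter the percentile pool
  thin[thin <= 1e-9] <- 0

  if (!is.null(config$exclude_bright_quantile)) {
    cut <- stats::quantile(sm$pixels, config$exclude_bright_quantile,
                           names = FALSE)
    thin[sm$pixels > cut] <- 0
  }

  nz <- thin[thin > 0]
  if (length(nz) == 0L) {
    warnf("degenerate image: zero gradient everywhere, returning empty edge map")
    return(edge_map(matrix(0, nrow(thin), ncol(thin)), 0, 0))
  }
  if (config$threshold_mode == "percentile") {
    high <- stats::quantile(nz, config$high_quantile, names = FALSE)
    low <- config$low_fraction * high
  } else {
    high <- config$high
    low <- config$low
  }
  hysteresis_threshold(thin, low, high)
}
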