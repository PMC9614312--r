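# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lo || x > hi)
    stopf("`%s` = %g is outside [%g, %g]", name, x, lo, hi)
  invisible(x)
}

# Symmetric (edge-inclusive) padding of a matrix by k rows and columns,
# the border handling used by every convolution in the package: it avoids
# the dark halos a zero pad would create at tile borders, which would
# otherwise spawn false Canny edges.
pad_symmetric <- function(m, k) {
  if (k == 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  if (k >= H || k >= W)
    stopf("symmetric pad of %d exceeds image dimensions %dx%d", k, H, W)
  m[c(k:1, 1:H, H:(H - k + 1L)), c(k:1, 1:W, W:(W - k + 1L))]
}

# Cross-correlation of an image with a small odd-sized kernel under
# symmetric borders, done as a sum of shifted copies (fast in R for the
# 3x3 and 5x5 kernels used here).
filter2_sym <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh %% 2L == 0L || kw %% 2L == 0L)
    stopf("kernel must have odd dimensions")
  k <- max((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)
  p <- pad_symmetric(m, k)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  r0 <- k - (kh - 1L) %/% 2L
  c0 <- k - (kw - 1L) %/% 2L
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      w <- kernel[i, j]
      if (w != 0)
        out <- out + w * p[r0 + i - 1L + 1:H, c0 + j - 1L + 1:W, drop = FALSE]
    }
  }
  out
}

clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

# Summed-area table with a leading zero row/column, so that
# sum(m[a:b, c:d]) == ii[b+1, d+1] - ii[a, d+1] - ii[b+1, c] + ii[a, c].
integral_image <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ii <- matrix(0, H + 1L, W + 1L)
  ii[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  ii
}

# Rotate a (row, col) vector by `deg` degrees, in the same orientation
# convention used by hka_angle(): the signed angle from v to rot2(v, deg)
# is deg.
rot2 <- function(v, deg) {
  a <- deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2],
    sin(a) * v[1] + cos(a) * v[2])
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
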