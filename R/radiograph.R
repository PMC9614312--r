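#' Radiograph objects
#'
#' A radiograph is the package's canonical image container: a numeric
#' `H x W` matrix of intensities on `[0, 1]` in (row, col) orientation
#' (origin top-left, row index increasing downward), together with an
#' anatomical part label, the cumulative downsampling factor and an
#' optional source path.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`, at least 8x8.
#' @param part_label One of `"hip"`, `"knee"`, `"ankle"`, `"stitched"`,
#'   `"phantom"`.
#' @param downsample_factor Positive integer, the cumulative factor by
#'   which the image has been downsampled from its source.
#' @param source_path Optional path of the file the image was read from.
#'
#' @return An object of class `radiograph` with fields `pixels`,
#'   `part_label`, `downsample_factor`, `source_path`.
#' @export
#' @examples
#' r <- radiograph(matrix(runif(64), 8, 8), "phantom")
#' dim(r)
radiograph <- function(pixels, part_label = "phantom",
                       downsample_factor = 1L, source_path = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stopf("radiograph must be at least 8x8, got %dx%d",
          nrow(pixels), ncol(pixels))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stopf("radiograph intensities must lie in [0, 1] with no missing values")
  part_label <- match.arg(part_label,
                          c("hip", "knee", "ankle", "stitched", "phantom"))
  assert_scalar_number(downsample_factor, "downsample_factor", lo = 1)
  structure(
    list(pixels = pixels, part_label = part_label,
         downsample_factor = as.integer(downsample_factor),
         source_path = source_path),
    class = "radiograph")
}

#' @export
dim.radiograph <- function(x) dim(x$pixels)

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %s, %d x %d px, downsample x%d\n",
              x$part_label, nrow(x$pixels), ncol(x$pixels),
              x$downsample_factor))
  if (!is.null(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' Read a radiograph tile from an image file
#'
#' Reads a JPG/PNG/TIFF image (8- or 16-bit grayscale, or RGB), converts
#' color to grayscale by Rec. 709 luminance, rescales intensities to
#' `[0, 1]` and attaches the anatomical part label. Tiles are expected in
#' hip, knee, ankle order downstream.
#'
#' @param path Path to an image file.
#' @param part_label Anatomical label, see [radiograph()].
#' @return A [radiograph()].
#' @export
load_radiograph <- function(path, part_label = "phantom") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stopf("image file not found: %s", as.character(path)[1])
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stopf("cannot read image '%s': %s",
                                            path, conditionMessage(e)))
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3L) {
    # color planes are stored as (x, y, channel); drop alpha, take luminance
    nc <- dim(px)[3L]
    if (nc >= 3L) {
      px <- 0.2126 * px[, , 1L] + 0.7152 * px[, , 2L] + 0.0722 * px[, , 3L]
    } else {
      px <- px[, , 1L]
    }
  }
  px <- t(px)  # EBImage stores x (=column) first; we use (row, col)
  radiograph(clip01(px), part_label = part_label, source_path = path)
}

#' Write a radiograph (or plain matrix) as an image file
#'
#' @param x A [radiograph()] or numeric matrix in `[0, 1]`.
#' @param path Output path; the format is chosen from the extension
#'   (png/jpg/tiff).
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(x, path) {
  m <- if (inherits(x, "radiograph")) x$pixels else x
  EBImage::writeImage(EBImage::Image(t(m)), path)
  invisible(path)
}

#' Downsample a radiograph by block averaging
#'
#' Each output pixel is the mean of a `factor x factor` block of input
#' pixels; trailing rows/columns that do not fill a block are dropped.
#' Block means act as the anti-alias filter, and the radiograph's
#' cumulative `downsample_factor` is multiplied by `factor`.
#'
#' @param r A [radiograph()].
#' @param factor Positive integer downsampling factor.
#' @return A [radiograph()] of size `floor(H/factor) x floor(W/factor)`.
#' @export
downsample <- function(r, factor) {
  stopifnot(inherits(r, "radiograph"))
  assert_scalar_number(factor, "factor", lo = 1)
  f <- as.integer(factor)
  if (f != factor) stopf("`factor` must be an integer")
  if (f == 1L) return(r)
  m <- r$pixels
  H2 <- nrow(m) %/% f
  W2 <- ncol(m) %/% f
  if (H2 < 8L || W2 < 8L)
    stopf("downsampling by %d would leave an image smaller than 8x8", f)
  m <- m[seq_len(H2 * f), seq_len(W2 * f), drop = FALSE]
  y <- colMeans(array(m, c(f, H2, W2 * f)))        # average row groups
  z <- t(colMeans(array(t(y), c(f, W2, H2))))      # average column groups
  radiograph(z, part_label = r$part_label,
             downsample_factor = r$downsample_factor * f,
             source_path = r$source_path)
}

#' 5x5 Gaussian kernel
#'
#' The normalized 5x5 kernel used by [gaussian_smooth()]: an outer
#' product of 1-D Gaussians sampled at integer offsets -2..2, rescaled to
#' sum to one.
#'
#' @param sigma Positive standard deviation in pixels.
#' @return A 5x5 numeric matrix with nonnegative entries summing to 1.
#' @export
gaussian_kernel5 <- function(sigma = 1) {
  assert_scalar_number(sigma, "sigma")
  if (sigma <= 0) stopf("`sigma` must be positive")
  g <- exp(-(-2:2)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Smooth a radiograph with a 5x5 Gaussian filter
#'
#' Noise suppression stage applied before edge detection: convolution
#' with a normalized 5x5 Gaussian kernel under symmetric (mirrored)
#' borders. Output has the same shape and stays in `[0, 1]`.
#'
#' @param r A [radiograph()].
#' @param sigma Kernel standard deviation in pixels (default 1, the
#'   standard choice for a 5-tap support).
#' @return A smoothed [radiograph()].
#' @export
gaussian_smooth <- function(r, sigma = 1) {
  stopifnot(inherits(r, "radiograph"))
  k <- gaussian_kernel5(sigma)
  out <- clip01(filter2_sym(r$pixels, k))
  radiograph(out, part_label = r$part_label,
             downsample_factor = r$downsample_factor,
             source_path = r$source_path)
}

#' Add pixelwise Gaussian noise to a radiograph
#'
#' Additive zero-mean Gaussian noise clipped back to `[0, 1]`, the noise
#' model used throughout the phantom experiments (applied independently
#' per tile to emulate exposure-to-exposure detector noise).
#'
#' @param r A [radiograph()].
#' @param sd Noise standard deviation on the `[0, 1]` intensity scale.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A [radiograph()].
#' @export
add_noise <- function(r, sd, seed) {
  stopifnot(inherits(r, "radiograph"))
  assert_scalar_number(sd, "sd", lo = 0)
  if (sd == 0) return(r)
  m <- r$pixels
  noisy <- with_seed(seed, m + matrix(stats::rnorm(length(m), 0, sd),
                                      nrow(m), ncol(m)))
  radiograph(clip01(noisy), part_label = r$part_label,
             downsample_factor = r$downsample_factor,
             source_path = r$source_path)
}
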