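#' Specify a synthetic leg phantom
#'
#' Describes a full-length lower-limb phantom: two capsule-shaped
#' "bones" (femur and tibia) meeting at the knee, rendered inside a
#' soft-tissue silhouette whose radius varies along each axis (a
#' tapering thigh and a bulging calf) against an air background. Every
#' boundary carries a smooth cortical-edge intensity ramp so a gradient
#' edge detector fires cleanly on the contour, and the converging skin
#' boundaries make the tile-to-tile translation well-posed even along
#' straight bone shafts (a featureless parallel-edged shaft would leave
#' the registration free to slide along the bone axis). The default
#' intensity steps air -> soft tissue -> bone are equal so both edge
#' families present the same gradient magnitude to the detector.
#'
#' The tibial axis is derived from the femoral axis by rotating it so
#' the knee angle is exactly `180 + varus_valgus_deg` under the sign
#' convention of [hka_angle()], which makes the programmed HKA angle an
#' identity by construction.
#'
#' The default canvas (852 x 830) mirrors a 3408 x 3320 clinical
#' acquisition downsampled by 4, i.e. desk-scale but proportionate to
#' real full-length studies.
#'
#' @param canvas_height,canvas_width Canvas dimensions in pixels.
#' @param hip_center,knee_center Femoral axis endpoints as `(row, col)`.
#' @param tibia_length Tibial axis length in pixels (defaults to the
#'   femoral length).
#' @param varus_valgus_deg Signed deviation from a straight 180-degree
#'   leg, in degrees; positive values give a reported HKA of
#'   `180 + varus_valgus_deg`.
#' @param bone_halfwidth Capsule half-width in pixels (>= 2).
#' @param edge_ramp Width in pixels of the linear intensity ramp at the
#'   cortical and skin contours.
#' @param bone_intensity,soft_tissue_intensity,background_intensity
#'   Intensity levels on `[0, 1]` for bone, soft tissue and the air
#'   background; defaults (0.72, 0.37, 0.02) give equal contrast steps.
#' @param soft_tissue Render the soft-tissue silhouette (default
#'   `TRUE`; turning it off leaves bare bones on air).
#' @param texture_amplitude Amplitude of an optional smoothed-noise
#'   background texture (default 0: flat soft-tissue background, which
#'   keeps noiseless edge maps exactly reproducible between tiles).
#' @param noise_sd Additive Gaussian noise standard deviation on the
#'   full canvas (default 0).
#' @param ruler Add a vertical strip of periodic tick marks at the right
#'   border (off by default; cosmetic only, never used by the
#'   algorithm).
#' @param seed Integer seed controlling noise and texture.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(varus_valgus_deg = 6)
#' ph <- generate_phantom(spec)
#' ph$truth$hka_true_deg
phantom_spec <- function(canvas_height = 852, canvas_width = 830,
                         hip_center = c(70, 445), knee_center = c(430, 405),
                         tibia_length = NULL, varus_valgus_deg = 0,
                         bone_halfwidth = 18, edge_ramp = 3,
                         bone_intensity = 0.72, soft_tissue_intensity = 0.37,
                         background_intensity = 0.02, soft_tissue = TRUE,
                         texture_amplitude = 0, noise_sd = 0,
                         ruler = FALSE, seed = 1L) {
  assert_scalar_number(canvas_height, "canvas_height", lo = 96)
  assert_scalar_number(canvas_width, "canvas_width", lo = 64)
  assert_scalar_number(varus_valgus_deg, "varus_valgus_deg", lo = -45, hi = 45)
  assert_scalar_number(bone_halfwidth, "bone_halfwidth")
  if (bone_halfwidth < 2) stopf("`bone_halfwidth` must be >= 2")
  assert_scalar_number(edge_ramp, "edge_ramp", lo = 1)
  assert_scalar_number(noise_sd, "noise_sd", lo = 0)
  assert_scalar_number(texture_amplitude, "texture_amplitude", lo = 0, hi = 0.5)
  assert_scalar_number(bone_intensity, "bone_intensity", lo = 0, hi = 1)
  assert_scalar_number(soft_tissue_intensity, "soft_tissue_intensity",
                       lo = 0, hi = 1)
  assert_scalar_number(background_intensity, "background_intensity",
                       lo = 0, hi = 1)
  if (length(hip_center) != 2L || length(knee_center) != 2L)
    stopf("`hip_center` and `knee_center` must be (row, col) pairs")

  femur_vec <- hip_center - knee_center
  femur_len <- sqrt(sum(femur_vec^2))
  if (femur_len < 8) stopf("femoral axis is degenerate (length %.1f px)",
                           femur_len)
  tibia_length <- tibia_length %||% femur_len
  assert_scalar_number(tibia_length, "tibia_length", lo = 8)
  # knee->ankle direction such that the signed knee angle is 180 + vv
  u <- rot2(femur_vec / femur_len, 180 + varus_valgus_deg)
  ankle_center <- knee_center + tibia_length * u

  pts <- rbind(hip_center, knee_center, ankle_center)
  margin <- bone_halfwidth + edge_ramp + 2
  if (any(pts[, 1] < margin) || any(pts[, 1] > canvas_height - margin) ||
      any(pts[, 2] < margin) || any(pts[, 2] > canvas_width - margin))
    stopf("bone axis endpoints (plus bone width) must lie inside the canvas")
  if (isTRUE(soft_tissue)) {
    # silhouette may clip at the top/bottom (like a real field of view)
    # but must fit horizontally so no skin edge touches the canvas sides
    bulge <- knee_center + 0.33 * tibia_length * u
    ext <- max(hip_center[2] + 0.29 * femur_len,
               bulge[2] + 0.19 * tibia_length) + edge_ramp
    ext_lo <- min(hip_center[2] - 0.29 * femur_len,
                  bulge[2] - 0.19 * tibia_length) - edge_ramp
    if (ext > canvas_width - 2 || ext_lo < 2)
      stopf("soft-tissue silhouette would clip the canvas sides")
  }

  structure(
    list(canvas_height = as.integer(canvas_height),
         canvas_width = as.integer(canvas_width),
         femur_axis = list(hip = as.numeric(hip_center),
                           knee = as.numeric(knee_center)),
         tibia_axis = list(knee = as.numeric(knee_center),
                           ankle = as.numeric(ankle_center)),
         varus_valgus_deg = varus_valgus_deg,
         bone_halfwidth = bone_halfwidth, edge_ramp = edge_ramp,
         bone_intensity = bone_intensity,
         soft_tissue_intensity = soft_tissue_intensity,
         background_intensity = background_intensity,
         soft_tissue = isTRUE(soft_tissue),
         texture_amplitude = texture_amplitude,
         noise_sd = noise_sd, ruler = isTRUE(ruler),
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# Projection of every canvas pixel onto the segment p--q (all
# (row, col)): returns the clamped axial parameter t in [0, 1] and the
# distance to the projected point.
segment_projection_grid <- function(H, W, p, q) {
  rg <- matrix(rep(seq_len(H), W), H, W)
  cg <- matrix(rep(seq_len(W), each = H), H, W)
  v <- q - p
  len2 <- sum(v^2)
  tt <- ((rg - p[1]) * v[1] + (cg - p[2]) * v[2]) / len2
  tt[tt < 0] <- 0
  tt[tt > 1] <- 1
  d <- sqrt((rg - (p[1] + tt * v[1]))^2 + (cg - (p[2] + tt * v[2]))^2)
  list(t = tt, d = d)
}

segment_distance_grid <- function(H, W, p, q) {
  segment_projection_grid(H, W, p, q)$d
}

# Membership weight (0 = outside, 1 = inside) of a capsule whose radius
# varies along the axis, with a linear boundary ramp of width `ramp`.
capsule_weight <- function(proj, radius, ramp) {
  w <- (radius + ramp / 2 - proj$d) / ramp
  w[w < 0] <- 0
  w[w > 1] <- 1
  w
}

# Soft-tissue silhouette radii as fractions of the axis length:
# a thigh tapering from hip to knee and a calf that bulges in its upper
# third and slims toward the ankle.
thigh_radius <- function(t, len) (0.29 - 0.125 * t) * len
calf_radius <- function(t, len) {
  (0.095 + 0.095 * exp(-((t - 0.33) / 0.26)^2)) * len
}

#' Generate a synthetic leg phantom with ground truth
#'
#' Renders the phantom described by a [phantom_spec()] and returns both
#' the full-canvas radiograph and the ground truth needed to validate
#' every stage of the stitching pipeline: the three landmark centers,
#' the programmed HKA angle, and (after [tile_phantom()]) the true
#' inter-tile offsets. Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (a [radiograph()]) and `truth`
#'   (class `phantom_truth`: `hip_center`, `knee_center`, `ankle_center`
#'   in full-canvas `(row, col)` coordinates, `hka_true_deg`, and
#'   `true_offset_12`/`true_offset_23` filled in by [tile_phantom()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$canvas_height; W <- spec$canvas_width
  hip <- spec$femur_axis$hip
  knee <- spec$femur_axis$knee
  ankle <- spec$tibia_axis$ankle

  img <- matrix(spec$background_intensity, H, W)
  if (spec$texture_amplitude > 0) {
    tex <- with_seed(spec$seed + 1L,
                     matrix(stats::rnorm(H * W), H, W))
    k <- gaussian_kernel5(2)
    for (i in 1:3) tex <- filter2_sym(tex, k)   # low-frequency field
    tex <- tex / max(abs(tex))
    img <- img + spec$texture_amplitude * tex
  }

  pf <- segment_projection_grid(H, W, hip, knee)
  pt <- segment_projection_grid(H, W, knee, ankle)

  if (spec$soft_tissue) {
    lf <- sqrt(sum((hip - knee)^2))
    lt <- sqrt(sum((ankle - knee)^2))
    w_skin <- pmax(
      capsule_weight(pf, thigh_radius(pf$t, lf), spec$edge_ramp),
      capsule_weight(pt, calf_radius(pt$t, lt), spec$edge_ramp))
    img <- img * (1 - w_skin) + spec$soft_tissue_intensity * w_skin
  }

  w_bone <- pmax(
    capsule_weight(pf, spec$bone_halfwidth, spec$edge_ramp),
    capsule_weight(pt, spec$bone_halfwidth, spec$edge_ramp))
  img <- img * (1 - w_bone) + spec$bone_intensity * w_bone

  if (spec$ruler) {
    cols <- (W - 20):(W - 14)
    img[, cols] <- pmax(img[, cols], 0.35)
    ticks <- seq(10, H - 10, by = 50)
    img[ticks, cols] <- 0.95
  }

  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed,
                     img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W))
  }
  img <- clip01(img)

  truth <- structure(
    list(hip_center = hip, knee_center = knee, ankle_center = ankle,
         hka_true_deg = 180 + spec$varus_valgus_deg,
         varus_valgus_deg = spec$varus_valgus_deg,
         true_offset_12 = NULL, true_offset_23 = NULL,
         tile_windows = NULL),
    class = "phantom_truth")

  list(image = radiograph(img, part_label = "phantom"), truth = truth)
}

#' Cut a phantom into three overlapping tiles
#'
#' Cuts the full canvas into hip, knee and ankle tiles that overlap
#' vertically by the requested number of rows, with optional horizontal
#' shifts implemented by cropping laterally displaced windows from the
#' canvas (so all three tiles keep a common width and stay inside the
#' canvas). The bottom `overlap_12` rows of tile 1 and the top
#' `overlap_12` rows of tile 2 show the same anatomy displaced by
#' exactly `(dx_12, 0)`; analogously for the 2-3 pair. The true offsets
#' and tile windows are recorded in the returned truth.
#'
#' Offsets follow the package-wide convention: `dx` is the column shift
#' of the lower tile relative to the upper one, `dy` is the overlap
#' height in rows.
#'
#' @param image Full-canvas [radiograph()] from [generate_phantom()].
#' @param truth The matching `phantom_truth`.
#' @param overlap_12,overlap_23 Overlap heights in rows (strictly
#'   positive, smaller than each adjacent tile height).
#' @param dx_12,dx_23 Integer column shifts of tile 2 relative to tile 1
#'   and tile 3 relative to tile 2.
#' @return A list with `tiles` (list of hip/knee/ankle [radiograph()]s)
#'   and `truth` updated with `true_offset_12`, `true_offset_23`
#'   (each `c(dx, dy)`) and `tile_windows`.
#' @export
tile_phantom <- function(image, truth, overlap_12, overlap_23,
                         dx_12 = 0L, dx_23 = 0L) {
  stopifnot(inherits(image, "radiograph"), inherits(truth, "phantom_truth"))
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  assert_scalar_number(overlap_12, "overlap_12", lo = 1)
  assert_scalar_number(overlap_23, "overlap_23", lo = 1)
  o12 <- as.integer(overlap_12); o23 <- as.integer(overlap_23)
  dx12 <- as.integer(dx_12); dx23 <- as.integer(dx_23)

  non_overlap <- H - o12 - o23
  if (non_overlap < 3L)
    stopf("overlaps (%d + %d rows) leave no room in a %d-row canvas: %s",
          o12, o23, H, "each overlap must be smaller than its tile heights")
  n1 <- non_overlap %/% 3L
  n3 <- non_overlap %/% 3L
  n2 <- non_overlap - n1 - n3
  h1 <- n1 + o12
  h2 <- o12 + n2 + o23
  h3 <- o23 + n3
  if (o12 >= h1 || o12 >= h2 || o23 >= h2 || o23 >= h3)
    stopf("overlap equals or exceeds a tile height (tiles %d/%d/%d rows)",
          h1, h2, h3)

  # lateral window starts; normalized so the leftmost window is at col 1
  c_rel <- c(0L, dx12, dx12 + dx23)
  c0 <- c_rel - min(c_rel)
  Wt <- W - max(c0)
  if (Wt < 8L)
    stopf("horizontal shifts too large for a %d-column canvas", W)

  r0 <- c(0L, n1, n1 + o12 + n2)
  hh <- c(h1, h2, h3)
  labels <- c("hip", "knee", "ankle")
  tiles <- vector("list", 3L)
  for (i in 1:3) {
    rows <- (r0[i] + 1L):(r0[i] + hh[i])
    cols <- (c0[i] + 1L):(c0[i] + Wt)
    tiles[[i]] <- radiograph(image$pixels[rows, cols, drop = FALSE],
                             part_label = labels[i])
  }
  names(tiles) <- labels

  truth$true_offset_12 <- c(dx = dx12, dy = o12)
  truth$true_offset_23 <- c(dx = dx23, dy = o23)
  truth$tile_windows <- data.frame(
    tile = labels, row0 = r0, col0 = c0, height = hh, width = Wt)
  list(tiles = tiles, truth = truth)
}
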