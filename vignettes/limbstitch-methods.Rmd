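---
title: "Edge-based stitching of full-length lower-limb radiographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-based stitching of full-length lower-limb radiographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbstitch)
```

## The problem

Planning a total knee arthroplasty or a high tibial osteotomy requires a
full-length (hip-to-ankle) radiograph, from which the hip–knee–ankle
(HKA) angle of the mechanical axis is read. Flat-panel digital
radiography detectors are smaller than a leg, so the study is acquired
as three overlapping exposures — hip, knee and ankle — that must be
mosaicked into one image. `limbstitch` does this automatically from the
bone and soft-tissue edges alone: no rulers, fiducials or external
markers are needed, and the only free parameters of the motion model
are a per-pair vertical overlap `dy` (in rows) and a lateral shift `dx`
(in columns). No rotation or scaling is modeled: the three exposures
come from the same linear gantry pass over a stationary patient.

## The pipeline

1. **Input and downsampling.** Tiles are read in hip, knee, ankle
   order, converted to `[0, 1]` grayscale by luminance, and block-mean
   downsampled (default factor 4, sized for ~3400-pixel clinical
   acquisitions; factor 1 for images already at desk scale). Block
   means are exact on integer blocks and act as the anti-alias filter.
2. **Edge detection.** A 5×5 Gaussian filter (default σ = 1, the
   standard choice for a 5-tap support) suppresses noise, then a Canny
   chain — Sobel gradients, non-maximum suppression (NMS), hysteresis
   thresholding — produces a binary edge map per tile. All convolutions
   use symmetric (mirrored) borders so tile edges do not spawn
   dark-halo gradients.
3. **Overlap estimation.** For each consecutive pair, every candidate
   `(dx, dy)` on a grid (defaults: `dy` over 10–50 % of the shorter
   tile height, `dx` over ±10 % of the width, step 1) is scored by the
   symmetric edge-matching distance
   $$A = \frac{\sum E^1 D^2}{\sum E^1} + \frac{\sum E^2 D^1}{\sum E^2},$$
   where \(E^i\) are the overlap-strip edge maps and \(D^i\) the
   per-pixel Euclidean distances to the nearest edge of the other
   strip. \(A\) is the sum of each strip's mean edge-to-nearest-edge
   distance; it is nonnegative, symmetric, and zero exactly when the
   two non-empty strip maps coincide. The grid minimum is taken — an
   exhaustive traversal, not a local optimizer.
4. **Fusion.** The aligned overlap strips are blended by a per-scale
   convex combination of multilevel wavelet coefficients,
   \(W_i = \theta W_i^1 + (1-\theta) W_i^2\), and the three tiles are
   composed onto one canvas whose height is
   `h1 + h2 + h3 − dy12 − dy23`.

## Numerical design choices

**Exhaustive search via cross-correlation.** Evaluating \(A\) on every
candidate crop would cost `O(candidates × strip area)`. The numerators
\(\sum E^1 D^2\) of *all* candidates are instead obtained at once as a
2-D FFT cross-correlation of the upper tile's edge tail with the lower
tile's distance-map head, and the denominators from summed-area tables
of the edge maps. This is an exact reformulation of the same sums (FFT
round-off is ~1e-9 relative and only affects ranking between
candidates closer than that; ties within 1e-9 are broken
deterministically by larger `dy`, then smaller `|dx|`, then negative
`dx`). A plain per-candidate `method = "direct"` evaluation is kept and
the test suite checks the two agree. The distance transform itself is
delegated to an exact Euclidean distance-transform routine (EBImage),
verified against an all-pairs brute-force oracle in the tests.

**Tile-level search, strip-level quality.** Distance maps are computed
once per full tile and cropped per candidate, so after `O(HW log HW)`
preprocessing each candidate costs `O(1)`. This has one consequence
worth documenting: an overlap strip always abuts each tile's image
border, and the mirrored convolution context there differs from the
true (cut-away) anatomy, so the per-tile edge maps of two perfectly
aligned strips can disagree by a pixel or two in the border rows. The
search is insensitive to this (the optimum is separated from its
neighbors by far more), but it would leave a small spurious floor on
the reported cost. The matching distance *reported* for the winning
offset is therefore re-evaluated with the detector run on the two
aligned strip crops (`overlap_quality()`): both crops then present
identical borders, and pixel-identical anatomy scores exactly zero.

**Hysteresis thresholds.** The paper-style Canny chain needs a low and
a high gradient threshold. The default resolves them adaptively — high
= 90th percentile of the nonzero thinned magnitudes, low = 0.4 × high —
which is robust to exposure differences between tiles of unknown
provenance. For phantom studies the intensities are calibrated by
construction and `validation_config()` uses absolute thresholds
(0.2 / 0.5 on the `[0, 1]` intensity scale): adaptive per-tile
percentiles make the survival of a whole contour family depend on
whether *that tile* handed it a seed pixel, which is exactly the kind
of exposure-adaptive behavior one wants on hospital images and exactly
the kind of content-dependent behavior one does not want when checking
bit-level reproducibility. Thinned magnitudes below 1e-9 are treated
as zero so that convolution round-off on flat regions never enters the
percentile pool. NMS uses four direction bins and a `≥` tie rule, so
genuine maxima on plateaus are never lost.

**Wavelet blending.** Default family Haar, 3 levels, uniform
θ = 0.5. The transform is a periodized orthonormal filter bank
(implemented in the package; Daubechies-2 is also provided), so
reconstruction is exact and, with a uniform θ, linearity makes the
blend identical to the per-pixel convex combination for *any* family —
the family only matters when per-scale θ values are used (e.g. to
favor the sharper tile at fine scales). Strips are symmetrically
padded to dimensions divisible by `2^levels` and cropped back;
strips smaller than `2^levels` are blended with correspondingly fewer
levels, down to a plain pixel blend.

**HKA sign convention.** `hka_angle()` returns the signed angle from
the knee→hip to the knee→ankle vector mapped into (0°, 360°): a
straight leg reads exactly 180°, and the sign of the 2-D cross product
decides whether a deviation δ is reported as 180 + δ or 180 − δ.
Mirroring the landmarks about a vertical axis swaps the two — the
convention, not the geometry, fixes which side is "varus". The measure
is invariant under translation, rotation and uniform scaling.
Zero-variance angle-set comparisons report p = 1 with a warning rather
than NaN.

## The phantom: what it emulates, and what it does not

Clinical images cannot ship with the package, so every stage is
validated against a synthetic leg phantom with known ground truth. The
default canvas is 852 × 830 — a 3408 × 3320 acquisition downsampled by
4, i.e. desk-scale but proportionate to real studies. It contains:

* two capsule-shaped bones (femur, tibia) meeting at the knee, with a
  3-pixel cortical intensity ramp so the detector fires on a clean,
  closed contour;
* a soft-tissue silhouette around each bone whose radius varies along
  the axis — a thigh tapering toward the knee and a calf that bulges
  in its upper third. This is not cosmetic: a bare bone shaft presents
  two parallel straight contours, and a translation along the shaft
  direction maps them onto themselves, so the offset would be
  genuinely unidentifiable from the overlap (the aperture problem).
  Real radiographs are never that featureless — the skin silhouette
  against air is always present, and its converging boundaries pin the
  translation uniquely;
* equal intensity steps air → soft tissue → bone (0.02 / 0.37 / 0.72
  by default), so both edge families present comparable gradient
  magnitudes; contrast is a free knob, not calibrated to any hospital
  data;
* the tibial axis is *derived* by rotating the femoral axis so the
  knee angle is exactly `180 + varus_valgus_deg`, making the
  programmed HKA angle an identity by construction;
* optional additive Gaussian noise (clipped to `[0, 1]`), an optional
  smoothed-noise background texture, and an optional ruler strip
  (cosmetic only).

`tile_phantom()` cuts the canvas into three vertically overlapping
tiles, with lateral shifts implemented as laterally displaced crop
windows, and records the true `(dx, dy)` per pair.

What the phantom does **not** emulate: projection physics, trabecular
texture, scatter, exposure differences between tiles, patient motion,
implants or pathology. Passing the phantom studies therefore
demonstrates the correctness and noise robustness of the geometry and
of every algorithmic stage — it does not certify performance on
hospital images, whose edge content is richer but also messier.

## Study conditions and problem sizes

The validation studies (`run_validation()`, also behind
`scripts/acceptance.R`) draw per trial: varus/valgus uniform on
[−10°, 10°], overlaps uniform on 40–120 rows, lateral shifts uniform
on −10..10 columns, at the default 852 × 830 canvas with
`downsample_factor = 1`. Noiseless batches check exact recovery
(offset error 0, matching distance exactly 0, canvas RMS at
floating-point level, HKA error < 1e-6°); noisy batches add
independent per-tile Gaussian noise with sd 0.01 and require recovery
within ±1 pixel. The test suite runs 100 trials per condition; the
acceptance script reports 50 per condition.

## Known limitations

* Pure translation model: rotation, scale or perspective differences
  between exposures are out of scope by design.
* Landmarks for the HKA angle are supplied by the user or the phantom
  truth; there is no automated landmark detector.
* Overlap-only blending: no feathering beyond the overlap, no
  multi-band seam optimization, no exposure compensation.
* The quality ceiling on the matching distance (default 2 px) is the
  only guard against misordered or non-adjacent tiles.
* DICOM is not read; export to PNG/TIFF first.
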