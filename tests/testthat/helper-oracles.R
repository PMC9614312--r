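# Shared fixtures and independent brute-force oracles.

# A compact phantom for module tests (the full-size default is used by
# the acceptance suite).
small_phantom_spec <- function(varus_valgus_deg = 0, seed = 1, ...) {
  phantom_spec(canvas_height = 400, canvas_width = 420,
               hip_center = c(48, 215), knee_center = c(200, 200),
               varus_valgus_deg = varus_valgus_deg, seed = seed, ...)
}

# Absolute-threshold detector settings used for phantom imagery (known,
# calibrated contrast).
abs_canny <- function() {
  canny_config(threshold_mode = "absolute", low = 0.2, high = 0.5)
}

# study-scale pipeline settings
phantom_config <- function() validation_config()

# a registration result fixed by hand (for composing with known offsets)
make_reg <- function(dx, dy, a = 0) {
  structure(list(dx = as.integer(dx), dy = as.integer(dy),
                 matching_distance = a, search_evaluations = 1L,
                 skipped = 0L, low_confidence = FALSE),
            class = "registration_result")
}

random_edge_matrix <- function(h, w, p = 0.05) {
  m <- matrix(as.numeric(stats::runif(h * w) < p), h, w)
  if (sum(m) == 0) m[sample(length(m), 1)] <- 1
  m
}

# all-pairs brute-force Euclidean distance transform
edt_bruteforce <- function(E) {
  idx <- which(E == 1, arr.ind = TRUE)
  H <- nrow(E); W <- ncol(E)
  out <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
    }
  }
  out
}

# literal per-pixel evaluation of the symmetric matching cost
matching_distance_oracle <- function(e1, d1, e2, d2) {
  n1 <- 0; n2 <- 0; s1 <- 0; s2 <- 0
  for (i in seq_len(nrow(e1))) {
    for (j in seq_len(ncol(e1))) {
      if (e1[i, j] == 1) { n1 <- n1 + d2[i, j]; s1 <- s1 + 1 }
      if (e2[i, j] == 1) { n2 <- n2 + d1[i, j]; s2 <- s2 + 1 }
    }
  }
  n1 / s1 + n2 / s2
}

# flood fill from all strong seeds through the weak mask (8-connected)
hysteresis_oracle <- function(thin, low, high) {
  H <- nrow(thin); W <- ncol(thin)
  weak <- thin >= low & thin > 0
  keep <- thin >= high & thin > 0
  repeat {
    grew <- FALSE
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        if (weak[i, j] && !keep[i, j]) {
          nb <- keep[max(1, i - 1):min(H, i + 1),
                     max(1, j - 1):min(W, j + 1)]
          if (any(nb)) { keep[i, j] <- TRUE; grew <- TRUE }
        }
      }
    }
    if (!grew) break
  }
  matrix(as.numeric(keep), H, W)
}

# distance from (row, col) points (matrix, one per row) to segment p--q
seg_dist_points <- function(pts, p, q) {
  v <- q - p
  tt <- ((pts[, 1] - p[1]) * v[1] + (pts[, 2] - p[2]) * v[2]) / sum(v^2)
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((pts[, 1] - (p[1] + tt * v[1]))^2 + (pts[, 2] - (p[2] + tt * v[2]))^2)
}

# reflect-padded cross-correlation by explicit loops
filter_sym_oracle <- function(m, kernel) {
  H <- nrow(m); W <- ncol(m)
  k <- (nrow(kernel) - 1) / 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (a in -k:k) {
        for (b in -k:k) {
          acc <- acc + kernel[a + k + 1, b + k + 1] *
            m[refl(i + a, H), refl(j + b, W)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}
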