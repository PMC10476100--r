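# Fixture builders and independent oracles used across the suite.
# Everything here is generated in code; no binary fixtures.

fix_disk <- function(r = 20, pad = 5) {
  n <- 2 * (r + pad)
  cx <- (n - 1) / 2
  m <- matrix(0L, n, n)
  for (row in seq_len(n)) {
    d2 <- r^2 - (row - 1 - cx)^2
    if (d2 >= 0) {
      cols <- which(abs(0:(n - 1) - cx) <= sqrt(d2))
      m[row, cols] <- 1L
    }
  }
  m
}

fix_rect <- function(h = 40, w = 8, pad = 5) {
  m <- matrix(0L, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- 1L
  m
}

# Smooth star-shaped blob: a disk with low-order radial harmonics. Single
# connected component by construction.
random_blob <- function(seed, r = 20, pad = 8, wobble = 0.15) {
  set.seed(seed)
  amp <- runif(3, 0, wobble / 3)
  pha <- runif(3, 0, 2 * pi)
  n <- 2 * (r + pad)
  cx <- (n - 1) / 2
  xs <- matrix(rep(0:(n - 1), each = n), n, n) - cx
  ys <- matrix(rep(0:(n - 1), n), n, n) - cx
  th <- atan2(ys, xs)
  rad <- r * (1 + amp[1] * cos(2 * th + pha[1]) + amp[2] * cos(3 * th + pha[2]) +
                amp[3] * cos(4 * th + pha[3]))
  matrix(as.integer(sqrt(xs^2 + ys^2) <= rad), n, n)
}

# Distance from point p to the segment (a, b), by projection clamped to the
# segment (independent of the package's line representation).
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

# Brute-force longest centroid chord: over all contour point pairs whose
# segment passes within eps of the centroid, the maximal pair distance.
brute_chord_length <- function(contour, centroid, eps = 1.0) {
  pts <- unique(contour)
  m <- nrow(pts)
  cen <- c(centroid[["x"]], centroid[["y"]])
  best <- 0
  for (i in seq_len(m - 1)) {
    a <- c(pts[i, "x"], pts[i, "y"])
    for (j in (i + 1):m) {
      b <- c(pts[j, "x"], pts[j, "y"])
      if (point_segment_distance(cen, a, b) <= eps) {
        best <- max(best, sqrt(sum((a - b)^2)))
      }
    }
  }
  best
}

# Reference sRGB (0-255) -> CIELAB (D65, 2 deg) conversion, written from the
# closed-form definition, independent of grDevices.
ref_lab <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  wp <- c(0.95047, 1.0, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz / wp)
  c(L = 116 * fx[2] - 16, a = 500 * (fx[1] - fx[2]), b = 200 * (fx[2] - fx[3]))
}

# Rasterize a rectangle rotated by `deg` about the patch centre.
rotated_rect_mask <- function(h = 40, w = 8, deg = 30, n = 64) {
  cx <- (n - 1) / 2
  xs <- matrix(rep(0:(n - 1), each = n), n, n) - cx
  ys <- matrix(rep(0:(n - 1), n), n, n) - cx
  th <- deg * pi / 180
  xr <- cos(th) * xs + sin(th) * ys
  yr <- -sin(th) * xs + cos(th) * ys
  matrix(as.integer(abs(xr) <= w / 2 & abs(yr) <= h / 2), n, n)
}

# Small cached classifier benchmark so several test files can reuse one
# feature extraction pass.
.bench_env <- new.env(parent = emptyenv())

bench_small <- function() {
  if (is.null(.bench_env$small)) {
    ds <- synth_dataset(15, seed = 3)
    feats <- extract_features(ds)
    .bench_env$small <- list(data = ds, features = feats)
  }
  .bench_env$small
}

# The full synthetic benchmark: 100 patches per stage, generator seed 7,
# stratified 70/30 split with seed 0. Cached so the classifier-recovery and
# region-ablation checks share one feature-extraction pass.
bench_full <- function() {
  if (is.null(.bench_env$full)) {
    ds <- synth_dataset(100, seed = 7)
    feats <- extract_features(ds)
    .bench_env$full <- c(list(features = feats),
                         stratified_split(feats, 0.7, seed = 0))
  }
  .bench_env$full
}
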