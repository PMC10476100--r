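test_that("preprocessing keeps the largest component and fills holes", {
  blob <- fix_rect(25, 20)
  expect_identical(preprocess_mask(blob), blob)

  speckled <- blob
  speckled[1, 1:3] <- 1L
  expect_warning(cleaned <- preprocess_mask(speckled), "components")
  expect_identical(cleaned, blob)

  holed <- blob
  holed[10, 10] <- 0L
  filled <- preprocess_mask(holed)
  expect_equal(sum(filled), sum(holed) + 1)

  expect_error(preprocess_mask(matrix(0L, 10, 10)), class = "berry_empty_mask")
  small <- matrix(0L, 20, 20); small[5:7, 5:7] <- 1L
  expect_error(preprocess_mask(small), class = "berry_too_small")
})

test_that("centroid equals the mean of foreground coordinates", {
  one <- matrix(0L, 10, 10); one[6, 4] <- 1L   # x = 3, y = 5
  expect_equal(mask_centroid(one), c(x = 3, y = 5))

  sq <- matrix(0L, 4, 4); sq[1:4, 1:4] <- 1L
  expect_equal(mask_centroid(sq), c(x = 1.5, y = 1.5))

  blob <- random_blob(11, r = 8, pad = 3)
  idx <- which(blob == 1, arr.ind = TRUE)
  sx <- 0; sy <- 0
  for (k in seq_len(nrow(idx))) {           # brute-force loop oracle
    sx <- sx + unname(idx[k, 2] - 1); sy <- sy + unname(idx[k, 1] - 1)
  }
  expect_equal(mask_centroid(blob),
               c(x = sx / nrow(idx), y = sy / nrow(idx)), tolerance = 1e-12)
})

test_that("contour tracing is closed, 8-connected and boundary-only", {
  bar <- matrix(0L, 5, 9); bar[3, 3:7] <- 1L
  expect_equal(nrow(unique(trace_contour(bar))), 5)

  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  expect_equal(nrow(trace_contour(sq)), 36)   # 4*10 - 4 perimeter pixels

  disk <- fix_disk(20)
  ct <- trace_contour(disk)
  steps <- diff(rbind(ct, ct[1, , drop = FALSE]))
  expect_true(max(abs(steps)) <= 1)           # 8-neighbour consecutive steps
  for (k in seq_len(nrow(ct))) {              # every point touches background
    r <- ct[k, "y"] + 1; c <- ct[k, "x"] + 1
    nb <- c(
      if (r > 1) disk[r - 1, c] else 0L, if (r < nrow(disk)) disk[r + 1, c] else 0L,
      if (c > 1) disk[r, c - 1] else 0L, if (c < ncol(disk)) disk[r, c + 1] else 0L
    )
    expect_true(any(nb == 0L) || length(nb) < 4)
  }
})

test_that("implicit lines contain their points and measure distance correctly", {
  lh <- line_through(c(x = 0, y = 0), c(x = 1, y = 0))
  expect_equal(point_line_distance(lh, c(x = 0, y = 0)), 0)
  expect_equal(point_line_distance(lh, c(x = 1, y = 0)), 0)

  lv <- line_through(c(x = 0, y = 0), c(x = 0, y = 1))
  expect_equal(point_line_distance(lv, c(x = 1, y = 0)), 1)

  expect_error(line_through(c(x = 1, y = 2), c(x = 1, y = 2)),
               class = "berry_coincident_points")

  set.seed(42)
  for (k in 1:200) {
    p <- c(x = runif(1, -50, 50), y = runif(1, -50, 50))
    q <- c(x = runif(1, -50, 50), y = runif(1, -50, 50))
    ln <- line_through(p, q)
    expect_lt(abs(ln[["A"]] * p[["y"]] + ln[["B"]] * p[["x"]] + ln[["C"]]), 1e-9)
    expect_lt(abs(ln[["A"]] * q[["y"]] + ln[["B"]] * q[["x"]] + ln[["C"]]), 1e-9)
    # vector-projection oracle for a third point
    z <- c(runif(1, -50, 50), runif(1, -50, 50))
    ab <- c(q[["x"]] - p[["x"]], q[["y"]] - p[["y"]])
    ap <- z - c(p[["x"]], p[["y"]])
    d_ref <- abs(ab[1] * ap[2] - ab[2] * ap[1]) / sqrt(sum(ab^2))
    expect_equal(point_line_distance(ln, c(x = z[1], y = z[2])), d_ref,
                 tolerance = 1e-9)
  }
})

test_that("opposite intersections land across the centroid", {
  disk <- fix_disk(20)
  ct <- trace_contour(disk)
  cen <- mask_centroid(disk)
  for (i in c(1, 17, 53)) {
    opp <- opposite_intersection(ct, cen, i)
    span <- sqrt(unname(ct[i, "x"] - opp$point[["x"]])^2 +
                 unname(ct[i, "y"] - opp$point[["y"]])^2)
    expect_equal(span, 40, tolerance = 2)     # within 2 px of the diameter
  }

  rect <- fix_rect(30, 14)
  rct <- trace_contour(rect)
  rcen <- mask_centroid(rect)
  corner <- which(rct[, "x"] == min(rct[, "x"]) & rct[, "y"] == min(rct[, "y"]))[1]
  opp <- opposite_intersection(rct, rcen, corner)
  expect_equal(unname(opp$point),
               unname(c(max(rct[, "x"]), max(rct[, "y"]))))  # opposite corner

  blob <- random_blob(5)
  bct <- trace_contour(blob)
  bcen <- mask_centroid(blob)
  for (i in seq(1, nrow(bct), by = 7)) {
    u <- c(bct[i, "x"] - bcen[["x"]], bct[i, "y"] - bcen[["y"]])
    opp <- opposite_intersection(bct, bcen, i)
    w <- c(opp$point[["x"]] - bcen[["x"]], opp$point[["y"]] - bcen[["y"]])
    expect_lt(sum(u * w), 0)                  # strictly opposite side
  }
})

test_that("longest chord matches analytic geometry and is maximal", {
  disk <- fix_disk(20)
  ch <- longest_chord(trace_contour(disk), mask_centroid(disk))
  expect_equal(ch$length, 40, tolerance = 2)

  # tall rectangle: the longest centroid chord is the main diagonal
  rect <- fix_rect(60, 20)
  rch <- longest_chord(trace_contour(rect), mask_centroid(rect))
  diag_len <- sqrt(59^2 + 19^2)
  expect_equal(rch$length, diag_len, tolerance = 1.5)
  expect_equal(abs(rch$p_end[["x"]] - rch$p_start[["x"]]), 19, tolerance = 1)

  # maximality: never shorter than the vertical chord through the centroid
  for (seed in 1:5) {
    blob <- random_blob(seed)
    ct <- trace_contour(blob)
    cen <- mask_centroid(blob)
    ch <- longest_chord(ct, cen)
    col <- round(cen[["x"]]) + 1
    vert <- sum(blob[, col])
    expect_gte(ch$length + 1, vert)
  }
})

test_that("longest chord agrees with the all-pairs brute-force oracle", {
  for (seed in 1:8) {
    blob <- random_blob(seed, r = 16, pad = 5)
    ct <- trace_contour(blob)
    cen <- mask_centroid(blob)
    ch <- longest_chord(ct, cen)
    oracle <- brute_chord_length(ct, cen, eps = 1.0)
    expect_lt(abs(ch$length - oracle), 1.0)
  }
})

make_chord <- function(p, q) {
  structure(list(p_start = p, p_end = q, length = sqrt(sum((q - p)^2)),
                 start_index = NA, end_index = NA), class = "berry_chord")
}

test_that("quarter points cut the chord into four equal parts", {
  qc <- quarter_cut_lines(make_chord(c(x = 0, y = 0), c(x = 0, y = 8)))
  expect_equal(qc$points$x, c(0, 0, 0))
  expect_equal(qc$points$y, c(2, 4, 6))
  # cuts are horizontal: both (10, y) and (-10, y) lie on each line
  for (k in 1:3) {
    ln <- qc$lines[[k]]
    expect_equal(point_line_distance(ln, c(x = 10, y = qc$points$y[k])), 0,
                 tolerance = 1e-9)
  }

  qd <- quarter_cut_lines(make_chord(c(x = 0, y = 0), c(x = 8, y = 8)))
  expect_equal(qd$points$x[2], 4)
  expect_equal(qd$points$y[2], 4)
  # l_b has direction (1, -1): point (5, 3) lies on it
  expect_equal(point_line_distance(qd$lines$l_b, c(x = 5, y = 3)), 0,
               tolerance = 1e-9)

  set.seed(9)
  p <- c(x = runif(1, -20, 20), y = runif(1, -20, 20))
  q <- c(x = runif(1, -20, 20), y = runif(1, -20, 20))
  qr <- quarter_cut_lines(make_chord(p, q))
  segs <- diff(c(0, qr$points$t, sqrt(sum((q - p)^2))))
  expect_equal(max(segs) - min(segs), 0, tolerance = 1e-9)
})

test_that("partitioning quarters the mask and labels R1 at the bottom", {
  rect <- fix_rect(40, 8)
  part <- partition_instance(rect)
  expect_equal(sum(part$region_centroids$area), sum(rect))
  # R1 is the bottom band
  expect_true(all(diff(part$region_centroids$y) < 0))
  expect_equal(part$region_centroids$area, rep(sum(rect) / 4, 4),
               tolerance = 0.06)

  rot <- rotated_rect_mask(40, 8, deg = 30)
  prot <- partition_instance(rot)
  expect_true(all(abs(prot$region_centroids$area - sum(rot) / 4) <=
                    0.05 * sum(rot) / 4 + 2))

  tear <- synth_shape_mask(64, 64, rotation = 0)
  pt <- partition_instance(tear)
  a <- setNames(pt$region_centroids$area, pt$region_centroids$region)
  expect_lt(a[["R1"]], a[["R2"]])             # the tip region is smallest
})

test_that("partitions are complete, disjoint, ordered and 90-degree equivariant", {
  for (seed in 1:10) {
    blob <- random_blob(seed)
    part <- partition_instance(blob)
    total <- Reduce(`+`, part$regions)
    expect_true(all(total == blob))           # complete and pairwise disjoint
    expect_true(all(diff(part$region_centroids$y) <= 0))

    rot90 <- t(blob)[, rev(seq_len(nrow(blob)))]  # 90-degree rotation
    part90 <- partition_instance(matrix(as.integer(rot90), nrow(rot90)))
    a0 <- sort(part$region_centroids$area)
    a90 <- sort(part90$region_centroids$area)
    expect_true(all(abs(a0 - a90) <= 0.02 * sum(blob)))
  }
})
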