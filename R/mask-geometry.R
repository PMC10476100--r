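# Geometry of a single fruit instance mask.
#
# Conventions used throughout: a mask is an integer matrix with values in
# {0, 1}, indexed mask[row, col]; pixel coordinates are 0-based with
# x = col - 1 and y = row - 1, and rows increase downward so "bottom" means
# maximal y. Points are named numeric vectors c(x = , y = ). A line is stored
# in the implicit form A*y + B*x + C = 0 as c(A = , B = , C = ), normalized
# so that A^2 + B^2 = 1.

as_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stopf("berry_bad_mask", "mask must be a matrix")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  m
}

mask_coords <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

#' Clean up a raw instance mask
#'
#' Keeps the largest 8-connected foreground component, fills interior holes
#' and drops everything else. Segmentation masks of occluded fruit are often
#' split into fragments or pierced by stalks and leaves; partitioning assumes
#' one solid blob, so this is run before any geometry.
#'
#' @param mask Binary matrix (any nonzero value is foreground).
#' @param min_area Minimum foreground pixel count accepted after cleaning.
#'   Masks below this are rejected: quartering a tiny blob is meaningless.
#' @return The cleaned 0/1 integer matrix, same shape as the input.
#' @examples
#' m <- matrix(0L, 40, 40); m[5:35, 5:30] <- 1L; m[10, 10] <- 0L
#' sum(preprocess_mask(m)) - sum(m)  # the hole is filled
#' @export
preprocess_mask <- function(mask, min_area = 64) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0) stopf("berry_empty_mask", "mask has no foreground pixels")
  lab <- EBImage::bwlabel(mask)
  ncomp <- max(lab)
  if (ncomp > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    keep <- which.max(sizes)
    warn(sprintf("mask has %d components; keeping the largest (%d px)",
                 ncomp, sizes[keep]))
    mask <- matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
  }
  mask <- matrix(as.integer(EBImage::fillHull(mask) != 0), nrow(mask), ncol(mask))
  if (sum(mask) < min_area) {
    stopf("berry_too_small", "largest component has %d px (< min_area = %d)",
          sum(mask), min_area)
  }
  mask
}

#' Centroid of a binary mask
#'
#' The centre of mass of the foreground: the arithmetic mean of the
#' foreground pixel coordinates,
#' \eqn{x_0 = \sum p_i x_i / \sum p_i}, \eqn{y_0 = \sum p_i y_i / \sum p_i}.
#'
#' @param mask Binary matrix.
#' @return Named numeric vector `c(x = , y = )` in 0-based pixel coordinates.
#' @export
mask_centroid <- function(mask) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0) stopf("berry_empty_mask", "mask has no foreground pixels")
  xy <- mask_coords(mask)
  c(x = mean(xy[, "x"]), y = mean(xy[, "y"]))
}

#' Trace the outer contour of a mask
#'
#' Returns the ordered closed traversal of the outer boundary of a
#' single-component mask: consecutive points are 8-neighbours, every point is
#' a foreground pixel touching the background, and the sequence loops back to
#' its start. Thin structures (one pixel wide) are traversed out and back, so
#' a pixel may appear twice in the sequence.
#'
#' @param mask Preprocessed single-component binary matrix.
#' @return A two-column matrix with columns `x`, `y` (0-based), one row per
#'   traversal step.
#' @export
trace_contour <- function(mask) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0) stopf("berry_empty_mask", "mask has no foreground pixels")
  oc <- EBImage::ocontour(mask)
  if (length(oc) == 0) stopf("berry_degenerate_shape", "no contour found")
  # ocontour() is per labelled object; a preprocessed mask has exactly one
  pts <- unname(oc[[1]])
  out <- cbind(x = pts[, 2], y = pts[, 1])
  if (nrow(unique(out)) < 3) {
    stopf("berry_degenerate_shape", "contour has fewer than 3 distinct points")
  }
  out
}

#' Implicit line through two points
#'
#' Builds the line A*y + B*x + C = 0 through `p` and `q`, normalized so that
#' A^2 + B^2 = 1.
#'
#' @param p,q Points `c(x = , y = )`; must be distinct.
#' @return Named numeric vector `c(A = , B = , C = )`.
#' @export
line_through <- function(p, q) {
  a <- q[["x"]] - p[["x"]]
  b <- -(q[["y"]] - p[["y"]])
  nrm <- sqrt(a^2 + b^2)
  if (nrm < 1e-12) stopf("berry_coincident_points", "p and q coincide")
  a <- a / nrm; b <- b / nrm
  c(A = a, B = b, C = -(a * p[["y"]] + b * p[["x"]]))
}

#' Perpendicular distance from a point to a line
#'
#' @param line Line `c(A, B, C)` with A*y + B*x + C = 0.
#' @param p A point `c(x = , y = )`, or a matrix with columns `x`, `y`.
#' @return Nonnegative distance(s) in pixels.
#' @export
point_line_distance <- function(line, p) {
  nrm <- sqrt(line[["A"]]^2 + line[["B"]]^2)
  if (nrm < 1e-12) stopf("berry_bad_line", "(A, B) must not both be zero")
  if (is.matrix(p)) {
    abs(line[["A"]] * p[, "y"] + line[["B"]] * p[, "x"] + line[["C"]]) / nrm
  } else {
    abs(line[["A"]] * p[["y"]] + line[["B"]] * p[["x"]] + line[["C"]]) / nrm
  }
}

#' Opposite intersection of a centroid ray with the contour
#'
#' For the line through contour point `i` and the mask centroid, finds the
#' contour point on the *opposite* side of the centroid (negative signed
#' projection onto the direction from centroid to point `i`) lying closest to
#' the line — the approximate second intersection of the line with the fruit
#' outline. Same-side points, including point `i` itself, are excluded.
#'
#' @param contour Contour matrix from [trace_contour()].
#' @param centroid Mask centroid `c(x = , y = )`.
#' @param i Row index of the contour point defining the line.
#' @return List with `point` (the opposite intersection), `index` (its row in
#'   `contour`) and `distance` (its perpendicular distance to the line).
#' @export
opposite_intersection <- function(contour, centroid, i) {
  u <- c(contour[i, "x"] - centroid[["x"]], contour[i, "y"] - centroid[["y"]])
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) {
    stopf("berry_coincident_points", "contour point %d coincides with the centroid", i)
  }
  dx <- contour[, "x"] - centroid[["x"]]
  dy <- contour[, "y"] - centroid[["y"]]
  s <- dx * u[1] + dy * u[2]              # signed projection on the ray to P_i
  d <- abs(dx * u[2] - dy * u[1]) / nu     # perpendicular distance to the line
  cand <- which(s < 0)
  if (length(cand) == 0) {
    stopf("berry_no_opposite_point",
          "no contour point lies opposite point %d across the centroid", i)
  }
  j <- cand[which.min(d[cand])]
  list(point = c(x = unname(contour[j, "x"]), y = unname(contour[j, "y"])),
       index = j, distance = unname(d[j]))
}

#' Longest chord through the centroid
#'
#' Traverses every contour point P_i, pairs it with its opposite intersection
#' P_i' across the centroid, and returns the pair with the greatest Euclidean
#' separation: the longest line segment through the fruit's centre of mass
#' with both ends on the outline. For a fruit in hanging posture this chord
#' runs roughly from calyx to tip and defines the axis along which the mask
#' is quartered.
#'
#' Contour points for which no opposite intersection exists (possible on
#' strongly concave outlines) are skipped; ties in length within 1e-6 px are
#' broken toward the smallest start index for determinism.
#'
#' @inheritParams opposite_intersection
#' @return An object of class `berry_chord`: list with points `p_start`,
#'   `p_end`, the `length` in pixels, and the contour row indices
#'   `start_index`, `end_index`.
#' @export
longest_chord <- function(contour, centroid) {
  dx <- contour[, "x"] - centroid[["x"]]
  dy <- contour[, "y"] - centroid[["y"]]
  m <- nrow(contour)
  if (m < 3) stopf("berry_degenerate_shape", "contour has fewer than 3 points")
  nrm <- sqrt(dx^2 + dy^2)
  valid <- nrm > 1e-9
  # S[j, i] = (P_j - C) . (P_i - C); D[j, i] = dist of P_j to line(C, P_i)
  U <- cbind(dx, dy)
  S <- U %*% t(U)
  X <- outer(dx, dy) - outer(dy, dx)
  D <- sweep(abs(X), 2, pmax(nrm, 1e-12), "/")
  opp <- S < 0
  D[!opp] <- Inf
  j_best <- max.col(-t(D), ties.method = "first")   # per column i, argmin_j
  d_best <- D[cbind(j_best, seq_len(m))]
  len <- sqrt((contour[, "x"] - contour[j_best, "x"])^2 +
              (contour[, "y"] - contour[j_best, "y"])^2)
  len[!valid | !is.finite(d_best)] <- -Inf
  if (all(!is.finite(len))) {
    stopf("berry_no_opposite_point", "no centroid chord could be formed")
  }
  i_star <- which(len >= max(len) - 1e-6)[1]
  j_star <- j_best[i_star]
  p <- c(x = unname(contour[i_star, "x"]), y = unname(contour[i_star, "y"]))
  q <- c(x = unname(contour[j_star, "x"]), y = unname(contour[j_star, "y"]))
  structure(
    list(p_start = p, p_end = q, length = sqrt(sum((p - q)^2)),
         start_index = i_star, end_index = j_star),
    class = "berry_chord"
  )
}

#' @export
print.berry_chord <- function(x, ...) {
  cat(sprintf("<berry_chord> (%.1f, %.1f) -- (%.1f, %.1f), length %.2f px\n",
              x$p_start[["x"]], x$p_start[["y"]],
              x$p_end[["x"]], x$p_end[["y"]], x$length))
  invisible(x)
}

#' Quarter points and perpendicular cut lines of a chord
#'
#' Places points a, b, c at parameters 1/4, 1/2 and 3/4 along the chord and
#' constructs the three lines through them perpendicular to it — the cuts
#' that split the fruit into four equal-length slices along its axis.
#'
#' @param chord A `berry_chord` from [longest_chord()].
#' @return List with `points` (tibble: `name`, `x`, `y`, `t` the arc-length
#'   parameter) and `lines` (named list of `c(A, B, C)` vectors `l_a`, `l_b`,
#'   `l_c`).
#' @export
quarter_cut_lines <- function(chord) {
  if (chord$length <= 0) stopf("berry_bad_chord", "chord has zero length")
  v <- (chord$p_end - chord$p_start) / chord$length
  ts <- c(a = 0.25, b = 0.5, c = 0.75) * chord$length
  pts <- tibble(
    name = names(ts),
    x = unname(chord$p_start[["x"]] + v[["x"]] * ts),
    y = unname(chord$p_start[["y"]] + v[["y"]] * ts),
    t = unname(ts)
  )
  # line perpendicular to v through m: v.x * x + v.y * y - (v . m) = 0,
  # i.e. A = v.y, B = v.x, C = -(v . m) in the A*y + B*x + C = 0 form
  lines <- lapply(seq_len(3), function(k) {
    m <- c(x = pts$x[k], y = pts$y[k])
    c(A = v[["y"]], B = v[["x"]], C = -(v[["x"]] * m[["x"]] + v[["y"]] * m[["y"]]))
  })
  names(lines) <- paste0("l_", pts$name)
  list(points = pts, lines = lines)
}

#' Partition a mask into four ordered sub-regions
#'
#' Assigns every foreground pixel to one of four bins by its signed
#' projection onto the chord direction, cut at 1/4, 1/2 and 3/4 of the chord
#' length (projections outside the chord clamp into the end bins; bins are
#' half-open, the last closed). The four sub-masks are then relabelled
#' R1..R4 by descending centroid row, so R1 is always the bottom-most
#' region in image coordinates — the fruit tip for a hanging berry.
#'
#' @param mask Preprocessed binary matrix.
#' @param chord Chord from [longest_chord()] on this mask.
#' @param contour Optional contour (recomputed if missing); used only to
#'   record the cut-line/outline intersection points for visualization.
#' @return An object of class `subregion_partition`: list with `regions`
#'   (list of four 0/1 matrices R1..R4), `labels` (integer matrix, 0
#'   background, 1--4 = R1--R4), `region_centroids` (tibble with `region`,
#'   `x`, `y`, `area`), `chord`, `quarter_points`, `cut_lines`,
#'   `cut_intersections` and the parent `centroid`.
#' @examples
#' m <- matrix(0L, 50, 20); m[6:45, 7:14] <- 1L
#' part <- partition_mask(m, longest_chord(trace_contour(m), mask_centroid(m)))
#' part$region_centroids
#' @export
partition_mask <- function(mask, chord, contour = NULL) {
  mask <- as_binary_mask(mask)
  xy <- mask_coords(mask)
  if (nrow(xy) == 0) stopf("berry_empty_mask", "mask has no foreground pixels")
  v <- (chord$p_end - chord$p_start) / chord$length
  t <- (xy[, "x"] - chord$p_start[["x"]]) * v[["x"]] +
       (xy[, "y"] - chord$p_start[["y"]]) * v[["y"]]
  bin <- floor(t / chord$length * 4) + 1
  bin[bin < 1] <- 1L
  bin[bin > 4] <- 4L
  counts <- tabulate(bin, nbins = 4)
  if (any(counts == 0)) {
    stopf("berry_empty_region", "quartile bin(s) %s received no pixels",
          paste(which(counts == 0), collapse = ", "))
  }
  cent <- vapply(1:4, function(k) {
    c(mean(xy[bin == k, "x"]), mean(xy[bin == k, "y"]))
  }, numeric(2))
  ord <- order(-cent[2, ])                 # descending centroid row: R1 bottom
  relabel <- match(seq_len(4), ord)        # bin k -> rank of its centroid
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[cbind(xy[, "y"] + 1, xy[, "x"] + 1)] <- relabel[bin]
  regions <- lapply(1:4, function(k) {
    matrix(as.integer(labels == k), nrow(mask), ncol(mask))
  })
  names(regions) <- paste0("R", 1:4)
  qc <- quarter_cut_lines(chord)
  if (is.null(contour)) contour <- trace_contour(mask)
  side <- sign((contour[, "x"] - chord$p_start[["x"]]) * v[["y"]] -
               (contour[, "y"] - chord$p_start[["y"]]) * v[["x"]])
  cut_int <- bind_rows(lapply(names(qc$lines), function(nm) {
    d <- point_line_distance(qc$lines[[nm]], contour)
    bind_rows(lapply(c(-1, 1), function(sg) {
      k <- which(side == sg)
      if (length(k) == 0) return(NULL)
      j <- k[which.min(d[k])]
      tibble(line = nm, side = sg, x = contour[j, "x"], y = contour[j, "y"])
    }))
  }))
  structure(
    list(
      regions = regions,
      labels = labels,
      region_centroids = tibble(
        region = paste0("R", 1:4),
        x = cent[1, ord], y = cent[2, ord],
        area = counts[ord]
      ),
      chord = chord,
      quarter_points = qc$points,
      cut_lines = qc$lines,
      cut_intersections = cut_int,
      centroid = mask_centroid(mask)
    ),
    class = "subregion_partition"
  )
}

#' @export
print.subregion_partition <- function(x, ...) {
  cat("<subregion_partition>\n")
  cat(sprintf("  chord length %.2f px; areas R1..R4: %s\n",
              x$chord$length, paste(x$region_centroids$area, collapse = ", ")))
  invisible(x)
}

#' Partition a raw mask end to end
#'
#' Convenience wrapper: preprocess, centroid, contour, longest chord,
#' partition.
#'
#' @inheritParams preprocess_mask
#' @return A `subregion_partition`.
#' @export
partition_instance <- function(mask, min_area = 64) {
  m <- preprocess_mask(mask, min_area = min_area)
  ct <- trace_contour(m)
  ch <- longest_chord(ct, mask_centroid(m))
  partition_mask(m, ch, contour = ct)
}
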