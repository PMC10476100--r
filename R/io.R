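# File formats: single-channel PNG masks (0 background / 255 foreground),
# RGB PNG images, labelme-style polygon annotation JSON (rasterized with the
# even-odd rule), partition label maps with a JSON sidecar, and versioned
# model bundles (serialized estimator + JSON metadata).

#' Read / write a binary mask PNG
#'
#' Masks are single-channel PNGs with 0 = background and 255 = foreground;
#' any value above half-scale reads as foreground.
#'
#' @param path PNG file.
#' @param mask 0/1 integer matrix.
#' @return `read_mask_png`: 0/1 integer matrix. `write_mask_png`: `path`,
#'   invisibly.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(img > 0.5), nrow(img), ncol(img))
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read / write an RGB image PNG
#'
#' @param path PNG file.
#' @param rgb H x W x 3 array, 0--255.
#' @return `read_image_png`: H x W x 3 array on the 0--255 scale.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

#' @rdname read_image_png
#' @export
write_image_png <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb, 0), 255) / 255, path)
  invisible(path)
}

#' Rasterize a polygon to a mask (even-odd rule)
#'
#' Scanline even-odd fill: a pixel is foreground when a ray from its centre
#' crosses the polygon boundary an odd number of times. Vertices are in
#' image pixel coordinates (x = column, y = row, 0-based).
#'
#' @param vertices Two-column matrix (x, y) of polygon vertices, or a list
#'   of such matrices (multiple rings; crossing parity accumulates, so an
#'   inner ring cuts a hole).
#' @param height,width Output mask dimensions.
#' @return 0/1 integer matrix.
#' @export
rasterize_polygon <- function(vertices, height, width) {
  rings <- if (is.list(vertices)) vertices else list(vertices)
  mask <- matrix(0L, height, width)
  xs <- 0:(width - 1)
  for (row in seq_len(height)) {
    y <- row - 1
    inside <- rep(FALSE, width)
    for (ring in rings) {
      px <- ring[, 1]; py <- ring[, 2]
      nv <- length(px)
      j <- nv
      for (i in seq_len(nv)) {
        if ((py[i] > y) != (py[j] > y)) {
          xint <- px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
          inside <- xor(inside, xs < xint)
        }
        j <- i
      }
    }
    mask[row, inside] <- 1L
  }
  mask
}

#' Read a labelme-style polygon annotation
#'
#' Parses the JSON produced by polygon annotation tools (fields `shapes`
#' with `label` and `points`, and `imageHeight`/`imageWidth`) and rasterizes
#' each shape to an instance mask with the even-odd rule.
#'
#' @param path JSON file.
#' @param height,width Mask dimensions; default from the file's
#'   `imageHeight`/`imageWidth`.
#' @return A tibble with one row per shape: `label` and a `mask`
#'   list-column.
#' @export
read_labelme <- function(path, height = NULL, width = NULL) {
  js <- jsonlite::read_json(path)
  height <- height %||% js$imageHeight
  width <- width %||% js$imageWidth
  if (is.null(height) || is.null(width)) {
    stopf("berry_bad_annotation", "image dimensions missing from %s", path)
  }
  rows <- purrr::map(js$shapes, function(sh) {
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    tibble(label = sh$label %||% NA_character_,
           mask = list(rasterize_polygon(pts, height, width)))
  })
  bind_rows(rows)
}

#' Write a mask as a labelme-style polygon annotation
#'
#' The mask's outer contour is traced and subsampled to polygon vertices.
#'
#' @param mask 0/1 matrix.
#' @param path Output JSON file.
#' @param label Shape label string.
#' @param every Keep every `every`-th contour point as a vertex.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(mask, path, label = "strawberry", every = 3) {
  ct <- trace_contour(as_binary_mask(mask))
  ct <- unique(ct)
  keep <- seq(1, nrow(ct), by = every)
  ann <- list(
    version = "5.0.0",
    shapes = list(list(
      label = label,
      points = lapply(keep, function(i) c(ct[i, "x"], ct[i, "y"])),
      shape_type = "polygon"
    )),
    imageHeight = nrow(mask),
    imageWidth = ncol(mask)
  )
  jsonlite::write_json(ann, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a partition as a label PNG plus JSON sidecar
#'
#' Writes `<prefix>.png`, a 4-valued label image (pixel values 1--4 mark
#' R1--R4, 0 background), and `<prefix>.json` with the centroid, chord
#' endpoints, quarter points and per-region centroids.
#'
#' @param partition A `subregion_partition`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_partition <- function(partition, prefix) {
  png_path <- paste0(prefix, ".png")
  json_path <- paste0(prefix, ".json")
  png::writePNG(partition$labels / 255, png_path)
  side <- list(
    centroid = as.list(partition$centroid),
    chord = list(p_start = as.list(partition$chord$p_start),
                 p_end = as.list(partition$chord$p_end),
                 length = partition$chord$length),
    quarter_points = partition$quarter_points,
    region_centroids = partition$region_centroids
  )
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(png_path, json_path))
}

#' Read a partition label PNG
#'
#' @param path Label PNG written by [write_partition()].
#' @return Integer matrix with values 0 (background) and 1--4 (R1--R4).
#' @export
read_partition_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Save / load a model bundle
#'
#' Persists a fitted `ripeness_model` as `<prefix>.rds` (the serialized
#' estimator) plus `<prefix>.json` metadata: feature schema, class levels,
#' family, hyperparameters, seed and package versions.
#'
#' @param model A `ripeness_model`.
#' @param prefix Path prefix.
#' @return `save_ripeness_model`: the two paths, invisibly.
#'   `load_ripeness_model`: the restored model.
#' @export
save_ripeness_model <- function(model, prefix) {
  rds <- paste0(prefix, ".rds")
  js <- paste0(prefix, ".json")
  saveRDS(model, rds)
  meta <- list(
    bundle_version = 1L,
    family = model$family,
    params = model$params,
    schema = model$schema,
    classes = model$levels,
    seed = model$seed,
    versions = list(
      berryripe = as.character(utils::packageVersion("berryripe")),
      backend = switch(model$family,
        svm = as.character(utils::packageVersion("e1071")),
        rf = as.character(utils::packageVersion("ranger")),
        knn = as.character(utils::packageVersion("caret")),
        lr = as.character(utils::packageVersion("glmnet")))
    )
  )
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(rds, js))
}

#' @rdname save_ripeness_model
#' @export
load_ripeness_model <- function(prefix) {
  model <- readRDS(paste0(prefix, ".rds"))
  if (!inherits(model, "ripeness_model")) {
    stopf("berry_bad_bundle", "%s.rds does not contain a ripeness model", prefix)
  }
  model
}
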