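# Colour-channel conversion and regional feature extraction.
#
# Nine candidate channels are considered: R, G, B (as supplied), H, S, V and
# CIELAB L, a, b computed from sRGB under D65. All channels are kept on 8-bit
# scales so that features share one magnitude: S, V and L span 0-255
# (L = L* * 255/100), H spans 0-179 (degrees/2), and a, b are offset-coded
# as value + 128. Of these, B, G, L, a and S track ripeness most strongly
# (a, the green-red opponent axis, rises as the fruit reddens; B, G and L
# fall) and form the default feature subset.

CHANNEL_ORDER <- c("B", "G", "L", "a", "S")
ALL_CHANNELS <- c("R", "G", "B", "H", "S", "V", "L", "a", "b")

check_channels <- function(channels) {
  bad <- setdiff(channels, CHANNEL_ORDER)
  if (length(bad)) {
    stopf("berry_bad_channel",
          "channels must be a subset of {B, G, L, a, S}; got: %s",
          paste(bad, collapse = ", "))
  }
  CHANNEL_ORDER[CHANNEL_ORDER %in% channels]
}

as_rgb_array <- function(rgb) {
  if (!(is.array(rgb) && length(dim(rgb)) == 3 && dim(rgb)[3] == 3)) {
    stopf("berry_bad_image", "expected an H x W x 3 RGB array")
  }
  if (max(rgb) <= 1 && is.double(rgb)) rgb <- rgb * 255
  rgb
}

#' Convert an RGB patch to the nine candidate channels
#'
#' @param rgb An H x W x 3 array, 8-bit values 0--255 (0--1 doubles are
#'   rescaled).
#' @return A `channel_stack`: named list of nine H x W matrices
#'   (`R`,`G`,`B`,`H`,`S`,`V`,`L`,`a`,`b`) on the 8-bit scales described
#'   above.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' round(sapply(to_channel_stack(px), c))
#' @export
to_channel_stack <- function(rgb) {
  rgb <- as_rgb_array(rgb)
  d <- dim(rgb)[1:2]
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 255)
  lab <- grDevices::convertColor(cbind(as.vector(r), as.vector(g),
                                       as.vector(b)) / 255,
                                 from = "sRGB", to = "Lab")
  shape <- function(v) matrix(v, d[1], d[2])
  structure(list(
    R = r, G = g, B = b,
    H = shape(hsv["h", ] * 179),
    S = shape(hsv["s", ] * 255),
    V = shape(hsv["v", ] * 255),
    L = shape(lab[, 1] * 255 / 100),
    a = shape(lab[, 2] + 128),
    b = shape(lab[, 3] + 128)
  ), class = "channel_stack", dim_hw = d)
}

#' Regional colour features of a partitioned fruit
#'
#' The feature the classifier sees: the mean of each selected channel over
#' the foreground pixels of each sub-region, ordered channel-major and
#' region-minor (B_R1, B_R2, ..., S_R4). With the default five channels the
#' vector has 20 entries.
#'
#' @param stack `channel_stack` of the same image the mask came from.
#' @param partition A [partition_mask()] result for that instance.
#' @param channels Subset of `c("B","G","L","a","S")`; order is fixed
#'   internally regardless of the order given.
#' @return A one-row tibble, one column per (channel, region) pair.
#' @export
regional_features <- function(stack, partition,
                              channels = c("B", "G", "L", "a", "S")) {
  channels <- check_channels(channels)
  vals <- unlist(lapply(channels, function(ch) {
    m <- stack[[ch]]
    vapply(partition$regions, function(reg) mean(m[reg == 1]), numeric(1))
  }))
  names(vals) <- as.vector(t(outer(channels, paste0("R", 1:4), paste, sep = "_")))
  as_tibble(as.list(vals))
}

#' Whole-fruit channel means
#'
#' Mean of each of the nine channels over the foreground pixels of one
#' instance. Used for channel-selection trend analysis and as the
#' whole-foreground baseline feature ("fruit means" method).
#'
#' @param stack A `channel_stack`.
#' @param mask Binary mask aligned with the stack.
#' @return A one-row tibble with columns `R,G,B,H,S,V,L,a,b`.
#' @export
whole_fruit_means <- function(stack, mask) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0) stopf("berry_empty_mask", "mask has no foreground pixels")
  fg <- mask == 1
  vals <- vapply(ALL_CHANNELS, function(ch) mean(stack[[ch]][fg]), numeric(1))
  as_tibble(as.list(vals))
}

#' Flattened-pixel baseline features
#'
#' The "every pixel is a feature" baseline: the bounding-box crop of the
#' instance is resized to 30 x 40 (width x height, bilinear) and each
#' requested channel is flattened row-major, giving 1200 values per channel.
#' Background pixels inside the box are included by design.
#'
#' @param rgb_patch H x W x 3 array: the rectangular crop of the instance's
#'   bounding box.
#' @param channels Subset of `c("B","G","L","a","S")`.
#' @return A one-row tibble with `1200 * length(channels)` columns named
#'   `<channel>_px<k>`.
#' @export
method1_features <- function(rgb_patch, channels = c("B", "G", "L", "a", "S")) {
  rgb_patch <- as_rgb_array(rgb_patch)
  channels <- check_channels(channels)
  resized <- array(0, dim = c(40, 30, 3))
  for (k in 1:3) {
    resized[, , k] <- EBImage::resize(rgb_patch[, , k], w = 40, h = 30)
  }
  stack <- to_channel_stack(resized)
  vals <- unlist(lapply(channels, function(ch) as.vector(t(stack[[ch]]))))
  names(vals) <- as.vector(t(outer(channels, paste0("px", 1:1200), paste, sep = "_")))
  as_tibble(as.list(vals))
}

#' Extract a feature table from an instance dataset
#'
#' Maps a dataset tibble (as produced by [synth_dataset()], or assembled from
#' files: one row per instance with `mask` and `rgb` list-columns) to the
#' feature table the classifiers consume.
#'
#' @param data Tibble with list-columns `mask` and `rgb`; columns
#'   `instance_id` and `label` are carried through when present.
#' @param channels Subset of `c("B","G","L","a","S")`.
#' @param method `"regional"` (four sub-region means; the package's main
#'   method), `"bbox_pixels"` (flattened 30 x 40 bounding-box crop) or
#'   `"fruit_means"` (whole-foreground channel means).
#' @param min_area Minimum mask area passed to [preprocess_mask()].
#' @return A tibble: `instance_id`, `label` (if present), then the feature
#'   columns.
#' @examples
#' \donttest{
#' feats <- synth_dataset(5, seed = 1) |> extract_features(channels = "a")
#' }
#' @export
extract_features <- function(data, channels = c("B", "G", "L", "a", "S"),
                             method = c("regional", "bbox_pixels", "fruit_means"),
                             min_area = 64) {
  method <- match.arg(method)
  channels <- check_channels(channels)
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    mask <- as_binary_mask(data$mask[[i]])
    rgb <- as_rgb_array(data$rgb[[i]])
    feats <- switch(method,
      regional = {
        part <- partition_instance(mask, min_area = min_area)
        regional_features(to_channel_stack(rgb), part, channels)
      },
      bbox_pixels = {
        idx <- which(mask == 1, arr.ind = TRUE)
        crop <- rgb[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), ,
                    drop = FALSE]
        method1_features(crop, channels)
      },
      fruit_means = {
        wm <- whole_fruit_means(to_channel_stack(rgb), mask)
        wm[, channels, drop = FALSE]
      }
    )
    meta <- tibble(.rows = 1)
    if ("instance_id" %in% names(data)) meta$instance_id <- data$instance_id[[i]]
    if ("label" %in% names(data)) meta$label <- data$label[[i]]
    bind_cols(meta, feats)
  })
  bind_rows(rows)
}

#' Write a feature table to CSV
#'
#' @param features Tibble from [extract_features()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
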