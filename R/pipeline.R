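# End-to-end orchestration: image + per-instance masks in, per-instance
# ripeness stage + probability out, with an annotated-overlay renderer.
# Segmentation is pluggable by construction: masks arrive as matrices (from
# PNG files, labelme JSON or any detector adapter); nothing here produces
# them.

#' Run the grading pipeline over one image
#'
#' For each instance mask: preprocess, partition into R1..R4, extract
#' regional colour features, and predict the stage with the supplied model.
#' Failures (empty/too small masks, degenerate geometry) are reported as
#' structured error codes in the result row — a bad instance never aborts
#' the batch and is never dropped silently.
#'
#' @param image H x W x 3 array, 0--255.
#' @param masks List of binary mask matrices aligned with the image (a
#'   tibble with a `mask` list-column also works).
#' @param model A fitted `ripeness_model`.
#' @param channels Channel subset; default recovered from the model schema.
#' @param min_area Minimum instance area in pixels.
#' @return A tibble with one row per input mask: `instance_id`, `stage`,
#'   `probability` (max class probability), `error` (NA or an error class),
#'   `area`, `chord_length`, plus list-columns `partition`, `outline` and
#'   `proba` (the full class-probability vector).
#' @export
run_pipeline <- function(image, masks, model, channels = NULL, min_area = 64) {
  if (is.data.frame(masks)) masks <- masks$mask
  if (length(masks) == 0) {
    return(tibble(instance_id = character(), stage = factor(levels = model$levels),
                  probability = numeric(), error = character(),
                  area = integer(), chord_length = numeric(),
                  partition = list(), outline = list(), proba = list()))
  }
  if (is.null(channels)) {
    channels <- unique(sub("_R[1-4]$", "", model$schema))
  }
  stack <- to_channel_stack(image)
  ids <- names(masks) %||% sprintf("inst_%03d", seq_along(masks))
  rows <- purrr::map(seq_along(masks), function(i) {
    mask <- masks[[i]]
    id <- ids[[i]]
    tryCatch({
      m <- preprocess_mask(mask, min_area = min_area)
      ct <- trace_contour(m)
      ch <- longest_chord(ct, mask_centroid(m))
      part <- partition_mask(m, ch, contour = ct)
      feats <- regional_features(stack, part, channels)
      pr <- predict_proba(model, feats)[1, ]
      k <- which.max(pr)
      tibble(instance_id = id,
             stage = factor(names(pr)[k], levels = model$levels),
             probability = unname(pr[k]), error = NA_character_,
             area = sum(m), chord_length = ch$length,
             partition = list(part), outline = list(ct), proba = list(pr))
    }, berryripe_error = function(e) {
      tibble(instance_id = id, stage = factor(NA, levels = model$levels),
             probability = NA_real_, error = class(e)[1],
             area = sum(as_binary_mask(mask)), chord_length = NA_real_,
             partition = list(NULL), outline = list(NULL), proba = list(NULL))
    })
  })
  bind_rows(rows)
}

# Fixed per-stage annotation colours (RGB 0-255).
stage_palette <- function() {
  list("White" = c(245, 245, 245), "Breaking" = c(255, 210, 80),
       "Turning-1" = c(255, 150, 60), "Turning-2" = c(250, 100, 60),
       "Ripe" = c(230, 40, 40), "Full ripe" = c(150, 20, 40))
}

# 5x7 bitmap glyphs for the overlay labels.
font5x7 <- function() {
  g <- list(
    "A" = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    "B" = c("####.", "#...#", "####.", "#...#", "#...#", "#...#", "####."),
    "E" = c("#####", "#....", "####.", "#....", "#....", "#....", "#####"),
    "F" = c("#####", "#....", "####.", "#....", "#....", "#....", "#...."),
    "G" = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
    "H" = c("#...#", "#...#", "#####", "#...#", "#...#", "#...#", "#...#"),
    "I" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####"),
    "K" = c("#...#", "#..#.", "###..", "#.#..", "#..#.", "#...#", "#...#"),
    "L" = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
    "N" = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
    "P" = c("####.", "#...#", "####.", "#....", "#....", "#....", "#...."),
    "R" = c("####.", "#...#", "####.", "#.#..", "#..#.", "#...#", "#...#"),
    "T" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
    "U" = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    "W" = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
    "0" = c(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
    "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", "#####"),
    "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
    "3" = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
    "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
    "5" = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
    "6" = c(".###.", "#....", "####.", "#...#", "#...#", "#...#", ".###."),
    "7" = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
    "8" = c(".###.", "#...#", ".###.", "#...#", "#...#", "#...#", ".###."),
    "9" = c(".###.", "#...#", "#...#", ".####", "....#", "....#", ".###."),
    "-" = c(".....", ".....", ".....", "#####", ".....", ".....", "....."),
    "." = c(".....", ".....", ".....", ".....", ".....", ".##..", ".##.."),
    "%" = c("##..#", "##..#", "...#.", "..#..", ".#...", "#..##", "#..##"),
    " " = c(".....", ".....", ".....", ".....", ".....", ".....", "....."),
    "?" = c(".###.", "#...#", "....#", "..#..", "..#..", ".....", "..#..")
  )
  g
}

draw_text <- function(image, text, row0, col0, colour) {
  glyphs <- font5x7()
  H <- dim(image)[1]; W <- dim(image)[2]
  chars <- strsplit(toupper(text), "")[[1]]
  for (ci in seq_along(chars)) {
    gl <- glyphs[[chars[ci]]] %||% glyphs[["?"]]
    for (gr in 1:7) {
      bits <- strsplit(gl[gr], "")[[1]] == "#"
      for (gc in 1:5) {
        if (!bits[gc]) next
        r <- row0 + gr - 1
        cl <- col0 + (ci - 1) * 6 + gc - 1
        if (r >= 1 && r <= H && cl >= 1 && cl <= W) {
          image[r, cl, ] <- colour
        }
      }
    }
  }
  image
}

#' Render stage annotations onto an image
#'
#' Draws each successfully graded instance's outline in its stage colour
#' (fixed deterministic palette) and prints the stage name and max class
#' probability above the instance. Instances that failed grading are
#' skipped. With zero results, the image is returned unmodified.
#'
#' @param image H x W x 3 array, 0--255.
#' @param results Tibble from [run_pipeline()].
#' @return The annotated H x W x 3 array.
#' @export
render_overlay <- function(image, results) {
  image <- as_rgb_array(image)
  if (nrow(results) == 0) return(image)
  pal <- stage_palette()
  H <- dim(image)[1]; W <- dim(image)[2]
  for (i in seq_len(nrow(results))) {
    if (!is.na(results$error[i])) next
    colr <- pal[[as.character(results$stage[i])]]
    ct <- results$outline[[i]]
    # thicken the outline by also painting the 4-neighbours
    for (off in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      rr <- ct[, "y"] + 1 + off[1]
      cc <- ct[, "x"] + 1 + off[2]
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      for (k in 1:3) {
        ch <- image[, , k]
        ch[cbind(rr[ok], cc[ok])] <- colr[k]
        image[, , k] <- ch
      }
    }
    label <- sprintf("%s %.2f", as.character(results$stage[i]),
                     results$probability[i])
    row0 <- max(min(ct[, "y"]) + 1 - 9, 1)
    col0 <- max(min(ct[, "x"]) + 1, 1)
    image <- draw_text(image, label, row0, col0, colr)
  }
  image
}
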