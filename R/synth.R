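# Seeded synthetic strawberry instances.
#
# The generator emulates what the six-stage grading scheme keys on: a convex
# teardrop silhouette in roughly fruit-hanging orientation (tip down, within
# +/- 30 degrees), and a red region that grows from the tip upward with a
# stage-specific red fraction (White 0, Breaking 1/5, Turning-1 2/5,
# Turning-2 3/5, Ripe 4/5, Full ripe 1 in a darker red). The red/green
# boundary is horizontal in fruit coordinates before rotation; Gaussian
# pixel noise and a smooth transition band blur it. It does not attempt
# photorealism: no achenes, calyx, lighting or background clutter.

#' Stage colour model for the synthetic generator
#'
#' @param green,red,dark_red RGB triples (0--255) for unripe flesh, ripe red
#'   and the darker red of a fully ripe fruit.
#' @param band Width of the smooth red/green transition band as a fraction
#'   of fruit height.
#' @param noise_sd Gaussian pixel noise, 8-bit units; raising it makes the
#'   classification benchmark monotonically harder.
#' @return A `stage_color_model` list, including the per-stage nominal red
#'   fractions from [ripeness_stages()].
#' @export
stage_color_model <- function(green = c(170, 200, 140), red = c(200, 40, 40),
                              dark_red = c(140, 20, 30), band = 0.08,
                              noise_sd = 6) {
  structure(list(
    red_fraction = setNames(ripeness_stages()$red_fraction, stage_levels()),
    green = green, red = red, dark_red = dark_red,
    band = band, noise_sd = noise_sd
  ), class = "stage_color_model")
}

# Half-width profile of the teardrop, u in [0,1] from calyx (0) to tip (1);
# peaks at u ~ 0.31 so the widest row sits above the midline.
teardrop_halfwidth <- function(u) {
  hw <- sqrt(pmax(u, 0)) * pmax(1 - u, 0)^1.1
  hw / (sqrt(0.3125) * 0.6875^1.1)   # normalise peak (at u = 0.5/1.6) to 1
}

#' Generate a teardrop-shaped fruit mask
#'
#' A convex teardrop silhouette, tip pointing down before rotation, with
#' mild seeded shape jitter (elongation and left/right skew). Rotation is in
#' degrees, positive clockwise in image coordinates.
#'
#' @param height,width Patch dimensions in pixels (>= 16).
#' @param elongation Length-to-width ratio of the fruit (~1.3 for a typical
#'   berry).
#' @param rotation Rotation angle in degrees.
#' @param seed Integer seed for the shape jitter; `NULL` for none.
#' @return A 0/1 integer matrix with attribute `fruit_frame` (centre,
#'   rotation and fruit length, used by [paint_stage()] to locate the tip).
#' @export
synth_shape_mask <- function(height = 64, width = 64, elongation = 1.3,
                             rotation = 0, seed = NULL) {
  if (height < 16 || width < 16) {
    stopf("berry_bad_shape_params", "patch dimensions must be >= 16")
  }
  jit <- with_seed(seed, c(el = exp(rnorm(1, 0, 0.05)), skew = rnorm(1, 0, 0.06)))
  if (is.null(seed)) jit <- c(el = 1, skew = 0)
  elong <- elongation * jit[["el"]]
  cx <- (width - 1) / 2
  cy <- (height - 1) / 2
  len <- 0.88 * min(height, width)
  wmax <- len / (2 * elong)
  th <- rotation * pi / 180
  xs <- matrix(rep(0:(width - 1), each = height), height, width) - cx
  ys <- matrix(rep(0:(height - 1), width), height, width) - cy
  # back-rotate into fruit frame: y' along the fruit axis (tip at +len/2)
  xr <- cos(th) * xs + sin(th) * ys
  yr <- -sin(th) * xs + cos(th) * ys
  u <- (yr + len / 2) / len
  hw <- teardrop_halfwidth(u) * wmax
  skewf <- 1 + jit[["skew"]] * (2 * u - 1) * sign(xr)
  inside <- u >= 0 & u <= 1 & abs(xr) <= hw * pmax(skewf, 0.5)
  mask <- matrix(as.integer(inside), height, width)
  if (sum(mask) < 64) {
    stopf("berry_bad_shape_params", "generated mask has %d px (< 64)", sum(mask))
  }
  attr(mask, "fruit_frame") <- list(cx = cx, cy = cy, rotation = rotation, length = len)
  mask
}

# Normalised height-from-tip (0 at tip, 1 at calyx) for each pixel of `mask`,
# in fruit coordinates when the mask carries its frame, else from the mask's
# vertical extent.
height_from_tip <- function(mask) {
  ff <- attr(mask, "fruit_frame")
  idx <- which(mask == 1, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  if (!is.null(ff)) {
    th <- ff$rotation * pi / 180
    yr <- -sin(th) * (x - ff$cx) + cos(th) * (y - ff$cy)
    u <- (yr + ff$length / 2) / ff$length
    v <- 1 - u
  } else {
    v <- (max(y) - y) / max(max(y) - min(y), 1)
  }
  list(idx = idx, v = pmin(pmax(v, 0), 1))
}

#' Paint a mask with stage-specific colours
#'
#' Pixels whose normalised height-from-tip lies below the stage's red
#' fraction are coloured red (dark red at Full ripe), the rest light green,
#' with a smooth transition band and seeded Gaussian pixel noise. Background
#' is neutral grey.
#'
#' @param mask Mask from [synth_shape_mask()].
#' @param stage Stage name, factor or code 0--5.
#' @param color_model A [stage_color_model()].
#' @param seed Integer seed for the pixel noise.
#' @return An H x W x 3 array, 0--255.
#' @export
paint_stage <- function(mask, stage, color_model = stage_color_model(),
                        seed = NULL) {
  stage <- as.character(as_stage(stage))
  rf <- color_model$red_fraction[[stage]]
  red <- if (stage == "Full ripe") color_model$dark_red else color_model$red
  hf <- height_from_tip(mask)
  # boundary height = the rf-quantile of pixel heights, so the red *area*
  # fraction matches the stage definition despite the tapered tip
  thr <- stats::quantile(hf$v, probs = rf, names = FALSE)
  # red weight: 1 well below the boundary, 0 well above, linear in the band
  bw <- color_model$band
  wred <- pmin(pmax((thr - hf$v) / bw + 0.5, 0), 1)
  if (rf >= 1) wred <- rep(1, length(hf$v))
  if (rf <= 0) wred <- rep(0, length(hf$v))
  out <- array(128, dim = c(nrow(mask), ncol(mask), 3))
  for (k in 1:3) {
    ch <- out[, , k]
    ch[hf$idx] <- wred * red[k] + (1 - wred) * color_model$green[k]
    out[, , k] <- ch
  }
  if (color_model$noise_sd > 0) {
    out <- out + with_seed(seed, array(rnorm(length(out), 0, color_model$noise_sd),
                                       dim = dim(out)))
    out <- pmin(pmax(out, 0), 255)
  }
  out
}

#' Generate a balanced synthetic instance dataset
#'
#' Seeded and fully reproducible: every instance's pose, shape jitter and
#' pixel noise derive from per-instance seeds drawn from the master seed.
#' Rotations are uniform within `rotation_range`, emulating fruit-hanging
#' posture with moderate sway.
#'
#' @param n_per_stage Instances per stage (6 stages).
#' @param seed Master seed.
#' @param height,width Patch size.
#' @param color_model A [stage_color_model()].
#' @param rotation_range Max absolute rotation in degrees.
#' @param elongation Mean fruit length-to-width ratio.
#' @return A tibble: `instance_id`, `label` (stage factor), `code`,
#'   `rotation`, `inst_seed`, and list-columns `mask`, `rgb`.
#' @examples
#' \donttest{
#' ds <- synth_dataset(3, seed = 1)
#' table(ds$label)
#' }
#' @export
synth_dataset <- function(n_per_stage, seed = 1, height = 64, width = 64,
                          color_model = stage_color_model(),
                          rotation_range = 30, elongation = 1.3) {
  stopifnot(n_per_stage >= 1)
  n <- 6 * n_per_stage
  meta <- with_seed(seed, tibble(
    instance_id = sprintf("inst_%04d", seq_len(n)),
    label = as_stage(rep(stage_levels(), each = n_per_stage)),
    rotation = runif(n, -rotation_range, rotation_range),
    inst_seed = sample.int(.Machine$integer.max - 1L, n)
  ))
  meta$code <- as.integer(meta$label) - 1L
  meta$mask <- purrr::map2(meta$rotation, meta$inst_seed, function(rot, s) {
    synth_shape_mask(height, width, elongation = elongation,
                     rotation = rot, seed = s)
  })
  meta$rgb <- purrr::pmap(list(meta$mask, as.character(meta$label), meta$inst_seed),
                          function(m, st, s) {
    paint_stage(m, st, color_model, seed = s + 1)
  })
  meta[, c("instance_id", "label", "code", "rotation", "inst_seed", "mask", "rgb")]
}

#' Write a dataset to disk
#'
#' Writes per-instance RGB and mask PNGs, a labelme-style polygon JSON per
#' instance, and a CSV manifest listing paths, labels and seeds.
#'
#' @param data Tibble from [synth_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map(seq_len(nrow(data)), function(i) {
    id <- data$instance_id[[i]]
    img <- file.path(dir, paste0(id, ".png"))
    msk <- file.path(dir, paste0(id, "_mask.png"))
    ann <- file.path(dir, paste0(id, ".json"))
    write_image_png(data$rgb[[i]], img)
    write_mask_png(data$mask[[i]], msk)
    write_labelme(data$mask[[i]], ann, label = as.character(data$label[[i]]))
    tibble(image = basename(img), mask = basename(msk), annotation = basename(ann))
  })
  manifest <- bind_cols(
    data[, c("instance_id", "label", "code", "rotation", "inst_seed")],
    bind_rows(paths)
  )
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Composite a multi-instance scene
#'
#' Places fruit instances on a smoothly textured background. With
#' `occlusion_fraction > 0`, instances after the first are pulled toward an
#' earlier one until the overlap removes at least that fraction of the
#' earlier instance's area; overlapping pixels belong to the instance
#' painted later (the upper one), and the emitted per-instance masks are the
#' visible (post-occlusion) regions — what an upstream segmenter would see.
#'
#' @param n_instances Number of fruits.
#' @param occlusion_fraction Target minimum fractional area loss of at least
#'   one occluded instance (0 for disjoint placement).
#' @param seed Master seed.
#' @param canvas Scene height and width in pixels.
#' @param patch Instance patch size.
#' @param color_model A [stage_color_model()].
#' @return List with `image` (H x W x 3 scene), `masks` (list of visible
#'   masks on scene coordinates), `labels` (stage factor) and `full_areas`
#'   (pre-occlusion pixel counts).
#' @export
synth_scene <- function(n_instances, occlusion_fraction = 0, seed = 1,
                        canvas = c(256, 256), patch = 64,
                        color_model = stage_color_model()) {
  stopifnot(n_instances >= 1)
  H <- canvas[1]; W <- canvas[2]
  ctx <- with_seed(seed, {
    labels <- sample(stage_levels(), n_instances, replace = TRUE)
    seeds <- sample.int(.Machine$integer.max - 1L, n_instances)
    rots <- runif(n_instances, -30, 30)
    # smooth textured background: low-frequency sinusoid mix + noise
    gx <- matrix(rep(seq_len(W), each = H), H, W) / W
    gy <- matrix(rep(seq_len(H), W), H, W) / H
    bg0 <- 110 + 25 * sin(2 * pi * (gx * runif(1, 1, 3) + runif(1))) +
           20 * cos(2 * pi * (gy * runif(1, 1, 3) + runif(1)))
    bg <- array(0, dim = c(H, W, 3))
    bg[, , 1] <- bg0 * 0.55; bg[, , 2] <- bg0 * 0.75; bg[, , 3] <- bg0 * 0.5
    bg <- bg + array(rnorm(length(bg), 0, 4), dim = dim(bg))
    pos <- if (occlusion_fraction > 0) {
      matrix(c(runif(n_instances, 0, H - patch),
               runif(n_instances, 0, W - patch)), ncol = 2)
    } else {
      # disjoint placement: sample patch-sized grid cells without replacement
      gr <- floor(H / patch); gc <- floor(W / patch)
      if (gr * gc < n_instances) {
        stopf("berry_bad_shape_params",
              "canvas holds %d disjoint %d-px instances; %d requested",
              gr * gc, patch, n_instances)
      }
      cells <- sample(gr * gc, n_instances) - 1
      cbind((cells %% gr) * patch, (cells %/% gr) * patch)
    }
    list(labels = labels, seeds = seeds, rots = rots,
         bg = pmin(pmax(bg, 0), 255), pos = pos)
  })
  pos <- floor(ctx$pos)
  if (occlusion_fraction > 0 && n_instances > 1) {
    # pull instance 2 onto instance 1 so their boxes overlap substantially
    shift <- round(patch * (1 - min(occlusion_fraction + 0.25, 0.9)))
    pos[2, ] <- pmin(pmax(pos[1, ] + c(shift, 0), 0), c(H, W) - patch)
  }
  image <- ctx$bg
  owner <- matrix(0L, H, W)
  full_areas <- integer(n_instances)
  for (i in seq_len(n_instances)) {
    m <- synth_shape_mask(patch, patch, rotation = ctx$rots[i], seed = ctx$seeds[i])
    rgb <- paint_stage(m, ctx$labels[i], color_model, seed = ctx$seeds[i] + 1)
    full_areas[i] <- sum(m)
    rr <- pos[i, 1] + seq_len(patch); cc <- pos[i, 2] + seq_len(patch)
    sub <- owner[rr, cc]
    sub[m == 1] <- i                    # later instances paint over earlier
    owner[rr, cc] <- sub
    for (k in 1:3) {
      ch <- image[rr, cc, k]
      ch[m == 1] <- rgb[, , k][m == 1]
      image[rr, cc, k] <- ch
    }
  }
  masks <- lapply(seq_len(n_instances), function(i) {
    matrix(as.integer(owner == i), H, W)
  })
  list(image = image, masks = masks,
       labels = as_stage(ctx$labels), full_areas = full_areas)
}
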