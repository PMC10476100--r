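# Self-calibrated convolution: a drop-in replacement for a standard
# convolution layer that splits the kernel set K of shape (C, C, w, h) into
# four groups K1..K4 of shape (C/2, C/2, w, h) — the same total parameter
# count — and uses a down-sampled branch to gate ("calibrate") half of the
# feature maps, enlarging the effective receptive field. Only the inference
# (forward) pass is implemented; feature maps are plain (C, H, W) arrays.

#' Initialise self-calibrated convolution parameters
#'
#' Draws the four kernel groups from a seeded normal distribution (He-style
#' scale, sd = sqrt(2 / (C/2 * w * h))).
#'
#' @param C Channel count (must be even; the block splits channels in half).
#' @param w,h Kernel width and height (odd, so same-padding is symmetric).
#' @param r Down-sampling rate of the calibration branch (integer >= 2).
#' @param seed Integer seed.
#' @return An `scconv_params`: list of kernels `K1`..`K4`, each an array of
#'   dim `(C/2, C/2, w, h)` indexed (out, in, kernel row, kernel col), and
#'   the rate `r`.
#' @examples
#' p <- scconv_init(4, 3, 3, seed = 1)
#' scconv_param_count(p)  # 4^2 * 3 * 3
#' @export
scconv_init <- function(C, w, h, r = 4, seed = 0) {
  if (C %% 2 != 0 || C < 2) stopf("berry_bad_shape", "C must be even and >= 2")
  if (w %% 2 != 1 || h %% 2 != 1) stopf("berry_bad_shape", "w and h must be odd")
  if (r < 2 || r != round(r)) stopf("berry_bad_shape", "r must be an integer >= 2")
  half <- C / 2
  sd <- sqrt(2 / (half * w * h))
  ks <- with_seed(seed, lapply(1:4, function(k) {
    array(rnorm(half * half * w * h, sd = sd), dim = c(half, half, w, h))
  }))
  names(ks) <- paste0("K", 1:4)
  structure(c(ks, list(r = as.integer(r))), class = "scconv_params")
}

#' Total parameter count of the block
#'
#' Equals `C^2 * w * h`, the parameter count of one standard convolution of
#' the same shape: splitting K into four (C/2, C/2, w, h) groups adds no
#' parameters.
#'
#' @param params An `scconv_params`.
#' @return Integer scalar.
#' @export
scconv_param_count <- function(params) {
  sum(vapply(params[paste0("K", 1:4)], length, numeric(1)))
}

# 2-D multi-channel convolution (cross-correlation), stride 1, zero
# same-padding, no bias. x: (Cin, H, W); k: (Cout, Cin, w, h).
conv2d_same <- function(x, k) {
  dn <- dim(x); cin <- dn[1]; H <- dn[2]; W <- dn[3]
  dk <- dim(k); cout <- dk[1]
  w <- dk[3]; h <- dk[4]
  pw <- (w - 1) / 2; ph <- (h - 1) / 2
  xp <- array(0, dim = c(cin, H + 2 * pw, W + 2 * ph))
  xp[, (pw + 1):(pw + H), (ph + 1):(ph + W)] <- x
  out <- array(0, dim = c(cout, H, W))
  for (a in seq_len(w)) {
    for (b in seq_len(h)) {
      # slab: (cin, H, W) window of the padded input at offset (a, b)
      slab <- xp[, (a):(a + H - 1), (b):(b + W - 1), drop = FALSE]
      sm <- matrix(slab, nrow = cin)             # cin x (H*W)
      km <- matrix(k[, , a, b], nrow = cout, ncol = cin)
      out <- out + array(km %*% sm, dim = c(cout, H, W))
    }
  }
  out
}

avg_pool <- function(x, r) {
  dn <- dim(x)
  if (dn[2] %% r != 0 || dn[3] %% r != 0) {
    stopf("berry_bad_shape", "spatial dims (%d, %d) not divisible by r = %d",
          dn[2], dn[3], r)
  }
  H2 <- dn[2] / r; W2 <- dn[3] / r
  out <- array(0, dim = c(dn[1], H2, W2))
  for (i in seq_len(H2)) {
    for (j in seq_len(W2)) {
      blk <- x[, ((i - 1) * r + 1):(i * r), ((j - 1) * r + 1):(j * r), drop = FALSE]
      out[, i, j] <- apply(blk, 1, mean)
    }
  }
  out
}

# Bilinear upsample (half-pixel-centre alignment, edge clamped) to (H, W).
bilinear_upsample <- function(x, H, W) {
  dn <- dim(x)
  src_pos <- function(n_out, n_in) {
    p <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pmin(pmax(p, 0), n_in - 1)
  }
  py <- src_pos(H, dn[2]); px <- src_pos(W, dn[3])
  y0 <- floor(py); x0 <- floor(px)
  y1 <- pmin(y0 + 1, dn[2] - 1); x1 <- pmin(x0 + 1, dn[3] - 1)
  wy <- py - y0; wx <- px - x0
  out <- array(0, dim = c(dn[1], H, W))
  for (ch in seq_len(dn[1])) {
    m <- x[ch, , ]
    m <- matrix(m, dn[2], dn[3])
    a <- m[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
    b <- m[cbind(rep(y0 + 1, W), rep(x1 + 1, each = H))]
    cc <- m[cbind(rep(y1 + 1, W), rep(x0 + 1, each = H))]
    d <- m[cbind(rep(y1 + 1, W), rep(x1 + 1, each = H))]
    wyv <- rep(wy, W); wxv <- rep(wx, each = H)
    out[ch, , ] <- matrix((1 - wyv) * (1 - wxv) * a + (1 - wyv) * wxv * b +
                          wyv * (1 - wxv) * cc + wyv * wxv * d, H, W)
  }
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Self-calibrated convolution forward pass
#'
#' The input (C, H, W) map is split channel-wise into halves A and B.
#' Branch B is average-pooled by the rate `r`, convolved with K2,
#' bilinearly upsampled back, added to B and passed through the logistic
#' map, yielding calibration weights in (0, 1). These gate the K3
#' convolution of B elementwise; the gated result is convolved with K4.
#' Branch A is convolved with K1. The two halves are concatenated, so the
#' output shape equals the input shape. All convolutions are stride-1,
#' zero-padded, bias-free.
#'
#' @param x Numeric array of dim `(C, H, W)` with `H`, `W` divisible by
#'   `params$r`.
#' @param params An [scconv_init()] parameter set.
#' @return List with `out` (the (C, H, W) output) and `weights` (the
#'   (C/2, H, W) calibration gate).
#' @export
scconv_forward <- function(x, params) {
  dn <- dim(x)
  if (length(dn) != 3) stopf("berry_bad_shape", "x must be a (C, H, W) array")
  half <- dim(params$K1)[1]
  if (dn[1] != 2 * half) {
    stopf("berry_bad_shape", "x has %d channels; params expect %d", dn[1], 2 * half)
  }
  A <- x[seq_len(half), , , drop = FALSE]
  B <- x[half + seq_len(half), , , drop = FALSE]
  up <- bilinear_upsample(conv2d_same(avg_pool(B, params$r), params$K2),
                          dn[2], dn[3])
  weights <- sigmoid(B + up)
  calibrated <- conv2d_same(B, params$K3) * weights
  out2 <- conv2d_same(calibrated, params$K4)
  out1 <- conv2d_same(A, params$K1)
  out <- array(0, dim = dn)
  out[seq_len(half), , ] <- out1
  out[half + seq_len(half), , ] <- out2
  list(out = out, weights = weights)
}

#' @export
print.scconv_params <- function(x, ...) {
  d <- dim(x$K1)
  cat(sprintf("<scconv_params> C = %d, kernel %d x %d, r = %d, %d parameters\n",
              2 * d[1], d[3], d[4], x$r, scconv_param_count(x)))
  invisible(x)
}

#' Export kernel shapes as JSON
#'
#' @param params An `scconv_params`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON describing the four kernel shapes, the rate and the
#'   parameter count.
#' @export
scconv_shapes_json <- function(params, path = NULL) {
  info <- list(
    kernels = lapply(params[paste0("K", 1:4)], dim),
    r = params$r,
    param_count = scconv_param_count(params)
  )
  js <- jsonlite::toJSON(info, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}
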