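# Independent naive oracle: plain scalar loops re-deriving the same
# dataflow (pool -> K2 conv -> bilinear up -> +B -> logistic gate -> K3 conv
# gated -> K4 conv; A -> K1 conv; concat).
naive_conv <- function(x, k) {
  dn <- dim(x); dk <- dim(k)
  out <- array(0, dim = c(dk[1], dn[2], dn[3]))
  pw <- (dk[3] - 1) / 2; ph <- (dk[4] - 1) / 2
  for (o in seq_len(dk[1])) for (i in seq_len(dn[2])) for (j in seq_len(dn[3])) {
    acc <- 0
    for (ci in seq_len(dn[1])) for (a in seq_len(dk[3])) for (b in seq_len(dk[4])) {
      r <- i + a - 1 - pw; cl <- j + b - 1 - ph
      if (r >= 1 && r <= dn[2] && cl >= 1 && cl <= dn[3]) {
        acc <- acc + k[o, ci, a, b] * x[ci, r, cl]
      }
    }
    out[o, i, j] <- acc
  }
  out
}

naive_pool <- function(x, r) {
  dn <- dim(x)
  out <- array(0, dim = c(dn[1], dn[2] / r, dn[3] / r))
  for (ch in seq_len(dn[1])) for (i in seq_len(dn[2] / r)) for (j in seq_len(dn[3] / r)) {
    acc <- 0
    for (a in seq_len(r)) for (b in seq_len(r)) {
      acc <- acc + x[ch, (i - 1) * r + a, (j - 1) * r + b]
    }
    out[ch, i, j] <- acc / r^2
  }
  out
}

naive_upsample <- function(x, H, W) {
  dn <- dim(x)
  out <- array(0, dim = c(dn[1], H, W))
  for (ch in seq_len(dn[1])) for (i in seq_len(H)) for (j in seq_len(W)) {
    py <- min(max((i - 0.5) * dn[2] / H - 0.5, 0), dn[2] - 1)
    px <- min(max((j - 0.5) * dn[3] / W - 0.5, 0), dn[3] - 1)
    y0 <- floor(py); x0 <- floor(px)
    y1 <- min(y0 + 1, dn[2] - 1); x1 <- min(x0 + 1, dn[3] - 1)
    wy <- py - y0; wx <- px - x0
    out[ch, i, j] <- (1 - wy) * (1 - wx) * x[ch, y0 + 1, x0 + 1] +
                     (1 - wy) * wx * x[ch, y0 + 1, x1 + 1] +
                     wy * (1 - wx) * x[ch, y1 + 1, x0 + 1] +
                     wy * wx * x[ch, y1 + 1, x1 + 1]
  }
  out
}

naive_scconv <- function(x, p) {
  C <- dim(x)[1]; half <- C / 2
  A <- x[1:half, , , drop = FALSE]
  B <- x[(half + 1):C, , , drop = FALSE]
  up <- naive_upsample(naive_conv(naive_pool(B, p$r), p$K2), dim(x)[2], dim(x)[3])
  w <- 1 / (1 + exp(-(B + up)))
  cal <- naive_conv(B, p$K3) * w
  out <- array(0, dim = dim(x))
  out[1:half, , ] <- naive_conv(A, p$K1)
  out[(half + 1):C, , ] <- naive_conv(cal, p$K4)
  out
}

zero_params <- function(C, w, h, r = 2) {
  p <- scconv_init(C, w, h, r = r, seed = 1)
  for (k in paste0("K", 1:4)) p[[k]][] <- 0
  p
}
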