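# Small vectorized image operations used by augmentation, resampling and
# Grad-CAM upsampling. All use align-centers sampling semantics.

# bilinear resize of a 2D matrix
bilinear_resize <- function(mat, out_h, out_w) {
  ph <- resample_axis_pos(nrow(mat), out_h)
  pw <- resample_axis_pos(ncol(mat), out_w)
  a <- mat[ph$lo, pw$lo, drop = FALSE]; b <- mat[ph$hi, pw$lo, drop = FALSE]
  c_ <- mat[ph$lo, pw$hi, drop = FALSE]; d <- mat[ph$hi, pw$hi, drop = FALSE]
  fh <- ph$frac; fw <- pw$frac
  top <- a * (1 - fh) + b * fh
  bot <- c_ * (1 - fh) + d * fh
  sweep(top, 2, 1 - fw, "*") + sweep(bot, 2, fw, "*")
}

# rotate a 2D matrix about its center by `deg` degrees, bilinear sampling,
# zero fill outside the source support
rotate_bilinear <- function(mat, deg) {
  if (deg == 0) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  th <- deg * pi / 180
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  yy <- rep(seq_len(h) - 1 - cy, times = w)
  xx <- rep(seq_len(w) - 1 - cx, each = h)
  # inverse mapping: sample source at the back-rotated position
  sy <- cos(th) * yy + sin(th) * xx + cy
  sx <- -sin(th) * yy + cos(th) * xx + cx
  lo_y <- floor(sy); lo_x <- floor(sx)
  fy <- sy - lo_y; fx <- sx - lo_x
  inside <- lo_y >= 0 & lo_y <= h - 2 & lo_x >= 0 & lo_x <= w - 2
  val <- numeric(h * w)
  if (any(inside)) {
    ly <- lo_y[inside] + 1; lx <- lo_x[inside] + 1
    fy_i <- fy[inside]; fx_i <- fx[inside]
    i00 <- ly + (lx - 1) * h
    v <- mat[i00] * (1 - fy_i) * (1 - fx_i) +
      mat[i00 + 1] * fy_i * (1 - fx_i) +
      mat[i00 + h] * (1 - fy_i) * fx_i +
      mat[i00 + h + 1] * fy_i * fx_i
    val[inside] <- v
  }
  matrix(val, h, w)
}

# trilinear resize of a 3D array (H, W, D) to out_dims
trilinear_resize <- function(arr, out_dims) {
  p1 <- resample_axis_pos(dim(arr)[1], out_dims[1])
  arr <- arr[p1$lo, , , drop = FALSE] * (1 - p1$frac) +
    arr[p1$hi, , , drop = FALSE] * p1$frac
  p2 <- resample_axis_pos(dim(arr)[2], out_dims[2])
  f2 <- rep(p2$frac, each = dim(arr)[1])
  arr <- arr[, p2$lo, , drop = FALSE] * (1 - f2) +
    arr[, p2$hi, , drop = FALSE] * f2
  p3 <- resample_axis_pos(dim(arr)[3], out_dims[3])
  f3 <- rep(p3$frac, each = dim(arr)[1] * dim(arr)[2])
  arr[, , p3$lo, drop = FALSE] * (1 - f3) + arr[, , p3$hi, drop = FALSE] * f3
}
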