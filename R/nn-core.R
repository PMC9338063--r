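# Minimal neural-network engine: 3D convolution via im2col + BLAS matmul,
# dense layers, ReLU, global average pooling, and Adam. Backpropagation is
# written out explicitly per layer; correctness is pinned down by
# finite-difference gradient checks in the test suite.

.im2col_cache <- new.env(parent = emptyenv())

he_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

new_conv3d <- function(c_in, c_out, kernel = c(3, 3, 3), stride = c(1, 1, 1),
                       pad = c(1, 1, 1)) {
  k_total <- prod(kernel) * c_in
  list(type = "conv3d",
       W = matrix(he_init(k_total * c_out, k_total), k_total, c_out),
       b = numeric(c_out),
       kernel = as.integer(kernel), stride = as.integer(stride),
       pad = as.integer(pad), c_in = c_in, c_out = c_out)
}

# im2col index matrix for a padded (Hp, Wp, Dp, C) input.
# Column order: kh fastest, then kw, kd, channel slowest.
# Row order: oh fastest, then ow, od (matches column-major output array).
conv3d_indices <- function(in_dim, c_in, kernel, stride, pad) {
  key <- paste(c(in_dim, c_in, kernel, stride, pad), collapse = "_")
  cached <- .im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  hp <- in_dim[1] + 2 * pad[1]; wp <- in_dim[2] + 2 * pad[2]
  dp <- in_dim[3] + 2 * pad[3]
  out <- floor((c(hp, wp, dp) - kernel) / stride) + 1L
  h0 <- (seq_len(out[1]) - 1L) * stride[1] + 1L
  w0 <- (seq_len(out[2]) - 1L) * stride[2] + 1L
  d0 <- (seq_len(out[3]) - 1L) * stride[3] + 1L
  base <- rep(h0, times = out[2] * out[3]) +
    (rep(rep(w0, each = out[1]), times = out[3]) - 1L) * hp +
    (rep(d0, each = out[1] * out[2]) - 1L) * hp * wp
  kh <- seq_len(kernel[1]) - 1L; kw <- seq_len(kernel[2]) - 1L
  kd <- seq_len(kernel[3]) - 1L
  tap <- rep(kh, times = kernel[2] * kernel[3]) +
    rep(rep(kw, each = kernel[1]), times = kernel[3]) * hp +
    rep(kd, each = kernel[1] * kernel[2]) * hp * wp
  chan <- (seq_len(c_in) - 1L) * hp * wp * dp
  offsets <- rep(tap, times = c_in) + rep(chan, each = length(tap))
  idx_sp <- outer(base, tap, "+")            # P x n_taps, spatial only
  idx <- outer(base, offsets, "+")
  res <- list(idx = idx, idx_sp = idx_sp, n_taps = length(tap),
              out_dim = out, pad_dim = c(hp, wp, dp))
  .im2col_cache[[key]] <- res
  res
}

pad_volume <- function(x, pad) {
  if (all(pad == 0)) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * pad[1], d[2] + 2 * pad[2],
                          d[3] + 2 * pad[3], d[4]))
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
      pad[3] + seq_len(d[3]), ] <- x
  out
}

# x: (H, W, D, C_in) -> list(y = (oH, oW, oD, C_out), cache)
conv3d_forward <- function(layer, x) {
  in_dim <- dim(x)[1:3]
  ci <- conv3d_indices(in_dim, layer$c_in, layer$kernel, layer$stride,
                       layer$pad)
  xp <- pad_volume(x, layer$pad)
  # flatten the index matrix: a P x K matrix with K == length(dim(xp))
  # would otherwise be taken as row-wise multi-dimensional indexing
  xcol <- matrix(xp[as.vector(ci$idx)], nrow = nrow(ci$idx))
  y <- xcol %*% layer$W
  y <- sweep(y, 2, layer$b, "+")
  list(y = array(y, dim = c(ci$out_dim, layer$c_out)),
       cache = list(xcol = xcol, ci = ci, in_dim = in_dim))
}

# dy: (oH, oW, oD, C_out). Returns grads and dx (H, W, D, C_in).
conv3d_backward <- function(layer, cache, dy) {
  p <- prod(dim(dy)[1:3])
  dy_mat <- matrix(dy, nrow = p)
  dW <- crossprod(cache$xcol, dy_mat)
  db <- colSums(dy_mat)
  dxcol <- dy_mat %*% t(layer$W)
  pd <- cache$ci$pad_dim
  n_taps <- cache$ci$n_taps
  # scatter per spatial tap, all channels at once; within one tap all
  # output positions map to distinct padded voxels
  dxp_mat <- matrix(0, prod(pd), layer$c_in)
  for (t in seq_len(n_taps)) {
    cols <- t + (seq_len(layer$c_in) - 1L) * n_taps
    ii <- cache$ci$idx_sp[, t]
    dxp_mat[ii, ] <- dxp_mat[ii, ] + dxcol[, cols, drop = FALSE]
  }
  dxp <- array(dxp_mat, dim = c(pd, layer$c_in))
  pad <- layer$pad
  dx <- dxp[pad[1] + seq_len(cache$in_dim[1]),
            pad[2] + seq_len(cache$in_dim[2]),
            pad[3] + seq_len(cache$in_dim[3]), , drop = FALSE]
  list(W = dW, b = db, dx = dx)
}

new_dense <- function(n_in, n_out) {
  list(type = "dense",
       W = matrix(he_init(n_in * n_out, n_in), n_in, n_out),
       b = numeric(n_out))
}

dense_forward <- function(layer, x) {
  # x: vector or matrix (rows = samples)
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  y <- sweep(xm %*% layer$W, 2, layer$b, "+")
  list(y = y, cache = xm)
}

dense_backward <- function(layer, cache, dy) {
  dym <- if (is.matrix(dy)) dy else matrix(dy, nrow = 1)
  list(W = crossprod(cache, dym), b = colSums(dym), dx = dym %*% t(layer$W))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(pre, dy) {
  dy[pre <= 0] <- 0
  dy
}

# ---- Adam over arbitrarily nested parameter lists ----------------------

# apply f to every numeric leaf of a nested list (matrices included)
map_numeric_leaves <- function(x, f) {
  if (is.list(x)) {
    for (nm in seq_along(x)) x[[nm]] <- map_numeric_leaves(x[[nm]], f)
    x
  } else if (is.numeric(x)) {
    f(x)
  } else {
    x
  }
}

adam_init <- function(params) {
  zeros <- map_numeric_leaves(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      nms <- names(p)
      for (i in seq_along(p)) {
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        gi <- tryCatch(g[[key]], error = function(e) NULL)
        if (is.null(gi)) next
        r <- walk(p[[i]], gi, m[[key]], v[[key]])
        out_p[[i]] <- r$p; out_m[[key]] <- r$m; out_v[[key]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else if (is.numeric(p)) {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      mh <- m2 / (1 - beta1^t)
      vh <- v2 / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    } else {
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# elementwise sum of two nested grad lists (a may be NULL)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(b)) {
    nms <- names(b)
    for (i in seq_along(b)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      a[[key]] <- grads_add(a[[key]], b[[i]])
    }
    a
  } else {
    a + b
  }
}

grads_scale <- function(g, s) map_numeric_leaves(g, function(x) x * s)
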