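# 3D convolutional backbone behind a fixed contract: any input window
# (H, W, D, 3) -> 512-d penultimate feature + scalar PE logit. The default
# configuration mirrors the 3D ResNet-18 stage layout (4 stages of 2
# residual blocks, channels 64/128/256/512); the test profile shrinks the
# stages so the same code path runs quickly on a CPU. Blocks are plain
# residual conv blocks (no batch normalization) with He initialization.

#' Configure the 3D backbone
#'
#' @param channels Integer vector of per-stage channel widths.
#' @param blocks Residual blocks per stage (same length as `channels`).
#' @param stem_channels Channels of the stem convolution.
#' @param feature_dim Penultimate feature dimension; the pipeline contract
#'   fixes this at 512.
#' @return An object of class `pe_backbone_config`.
#' @export
backbone_config <- function(channels = c(64, 128, 256, 512),
                            blocks = c(2, 2, 2, 2),
                            stem_channels = channels[1],
                            feature_dim = 512L) {
  stopifnot(length(channels) == length(blocks), feature_dim == 512L)
  structure(list(channels = as.integer(channels), blocks = as.integer(blocks),
                 stem_channels = as.integer(stem_channels),
                 feature_dim = 512L),
            class = "pe_backbone_config")
}

new_block <- function(c_in, c_out, stride) {
  proj <- NULL
  if (c_in != c_out || any(stride != 1)) {
    proj <- new_conv3d(c_in, c_out, kernel = c(1, 1, 1), stride = stride,
                       pad = c(0, 0, 0))
  }
  list(conv1 = new_conv3d(c_in, c_out, stride = stride),
       conv2 = new_conv3d(c_out, c_out),
       proj = proj)
}

#' Initialize backbone parameters
#'
#' @param config A [backbone_config()].
#' @param c_in Input channels (3 display-window channels).
#' @param seed Integer seed for weight initialization.
#' @return A backbone model (nested parameter list with class
#'   `pe_backbone`).
#' @export
backbone_init <- function(config = backbone_config(), c_in = 3, seed = 1L) {
  set.seed(seed)
  stages <- list()
  prev <- config$stem_channels
  for (s in seq_along(config$channels)) {
    blocks <- list()
    for (b in seq_len(config$blocks[s])) {
      stride <- if (b == 1 && s > 1) c(2, 2, 2) else c(1, 1, 1)
      blocks[[b]] <- new_block(prev, config$channels[s], stride)
      prev <- config$channels[s]
    }
    stages[[s]] <- blocks
  }
  structure(list(
    config = config,
    stem = new_conv3d(c_in, config$stem_channels, stride = c(2, 2, 1)),
    stages = stages,
    fc_feat = new_dense(prev, config$feature_dim),
    head = new_dense(config$feature_dim, 1)
  ), class = "pe_backbone")
}

block_forward <- function(block, x) {
  f1 <- conv3d_forward(block$conv1, x)
  a1 <- relu(f1$y)
  f2 <- conv3d_forward(block$conv2, a1)
  if (is.null(block$proj)) {
    res <- x; proj_cache <- NULL
  } else {
    fp <- conv3d_forward(block$proj, x)
    res <- fp$y; proj_cache <- fp$cache
  }
  pre <- f2$y + res
  list(y = relu(pre),
       cache = list(c1 = f1$cache, pre1 = f1$y, c2 = f2$cache,
                    proj = proj_cache, pre = pre))
}

block_backward <- function(block, cache, dy) {
  dpre <- relu_backward(cache$pre, dy)
  b2 <- conv3d_backward(block$conv2, cache$c2, dpre)
  da1 <- relu_backward(cache$pre1, b2$dx)
  b1 <- conv3d_backward(block$conv1, cache$c1, da1)
  dx <- b1$dx
  grads <- list(conv1 = list(W = b1$W, b = b1$b),
                conv2 = list(W = b2$W, b = b2$b))
  if (is.null(block$proj)) {
    dx <- dx + dpre
  } else {
    bp <- conv3d_backward(block$proj, cache$proj, dpre)
    grads$proj <- list(W = bp$W, b = bp$b)
    dx <- dx + bp$dx
  }
  list(grads = grads, dx = dx)
}

#' Forward pass: window tensor to logit and 512-d feature
#'
#' Runs the backbone on one window tensor. The feature is the penultimate
#' (pre-head) 512-d layer output; the logit is the scalar PE head. Forward
#' passes are deterministic (the backbone has no stochastic layers).
#'
#' @param model A `pe_backbone`.
#' @param x A `pe_window_tensor` or bare `(H, W, D, 3)` array in `[0, 1]`.
#' @param keep_cache Keep layer caches for backpropagation / Grad-CAM.
#' @return List with `logit` (scalar), `feature` (length-512), and `cache`
#'   when requested.
#' @export
forward_features <- function(model, x, keep_cache = FALSE) {
  stopifnot(inherits(model, "pe_backbone"))
  if (length(dim(x)) != 4 || dim(x)[4] != model$stem$c_in) {
    abort(sprintf("input must be an (H, W, D, %d) array", model$stem$c_in))
  }
  caches <- list()
  fs <- conv3d_forward(model$stem, x)
  a <- relu(fs$y)
  caches$stem <- fs$cache; caches$stem_pre <- fs$y
  caches$stage <- list()
  for (s in seq_along(model$stages)) {
    caches$stage[[s]] <- list()
    for (b in seq_along(model$stages[[s]])) {
      bf <- block_forward(model$stages[[s]][[b]], a)
      caches$stage[[s]][[b]] <- bf$cache
      a <- bf$y
    }
  }
  caches$final_act <- a                       # last conv activation (pre-GAP)
  sp <- prod(dim(a)[1:3])
  gap <- colMeans(matrix(a, nrow = sp))
  ff <- dense_forward(model$fc_feat, gap)
  fh <- dense_forward(model$head, ff$y)
  caches$gap_in_dim <- dim(a); caches$gap <- ff$cache; caches$feat <- fh$cache
  list(logit = as.numeric(fh$y), feature = as.numeric(ff$y),
       cache = if (keep_cache) caches)
}

backbone_backward <- function(model, cache, dlogit) {
  bh <- dense_backward(model$head, cache$feat, dlogit)
  bf <- dense_backward(model$fc_feat, cache$gap, bh$dx)
  sp <- prod(cache$gap_in_dim[1:3])
  dgap <- as.numeric(bf$dx) / sp
  da <- array(rep(dgap, each = sp), dim = cache$gap_in_dim)
  grads <- list(head = list(W = bh$W, b = bh$b),
                fc_feat = list(W = bf$W, b = bf$b), stages = list())
  for (s in rev(seq_along(model$stages))) {
    grads$stages[[s]] <- list()
    for (b in rev(seq_along(model$stages[[s]]))) {
      bb <- block_backward(model$stages[[s]][[b]], cache$stage[[s]][[b]], da)
      grads$stages[[s]][[b]] <- bb$grads
      da <- bb$dx
    }
  }
  ds <- relu_backward(cache$stem_pre, da)
  bs <- conv3d_backward(model$stem, cache$stem, ds)
  grads$stem <- list(W = bs$W, b = bs$b)
  grads
}
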