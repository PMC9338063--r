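# Phase 2: temporal convolutional network over canonical feature sequences,
# nine attention heads with per-label MLPs, a shared window-logit map, and
# the weighted multitask loss. All forward/backward passes are batched
# matrix operations; sequences are stacked row-wise with position fastest
# (row = t + (b - 1) * T).

#' Configure the TCN
#'
#' Canonical dilated-causal residual TCN settings: kernel size 3, two
#' levels with dilation `2^i` for zero-based level `i` (so 1 and 2),
#' dropout 0.2, 128 output channels. Each convolution pads `(k - 1) * d`
#' causally (left), keeping the output sequence length equal to the input
#' length; each conv is followed by weight normalization, ReLU and dropout,
#' and each level adds a residual connection (a 1x1 convolution when the
#' channel counts differ).
#'
#' @param kernel_size,levels,dropout,out_channels,in_channels TCN settings.
#' @return An object of class `pe_tcn_config`.
#' @export
tcn_config <- function(kernel_size = 3L, levels = 2L, dropout = 0.2,
                       out_channels = 128L, in_channels = 1536L) {
  dilations <- as.integer(2^(seq_len(levels) - 1))
  stopifnot(kernel_size >= 1, all(diff(dilations) > 0) || levels == 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 levels = as.integer(levels), dropout = dropout,
                 out_channels = as.integer(out_channels),
                 in_channels = as.integer(in_channels),
                 dilations = dilations),
            class = "pe_tcn_config")
}

#' Configure phase-2 training
#'
#' Defaults follow the reference recipe: Adam with initial learning rate
#' 5e-4 decayed by 0.9 every 20 steps, batch size 64, 200 epochs, model
#' selected at the minimum validation loss. The `"test"` profile keeps the
#' full model but trains fewer epochs for CPU-scale runs.
#'
#' @param profile `"paper"` or `"test"`.
#' @param learning_rate,decay_every,decay_factor,batch_size,epochs Optimizer.
#' @param tcn A [tcn_config()].
#' @param hidden Hidden width of the per-label two-layer MLPs.
#' @param w Window-loss weight (the reference work leaves it unstated;
#'   default 1).
#' @param w_k Nine per-label study-loss weights (defaults to 1s; the
#'   reference defers them to an external competition metric).
#' @param q_floor Optional floor on the positive-window proportion `q_i`
#'   (default 0 reproduces the printed loss exactly: all-negative studies
#'   contribute no window loss).
#' @param seed Integer seed.
#' @return An object of class `pe_phase2_config`.
#' @export
phase2_config <- function(profile = c("paper", "test"),
                          learning_rate = 5e-4, decay_every = 20L,
                          decay_factor = 0.9, batch_size = 64L,
                          epochs = NULL, tcn = tcn_config(), hidden = 64L,
                          w = 1, w_k = rep(1, 9), q_floor = 0, seed = 1L) {
  profile <- match.arg(profile)
  epochs <- epochs %||% if (profile == "paper") 200L else 30L
  stopifnot(length(w_k) == 9, w >= 0, all(w_k >= 0))
  structure(list(profile = profile, learning_rate = learning_rate,
                 decay_every = as.integer(decay_every),
                 decay_factor = decay_factor,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), tcn = tcn,
                 hidden = as.integer(hidden), w = w, w_k = w_k,
                 q_floor = q_floor, seed = as.integer(seed)),
            class = "pe_phase2_config")
}

new_conv1d_wn <- function(c_in, c_out, kernel) {
  k_total <- kernel * c_in
  v <- matrix(he_init(k_total * c_out, k_total), k_total, c_out)
  list(v = v, g = sqrt(colSums(v^2)), b = numeric(c_out),
       kernel = kernel, c_in = c_in, c_out = c_out)
}

wn_weight <- function(layer) {
  vn <- sqrt(colSums(layer$v^2))
  sweep(layer$v, 2, layer$g / vn, "*")
}

# dw -> (dv, dg) through w = g * v / ||v||
wn_backward <- function(layer, dw) {
  vn <- sqrt(colSums(layer$v^2))
  vhat <- sweep(layer$v, 2, vn, "/")
  dg <- colSums(dw * vhat)
  dv <- sweep(dw, 2, layer$g / vn, "*") -
    sweep(vhat, 2, dg * layer$g / vn, "*")
  list(v = dv, g = dg)
}

# causal gather indices into a zero-row-prepended (B*T+1) stack
causal_idx <- function(B, T, shift) {
  tvec <- rep(seq_len(T), B)
  bvec <- rep(seq_len(B), each = T)
  ifelse(tvec - shift >= 1, (bvec - 1L) * T + tvec - shift + 1L, 1L)
}

conv1d_forward <- function(layer, x, B, T, dilation) {
  k <- layer$kernel
  xz <- rbind(0, x)
  xcol <- matrix(0, nrow(x), k * layer$c_in)
  idxs <- vector("list", k)
  for (j in seq_len(k)) {
    idxs[[j]] <- causal_idx(B, T, (k - j) * dilation)
    xcol[, (j - 1) * layer$c_in + seq_len(layer$c_in)] <- xz[idxs[[j]], ,
                                                             drop = FALSE]
  }
  w <- wn_weight(layer)
  y <- sweep(xcol %*% w, 2, layer$b, "+")
  list(y = y, cache = list(xcol = xcol, idxs = idxs, w = w))
}

conv1d_backward <- function(layer, cache, dy) {
  dw <- crossprod(cache$xcol, dy)
  db <- colSums(dy)
  dxcol <- dy %*% t(cache$w)
  dx <- matrix(0, nrow(dy), layer$c_in)
  k <- layer$kernel
  for (j in seq_len(k)) {
    ii <- cache$idxs[[j]]
    keep <- ii > 1L
    block <- dxcol[, (j - 1) * layer$c_in + seq_len(layer$c_in), drop = FALSE]
    dx[ii[keep] - 1L, ] <- dx[ii[keep] - 1L, ] + block[keep, , drop = FALSE]
  }
  c(wn_backward(layer, dw), list(b = db, dx = dx))
}

#' Initialize the phase-2 model
#'
#' @param config A [phase2_config()].
#' @param labels Study-label names (default [study_label_names()]).
#' @return A `pe_phase2_model`: TCN levels, shared window head, and one
#'   attention head (128-d learned query) plus two-layer MLP per label.
#' @export
phase2_init <- function(config = phase2_config("test"),
                        labels = study_label_names()) {
  set.seed(config$seed)
  tc <- config$tcn
  lvls <- list()
  c_prev <- tc$in_channels
  for (i in seq_len(tc$levels)) {
    lvl <- list(conv1 = new_conv1d_wn(c_prev, tc$out_channels, tc$kernel_size),
                conv2 = new_conv1d_wn(tc$out_channels, tc$out_channels,
                                      tc$kernel_size))
    if (c_prev != tc$out_channels) {
      lvl$proj <- list(W = matrix(he_init(c_prev * tc$out_channels, c_prev),
                                  c_prev, tc$out_channels),
                       b = numeric(tc$out_channels))
    }
    lvls[[i]] <- lvl
    c_prev <- tc$out_channels
  }
  heads <- purrr::map(labels, function(nm) {
    list(w_q = rnorm(tc$out_channels, 0, 1 / sqrt(tc$out_channels)),
         mlp1 = new_dense(tc$out_channels, config$hidden),
         mlp2 = new_dense(config$hidden, 1))
  })
  names(heads) <- labels
  structure(list(config = config, levels = lvls,
                 win = new_dense(tc$out_channels, 1), heads = heads),
            class = "pe_phase2_model")
}

dropout_mask <- function(n_row, n_col, p) {
  matrix((runif(n_row * n_col) >= p) / (1 - p), n_row, n_col)
}

# Batched TCN forward. x: (B*T) x in_channels. Returns X (B*T) x 128.
tcn_forward_batch <- function(model, x, B, T, train = FALSE) {
  tc <- model$config$tcn
  p <- if (train) tc$dropout else 0
  caches <- vector("list", length(model$levels))
  a <- x
  for (i in seq_along(model$levels)) {
    lvl <- model$levels[[i]]
    d <- tc$dilations[i]
    inp <- a
    f1 <- conv1d_forward(lvl$conv1, inp, B, T, d)
    r1 <- relu(f1$y)
    m1 <- if (p > 0) dropout_mask(nrow(r1), ncol(r1), p) else NULL
    h1 <- if (is.null(m1)) r1 else r1 * m1
    f2 <- conv1d_forward(lvl$conv2, h1, B, T, d)
    r2 <- relu(f2$y)
    m2 <- if (p > 0) dropout_mask(nrow(r2), ncol(r2), p) else NULL
    h2 <- if (is.null(m2)) r2 else r2 * m2
    res <- if (is.null(lvl$proj)) inp else {
      sweep(inp %*% lvl$proj$W, 2, lvl$proj$b, "+")
    }
    pre <- h2 + res
    a <- relu(pre)
    caches[[i]] <- list(inp = inp, c1 = f1$cache, pre1 = f1$y, m1 = m1,
                        c2 = f2$cache, pre2 = f2$y, m2 = m2, h1 = h1,
                        pre = pre)
  }
  list(X = a, caches = caches)
}

tcn_backward_batch <- function(model, caches, dX) {
  grads <- list(levels = vector("list", length(model$levels)))
  da <- dX
  for (i in rev(seq_along(model$levels))) {
    lvl <- model$levels[[i]]
    cc <- caches[[i]]
    dpre <- relu_backward(cc$pre, da)
    dh2 <- dpre
    dr2 <- if (is.null(cc$m2)) dh2 else dh2 * cc$m2
    df2 <- relu_backward(cc$pre2, dr2)
    b2 <- conv1d_backward(lvl$conv2, cc$c2, df2)
    dh1 <- b2$dx
    dr1 <- if (is.null(cc$m1)) dh1 else dh1 * cc$m1
    df1 <- relu_backward(cc$pre1, dr1)
    b1 <- conv1d_backward(lvl$conv1, cc$c1, df1)
    dinp <- b1$dx
    g <- list(conv1 = list(v = b1$v, g = b1$g, b = b1$b),
              conv2 = list(v = b2$v, g = b2$g, b = b2$b))
    if (is.null(lvl$proj)) {
      dinp <- dinp + dpre
    } else {
      g$proj <- list(W = crossprod(cc$inp, dpre), b = colSums(dpre))
      dinp <- dinp + dpre %*% t(lvl$proj$W)
    }
    grads$levels[[i]] <- g
    da <- dinp
  }
  grads$dx <- da
  grads
}

#' Run the TCN on one canonical sequence
#'
#' @param model A `pe_phase2_model`.
#' @param canonical A `40 x 1536` matrix ([assemble_sequence()]).
#' @return The `40 x 128` sequence embedding.
#' @export
tcn_forward <- function(model, canonical) {
  stopifnot(inherits(model, "pe_phase2_model"))
  if (nrow(canonical) != CANONICAL_LEN ||
      ncol(canonical) != model$config$tcn$in_channels) {
    abort(sprintf("canonical sequence must be %d x %d", CANONICAL_LEN,
                  model$config$tcn$in_channels))
  }
  tcn_forward_batch(model, canonical, B = 1L, T = CANONICAL_LEN)$X
}

#' Attention pooling over a sequence embedding
#'
#' Computes `a = softmax(tanh(X w_q))` and `e = a . X`, with padded
#' positions masked to `-Inf` before the softmax so the weights form a
#' probability vector over the real windows.
#'
#' @param X `n x d` sequence embedding.
#' @param w_q Length-`d` learned query vector (or a model head).
#' @param mask Logical length-`n` validity mask (default all valid).
#' @return List with `a` (length-`n`, zeros at masked positions, sums to 1)
#'   and `e` (length-`d` pooled embedding).
#' @export
attention_pool <- function(X, w_q, mask = rep(TRUE, nrow(X))) {
  if (is.list(w_q)) w_q <- w_q$w_q
  if (!any(mask)) abort("attention_pool: all positions are masked")
  s <- tanh(as.numeric(X %*% w_q))
  s[!mask] <- -Inf
  a <- exp(s - max(s))
  a <- a / sum(a)
  list(a = a, e = as.numeric(crossprod(X, a)))
}

#' Predict window and study logits from a sequence embedding
#'
#' The shared linear map on per-position embeddings yields the window
#' logits; each of the nine (attention head, MLP) pairs yields one
#' study-level logit.
#'
#' @param model A `pe_phase2_model`.
#' @param X `40 x 128` sequence embedding from [tcn_forward()].
#' @param mask Length-40 validity mask.
#' @param study_id Carried through to the result.
#' @return A `pe_study_prediction`: `window_logits` (length 40, `NA` at
#'   padded positions), `study_logits` (nine named scalars),
#'   `attention_weights` (`9 x 40` row-stochastic over valid positions),
#'   `valid_mask`, `study_id`.
#' @export
predict_heads <- function(model, X, mask = rep(TRUE, CANONICAL_LEN),
                          study_id = "study") {
  stopifnot(inherits(model, "pe_phase2_model"))
  wl <- as.numeric(dense_forward(model$win, X)$y)
  wl[!mask] <- NA_real_
  labels <- names(model$heads)
  att <- matrix(0, length(labels), nrow(X),
                dimnames = list(labels, NULL))
  sl <- setNames(numeric(length(labels)), labels)
  for (nm in labels) {
    h <- model$heads[[nm]]
    ap <- attention_pool(X, h$w_q, mask)
    att[nm, ] <- ap$a
    h1 <- relu(dense_forward(h$mlp1, ap$e)$y)
    sl[nm] <- as.numeric(dense_forward(h$mlp2, h1)$y)
  }
  structure(list(study_id = study_id, window_logits = wl, study_logits = sl,
                 attention_weights = att, valid_mask = mask),
            class = "pe_study_prediction")
}

#' Per-window and per-label loss terms for one study
#'
#' Window term: `-w * q * [y log s(z) + (1 - y) log(1 - s(z))]`, where `q`
#' is the proportion of positive windows in the study (so an all-negative
#' study contributes exactly zero window loss). Study term for label k:
#' `-w_k * [y log s(z) + (1 - y) log(1 - s(z))]`.
#'
#' @param window_logits,window_labels Equal-length numeric/0-1 vectors over
#'   the study's (valid) windows.
#' @param q Proportion of positive windows in the study.
#' @param study_logits,study_labels Length-9 vectors.
#' @param w Scalar window-loss weight.
#' @param w_k Length-9 per-label weights.
#' @return List with `window` (per-window terms) and `study` (per-label
#'   terms).
#' @export
phase2_loss_terms <- function(window_logits, window_labels, q,
                              study_logits, study_labels,
                              w = 1, w_k = rep(1, 9)) {
  window_labels <- check_binary(window_labels, "window_labels")
  study_labels <- check_binary(study_labels, "study_labels")
  stopifnot(length(window_logits) == length(window_labels),
            length(study_logits) == 9, length(study_labels) == 9,
            length(w_k) == 9)
  list(window = w * q * bce_with_logits(window_logits, window_labels),
       study = w_k * bce_with_logits(study_logits, study_labels))
}

#' Combine loss terms into the phase-2 batch loss
#'
#' `L_2nd = sum of all window and study terms / sum_i (N_i + 9)`, where
#' `N_i` is the number of window terms for study `i`.
#'
#' @param terms List of per-study term lists from [phase2_loss_terms()].
#' @return Scalar loss.
#' @export
phase2_batch_loss <- function(terms) {
  if (length(terms) == 0) abort("empty batch")
  total <- sum(purrr::map_dbl(terms, ~ sum(.x$window) + sum(.x$study)))
  denom <- sum(purrr::map_dbl(terms, ~ length(.x$window) + 9))
  total / denom
}
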