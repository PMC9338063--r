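# Phase-2 training: batched forward/backward over canonical sequences,
# Adam with step decay, minimum-validation-loss model selection.

# Precompute canonical sequences + labels for a feature dataset
# (list with features / window_labels / study_labels tibbles).
prepare_sequences <- function(data) {
  mats <- features_by_study(data$features)
  ids <- names(mats)
  wl <- split(data$window_labels, data$window_labels$study_id)
  slab <- data$study_labels
  purrr::map(ids, function(id) {
    w <- wl[[id]]
    labs <- w$pe_present[order(w$window_index)]
    seq <- assemble_sequence(mats[[id]], study_id = id, window_labels = labs)
    srow <- slab[slab$study_id == id, study_label_names()]
    seq$study_labels <- as.integer(unlist(srow[1, ]))
    seq
  })
}

# Stack a list of sequences into batch matrices.
stack_batch <- function(seqs) {
  B <- length(seqs)
  T <- CANONICAL_LEN
  Z <- do.call(rbind, purrr::map(seqs, "canonical"))
  mask <- do.call(rbind, purrr::map(seqs, ~ matrix(.x$valid_mask, 1)))
  ylab <- purrr::map(seqs, "canonical_labels")
  y_w <- as.vector(t(do.call(rbind, purrr::map(ylab, function(l) {
    l[is.na(l)] <- 0L
    matrix(l, 1)
  }))))
  y_s <- do.call(rbind, purrr::map(seqs, ~ matrix(.x$study_labels, 1)))
  q <- purrr::map_dbl(seqs, ~ .x$q %||% 0)
  list(B = B, T = T, Z = Z, mask = mask, y_w = y_w, y_s = y_s, q = q,
       valid_vec = as.vector(t(mask)))
}

# Full batched forward: TCN + window head + nine attention heads.
phase2_forward_batch <- function(model, batch, train = FALSE) {
  tf <- tcn_forward_batch(model, batch$Z, batch$B, batch$T, train = train)
  X <- tf$X
  wl <- as.numeric(dense_forward(model$win, X)$y)
  bvec <- rep(seq_len(batch$B), each = batch$T)
  labels <- names(model$heads)
  z_s <- matrix(0, batch$B, length(labels), dimnames = list(NULL, labels))
  att <- array(0, dim = c(batch$B, batch$T, length(labels)))
  head_caches <- list()
  tmask <- t(batch$mask)                     # T x B
  for (hi in seq_along(labels)) {
    h <- model$heads[[hi]]
    u <- as.numeric(X %*% h$w_q)
    s <- tanh(u)
    sc <- matrix(s, batch$T, batch$B)
    sc[!tmask] <- -Inf
    mx <- apply(sc, 2, max)
    ex <- exp(sweep(sc, 2, mx))
    a <- sweep(ex, 2, colSums(ex), "/")      # T x B, zeros where masked
    a_vec <- as.vector(a)
    e <- rowsum(X * a_vec, bvec)             # B x d
    f1 <- dense_forward(h$mlp1, e)
    h1 <- relu(f1$y)
    f2 <- dense_forward(h$mlp2, h1)
    z_s[, hi] <- as.numeric(f2$y)
    att[, , hi] <- t(a)
    head_caches[[hi]] <- list(s = s, a = a, a_vec = a_vec, e = e,
                              pre1 = f1$y, h1 = h1)
  }
  list(X = X, window_logits = wl, study_logits = z_s, attention = att,
       tcn_caches = tf$caches, head_caches = head_caches, bvec = bvec)
}

# Loss and full gradient for one batch; returns list(loss, grads).
phase2_loss_and_grads <- function(model, batch, fw, w, w_k, q_floor = 0) {
  q_eff <- pmax(batch$q, q_floor)
  q_vec <- rep(q_eff, each = batch$T)
  valid <- batch$valid_vec
  denom <- sum(rowSums(batch$mask)) + 9 * batch$B

  l_w <- w * q_vec * bce_with_logits(fw$window_logits, batch$y_w)
  l_w[!valid] <- 0
  wk_mat <- matrix(w_k, batch$B, 9, byrow = TRUE)
  l_s <- wk_mat * bce_with_logits(fw$study_logits, batch$y_s)
  loss <- (sum(l_w) + sum(l_s)) / denom

  # gradients
  dz_w <- w * q_vec * (sigmoid(fw$window_logits) - batch$y_w) / denom
  dz_w[!valid] <- 0
  dz_s <- wk_mat * (sigmoid(fw$study_logits) - batch$y_s) / denom

  X <- fw$X
  bwin <- dense_backward(model$win, X, matrix(dz_w, ncol = 1))
  dX <- bwin$dx
  grads <- list(win = list(W = bwin$W, b = bwin$b),
                heads = vector("list", length(model$heads)))
  names(grads$heads) <- names(model$heads)
  for (hi in seq_along(model$heads)) {
    h <- model$heads[[hi]]
    hc <- fw$head_caches[[hi]]
    dz <- matrix(dz_s[, hi], ncol = 1)
    b2 <- dense_backward(h$mlp2, hc$h1, dz)
    dh1 <- relu_backward(hc$pre1, b2$dx)
    b1 <- dense_backward(h$mlp1, hc$e, dh1)
    de <- b1$dx                               # B x d
    # e = sum_t a_t X_t
    de_rows <- de[fw$bvec, , drop = FALSE]
    da <- matrix(rowSums(X * de_rows), batch$T, batch$B)
    dX <- dX + hc$a_vec * de_rows
    a <- hc$a
    ds_mat <- a * sweep(da, 2, colSums(a * da))
    du <- as.vector(ds_mat) * (1 - hc$s^2)
    du[!valid] <- 0
    dX <- dX + outer(du, h$w_q)
    dw_q <- as.numeric(crossprod(X, du))
    grads$heads[[hi]] <- list(w_q = dw_q,
                              mlp1 = list(W = b1$W, b = b1$b),
                              mlp2 = list(W = b2$W, b = b2$b))
  }
  tg <- tcn_backward_batch(model, fw$tcn_caches, dX)
  grads$levels <- tg$levels
  list(loss = loss, grads = grads)
}

# Validation loss in eval mode, chunked to bound memory.
phase2_eval_loss <- function(model, seqs, w, w_k, q_floor = 0,
                             chunk = 64L) {
  total <- 0; denom <- 0
  for (start in seq(1, length(seqs), by = chunk)) {
    sub <- seqs[start:min(start + chunk - 1L, length(seqs))]
    batch <- stack_batch(sub)
    fw <- phase2_forward_batch(model, batch, train = FALSE)
    q_eff <- pmax(batch$q, q_floor)
    q_vec <- rep(q_eff, each = batch$T)
    l_w <- w * q_vec * bce_with_logits(fw$window_logits, batch$y_w)
    l_w[!batch$valid_vec] <- 0
    wk_mat <- matrix(w_k, batch$B, 9, byrow = TRUE)
    l_s <- wk_mat * bce_with_logits(fw$study_logits, batch$y_s)
    total <- total + sum(l_w) + sum(l_s)
    denom <- denom + sum(rowSums(batch$mask)) + 9 * batch$B
  }
  total / denom
}

#' Train the phase-2 sequential model
#'
#' Mini-batch Adam over studies with the multitask loss; the learning rate
#' decays by `decay_factor` every `decay_every` steps. After each epoch the
#' validation loss is computed in evaluation mode and the checkpoint with
#' the minimum validation loss is returned.
#'
#' @param train_data,val_data Feature datasets (lists with `features`,
#'   `window_labels`, `study_labels` tibbles, as produced by
#'   [make_feature_dataset()] or the phase-1 extractor plus label tables).
#'   Must contain disjoint studies.
#' @param config A [phase2_config()].
#' @param verbose Print per-epoch losses.
#' @return A `pe_phase2_checkpoint`: `model`, `config`, `trace`,
#'   `selected_epoch`, `fingerprint`.
#' @export
train_phase2 <- function(train_data, val_data, config = phase2_config("test"),
                         verbose = FALSE) {
  train_seqs <- prepare_sequences(train_data)
  val_seqs <- prepare_sequences(val_data)
  if (length(train_seqs) == 0 || length(val_seqs) == 0) {
    abort("train and validation splits must be nonempty")
  }
  model <- phase2_init(config)
  opt <- adam_init(model)
  set.seed(derive_seed(config$seed, 999L))
  n <- length(train_seqs)
  step <- 0L
  best <- list(loss = Inf, epoch = NA_integer_, model = NULL)
  trace <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      batch <- stack_batch(train_seqs[idx])
      fw <- phase2_forward_batch(model, batch, train = TRUE)
      lg <- phase2_loss_and_grads(model, batch, fw, config$w, config$w_k,
                                  config$q_floor)
      lr <- config$learning_rate *
        config$decay_factor^(step %/% config$decay_every)
      upd <- adam_step(model, lg$grads, opt, lr = lr)
      model <- upd$params
      opt <- upd$state
      step <- step + 1L
      ep_losses <- c(ep_losses, lg$loss)
    }
    val_loss <- phase2_eval_loss(model, val_seqs, config$w, config$w_k,
                                 config$q_floor)
    trace[[epoch]] <- tibble(epoch = epoch, train_loss = mean(ep_losses),
                             val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %d  train %.5f  val %.5f", epoch,
                      mean(ep_losses), val_loss))
    }
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, epoch = epoch, model = model)
    }
  }
  ckpt <- list(model = best$model, config = config,
               trace = dplyr::bind_rows(trace),
               selected_epoch = best$epoch)
  ckpt$fingerprint <- rlang::hash(list(config, best$epoch))
  class(ckpt) <- "pe_phase2_checkpoint"
  ckpt
}

#' Predict window and study probabilities
#'
#' Runs the trained phase-2 model in evaluation mode. Window probabilities
#' are reported per real window: for studies with more than 40 windows the
#' canonical-grid logits are mapped back to the original windows by linear
#' interpolation.
#'
#' @param checkpoint A `pe_phase2_checkpoint`.
#' @param data A feature dataset (see [train_phase2()]).
#' @return List with `study_probs` (tibble: study_id + nine probability
#'   columns), `window_probs` (tibble: study_id, window_index, prob,
#'   pe_present), and `predictions` (list of `pe_study_prediction`).
#' @export
predict_studies <- function(checkpoint, data) {
  stopifnot(inherits(checkpoint, "pe_phase2_checkpoint"))
  model <- checkpoint$model
  seqs <- prepare_sequences(data)
  labels <- names(model$heads)
  preds <- list(); sp_rows <- list(); wp_rows <- list()
  for (start in seq(1, length(seqs), by = 64L)) {
    sub <- seqs[start:min(start + 63L, length(seqs))]
    batch <- stack_batch(sub)
    fw <- phase2_forward_batch(model, batch, train = FALSE)
    for (b in seq_along(sub)) {
      sq <- sub[[b]]
      rows <- (b - 1) * batch$T + seq_len(batch$T)
      wl <- fw$window_logits[rows]
      wl[!sq$valid_mask] <- NA_real_
      att <- t(fw$attention[b, , ])
      dimnames(att) <- list(labels, NULL)
      pred <- structure(list(study_id = sq$study_id, window_logits = wl,
                             study_logits = setNames(fw$study_logits[b, ], labels),
                             attention_weights = att,
                             valid_mask = sq$valid_mask),
                        class = "pe_study_prediction")
      preds[[sq$study_id]] <- pred
      sp_rows[[sq$study_id]] <- as_tibble(c(list(study_id = sq$study_id),
                                            as.list(sigmoid(pred$study_logits))))
      n <- sq$n_windows
      win_logit <- if (n <= CANONICAL_LEN) {
        wl[seq_len(n)]
      } else {
        approx(x = seq(0, n - 1, length.out = CANONICAL_LEN),
               y = wl, xout = seq_len(n) - 1)$y
      }
      wlabs <- data$window_labels[data$window_labels$study_id == sq$study_id, ]
      wlabs <- wlabs[order(wlabs$window_index), ]
      wp_rows[[sq$study_id]] <- tibble(
        study_id = sq$study_id, window_index = seq_len(n) - 1L,
        prob = sigmoid(win_logit),
        pe_present = wlabs$pe_present)
    }
  }
  list(study_probs = dplyr::bind_rows(sp_rows),
       window_probs = dplyr::bind_rows(wp_rows),
       predictions = preds)
}
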