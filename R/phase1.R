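# Phase 1: fine-tune the 3D backbone on window labels, export 512-d
# penultimate features per window.

#' Configure phase-1 training
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 4e-4, batch size 16, 20 epochs; slices resized to 224 px then randomly
#' cropped to 192 px with a random in-plane rotation of up to 15 degrees
#' during training, and resized directly to 192 px for evaluation. The
#' `"test"` profile shrinks the backbone and image sizes so the identical
#' code path trains in seconds on a CPU; the full-scale backbone is a
#' configuration choice, not a separate code path.
#'
#' @param profile `"paper"` or `"test"`.
#' @param learning_rate,batch_size,epochs Optimizer settings.
#' @param resize_px Per-slice resize used before the training crop.
#' @param crop_px Final square crop / eval resize.
#' @param rotation_deg Max absolute rotation during training augmentation.
#' @param backbone A [backbone_config()].
#' @param augment Use stochastic training augmentation (default). When
#'   `FALSE` the deterministic evaluation transform is used for training
#'   too — appropriate for memorization/overfit sanity checks.
#' @param seed Integer seed (weights, shuffling, augmentation).
#' @return An object of class `pe_phase1_config`.
#' @export
phase1_config <- function(profile = c("paper", "test"),
                          learning_rate = 4e-4, batch_size = 16L,
                          epochs = NULL, resize_px = NULL, crop_px = NULL,
                          rotation_deg = 15, backbone = NULL,
                          augment = TRUE, seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    epochs <- epochs %||% 20L
    resize_px <- resize_px %||% 224L
    crop_px <- crop_px %||% 192L
    backbone <- backbone %||% backbone_config()
  } else {
    epochs <- epochs %||% 8L
    resize_px <- resize_px %||% 40L
    crop_px <- crop_px %||% 32L
    backbone <- backbone %||% backbone_config(channels = c(8L, 16L),
                                              blocks = c(1L, 1L))
  }
  structure(list(profile = profile, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 resize_px = as.integer(resize_px),
                 crop_px = as.integer(crop_px),
                 rotation_deg = rotation_deg, backbone = backbone,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "pe_phase1_config")
}

# apply a per-slice 2D op to every (slice, channel) plane of (H, W, D, C)
apply_slices <- function(x, f, out_hw = NULL) {
  d <- dim(x)
  oh <- out_hw[1] %||% d[1]; ow <- out_hw[2] %||% d[2]
  out <- array(0, dim = c(oh, ow, d[3], d[4]))
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[3])) out[, , z, ch] <- f(x[, , z, ch])
  }
  out
}

#' Augment a window tensor
#'
#' Training mode resizes each 2D slice to `resize_px`, applies one random
#' in-plane rotation (a single angle shared by all 10 slices of the window)
#' and a random 3D crop down to `crop_px`; values are re-clamped to
#' `[0, 1]`. Evaluation mode is a deterministic direct resize to `crop_px`
#' with no crop or rotation.
#'
#' @param x A `pe_window_tensor` (`H x W x depth x 3`).
#' @param config A [phase1_config()].
#' @param train Logical; augment stochastically or resize deterministically.
#' @param seed Optional seed making the augmentation reproducible.
#' @return Tensor `crop_px x crop_px x depth x 3` in `[0, 1]`, attributes
#'   preserved.
#' @export
augment_window <- function(x, config, train = FALSE, seed = NULL) {
  at <- attributes(x)
  if (!train) {
    out <- apply_slices(x, function(m) {
      bilinear_resize(m, config$crop_px, config$crop_px)
    }, out_hw = c(config$crop_px, config$crop_px))
  } else {
    if (!is.null(seed)) set.seed(seed)
    out <- apply_slices(x, function(m) {
      bilinear_resize(m, config$resize_px, config$resize_px)
    }, out_hw = c(config$resize_px, config$resize_px))
    angle <- runif(1, -config$rotation_deg, config$rotation_deg)
    out <- apply_slices(out, function(m) rotate_bilinear(m, angle))
    max_off <- config$resize_px - config$crop_px
    oy <- sample.int(max_off + 1L, 1L) - 1L
    ox <- sample.int(max_off + 1L, 1L) - 1L
    out <- out[oy + seq_len(config$crop_px), ox + seq_len(config$crop_px), , ,
               drop = FALSE]
    out <- pmin(pmax(out, 0), 1)
  }
  attributes(out) <- c(attributes(out),
                       at[setdiff(names(at), c("dim", "dimnames"))])
  out
}

#' Phase-1 batch loss
#'
#' Mean binary cross-entropy with logits over a mini-batch:
#' `l(z, y) = -[y log s(z) + (1 - y) log(1 - s(z))]`, averaged.
#'
#' @param logits Numeric vector of window logits.
#' @param labels 0/1 vector, same length.
#' @return Scalar loss.
#' @export
phase1_batch_loss <- function(logits, labels) {
  if (length(logits) == 0) abort("empty batch")
  if (length(logits) != length(labels)) abort("logits/labels length mismatch")
  labels <- check_binary(labels, "labels")
  mean(bce_with_logits(logits, labels))
}

window_label <- function(t) attr(t, "label") %||% 0L

#' Train the phase-1 window classifier
#'
#' Mini-batch Adam on the binary window labels; after each epoch the
#' validation AUROC is computed in evaluation mode, and the checkpoint from
#' the epoch with the maximum validation AUROC is returned (ties broken by
#' the earliest epoch).
#'
#' @param train_tensors,val_tensors Lists of `pe_window_tensor` objects
#'   carrying `label` attributes; the two sets must come from disjoint
#'   studies.
#' @param config A [phase1_config()].
#' @param verbose Print per-epoch metrics.
#' @return A checkpoint: list with `model`, `config`, `trace` (tibble of
#'   per-epoch loss and val AUROC), `selected_epoch`, `fingerprint`.
#' @export
train_phase1 <- function(train_tensors, val_tensors, config = phase1_config("test"),
                         verbose = FALSE) {
  if (length(train_tensors) == 0 || length(val_tensors) == 0) {
    abort("train and validation splits must be nonempty")
  }
  model <- backbone_init(config$backbone, seed = config$seed)
  opt <- adam_init(model)
  y_val <- purrr::map_int(val_tensors, window_label)
  # the evaluation transform is deterministic: precompute it once
  val_inputs <- purrr::map(val_tensors, function(t) {
    unclass(augment_window(t, config, train = FALSE))
  })
  fixed_train <- if (!config$augment) {
    purrr::map(train_tensors, function(t) {
      unclass(augment_window(t, config, train = FALSE))
    })
  }
  set.seed(derive_seed(config$seed, 777L))
  n <- length(train_tensors)
  trace <- vector("list", config$epochs)
  best <- list(auroc = -Inf, epoch = NA_integer_, model = NULL)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    epoch_losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      m <- length(idx)
      grads <- NULL
      logits <- numeric(m)
      ys <- numeric(m)
      for (j in seq_len(m)) {
        x_in <- if (config$augment) {
          unclass(augment_window(train_tensors[[idx[j]]], config,
                                 train = TRUE))
        } else {
          fixed_train[[idx[j]]]
        }
        fw <- forward_features(model, x_in, keep_cache = TRUE)
        ys[j] <- window_label(train_tensors[[idx[j]]])
        logits[j] <- fw$logit
        dlogit <- (sigmoid(fw$logit) - ys[j]) / m
        grads <- grads_add(grads, backbone_backward(model, fw$cache, dlogit))
      }
      upd <- adam_step(model, grads, opt, lr = config$learning_rate)
      # adam walks named sublists; stages are unnamed -> walk by structure
      model <- upd$params
      opt <- upd$state
      step <- step + 1L
      epoch_losses <- c(epoch_losses, phase1_batch_loss(logits, ys))
    }
    val_logits <- purrr::map_dbl(val_inputs, function(x_in) {
      forward_features(model, x_in)$logit
    })
    val_auroc <- if (length(unique(y_val)) == 2) {
      roc_curve_auc(sigmoid(val_logits), y_val)$auroc
    } else NA_real_
    trace[[epoch]] <- tibble(epoch = epoch,
                             train_loss = mean(epoch_losses),
                             val_auroc = val_auroc)
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  val AUROC %.4f", epoch,
                      mean(epoch_losses), val_auroc))
    }
    if (!is.na(val_auroc) && val_auroc > best$auroc) {
      best <- list(auroc = val_auroc, epoch = epoch, model = model)
    }
  }
  if (is.null(best$model)) best <- list(auroc = NA, epoch = config$epochs,
                                        model = model)
  ckpt <- list(model = best$model, config = config,
               trace = dplyr::bind_rows(trace),
               selected_epoch = best$epoch)
  ckpt$fingerprint <- rlang::hash(list(config, best$epoch))
  class(ckpt) <- "pe_phase1_checkpoint"
  ckpt
}

#' Extract the 512-d feature table
#'
#' Runs every window through the trained backbone in evaluation mode and
#' returns one feature row per window, ordered by (study_id, window_index).
#'
#' @param tensors List of `pe_window_tensor` objects.
#' @param checkpoint A phase-1 checkpoint from [train_phase1()].
#' @return Tibble: study_id, window_index, f001..f512.
#' @export
extract_feature_table <- function(tensors, checkpoint) {
  stopifnot(inherits(checkpoint, "pe_phase1_checkpoint"))
  rows <- purrr::map_dfr(tensors, function(t) {
    fw <- forward_features(
      checkpoint$model,
      unclass(augment_window(t, checkpoint$config, train = FALSE)))
    feat <- setNames(as.list(fw$feature), sprintf("f%03d", seq_along(fw$feature)))
    as_tibble(c(list(study_id = attr(t, "study_id") %||% "study",
                     window_index = attr(t, "window_index") %||% 0L),
                feat))
  })
  dplyr::arrange(rows, .data$study_id, .data$window_index)
}
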