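# Interpretability: attention-weight saliency over window sequences and
# Grad-CAM heatmaps for the 3D backbone.

#' Attention saliency for one study label
#'
#' Restricts the label's attention row to real (non-padded) windows and
#' renormalizes it into a probability vector; the highlighted window is the
#' argmax (ties resolved to the lowest index).
#'
#' @param pred A `pe_study_prediction` from [predict_heads()] /
#'   [predict_studies()].
#' @param label One of [study_label_names()].
#' @return A `pe_saliency_map`: `label`, `weights` (over real windows,
#'   summing to 1), `highlighted_window` (1-based index).
#' @export
attention_heatmap <- function(pred, label) {
  stopifnot(inherits(pred, "pe_study_prediction"))
  if (!label %in% rownames(pred$attention_weights)) {
    abort(sprintf("unknown label '%s'", label))
  }
  w <- pred$attention_weights[label, pred$valid_mask]
  w <- w / sum(w)
  structure(list(label = label, weights = w,
                 highlighted_window = which.max(w),
                 study_id = pred$study_id),
            class = "pe_saliency_map")
}

#' @export
print.pe_saliency_map <- function(x, ...) {
  cat(sprintf("<pe_saliency_map %s/%s>  %d windows, argmax = %d (weight %.3f)\n",
              x$study_id %||% "?", x$label, length(x$weights),
              x$highlighted_window, max(x$weights)))
  invisible(x)
}

#' Plot an attention saliency map
#'
#' @param object A `pe_saliency_map`.
#' @param ... Unused.
#' @return A ggplot bar heatmap of attention weight per window.
#' @export
autoplot.pe_saliency_map <- function(object, ...) {
  df <- tibble(window = seq_along(object$weights) - 1L,
               weight = object$weights)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = 1,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
    ggplot2::labs(x = "window index", y = NULL, fill = "attention",
                  title = sprintf("Attention weights: %s", object$label)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' 3D Grad-CAM for the phase-1 backbone
#'
#' Gradient-weighted class activation mapping at the final convolutional
#' activation of the deepest residual stage: channel importances are the
#' spatial means of the logit gradient at that activation, the heatmap is
#' the rectified importance-weighted sum of activation channels, trilinearly
#' upsampled to the input window grid. Applied to the phase-1 backbone only
#' (gradients do not flow through the phase-2 sequential model).
#'
#' @param window A `pe_window_tensor` (already augmented/resized as for
#'   evaluation) or bare `(H, W, D, 3)` array.
#' @param model A `pe_backbone` or phase-1 checkpoint.
#' @return A `pe_cam_volume`: nonnegative `H x W x D` array matching the
#'   input spatial grid, plus the raw logit.
#' @export
grad_cam_3d <- function(window, model) {
  if (inherits(model, "pe_phase1_checkpoint")) model <- model$model
  stopifnot(inherits(model, "pe_backbone"))
  x <- unclass(window)
  fw <- forward_features(model, x, keep_cache = TRUE)
  # backprop the logit through the two dense layers down to the GAP input
  bh <- dense_backward(model$head, fw$cache$feat, 1)
  bf <- dense_backward(model$fc_feat, fw$cache$gap, bh$dx)
  in_dim <- fw$cache$gap_in_dim
  sp <- prod(in_dim[1:3])
  act <- fw$cache$final_act
  # per-voxel gradient is constant per channel under global average pooling,
  # so the spatial mean of gradients equals it
  importance <- as.numeric(bf$dx) / sp
  amat <- matrix(act, nrow = sp)
  cam <- matrix(amat %*% importance, in_dim[1], in_dim[2] * in_dim[3])
  cam <- array(pmax(cam, 0), dim = in_dim[1:3])
  up <- trilinear_resize(cam, dim(x)[1:3])
  structure(list(values = up, logit = fw$logit,
                 source_dim = in_dim[1:3]),
            class = "pe_cam_volume")
}

#' @export
print.pe_cam_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pe_cam_volume>  %d x %d x %d, mass %.3f, logit %.3f\n",
              d[1], d[2], d[3], sum(x$values), x$logit))
  invisible(x)
}

#' Center of mass of a Grad-CAM volume
#'
#' @param cam A `pe_cam_volume`.
#' @return Numeric `(y, x, z)` center of mass in 0-based voxel coordinates,
#'   or `NA`s for an all-zero heatmap.
#' @export
cam_center_of_mass <- function(cam) {
  v <- cam$values
  total <- sum(v)
  if (total == 0) return(c(y = NA_real_, x = NA_real_, z = NA_real_))
  idx <- which(v > 0, arr.ind = TRUE)
  w <- v[idx]
  c(y = sum((idx[, 1] - 1) * w) / total,
    x = sum((idx[, 2] - 1) * w) / total,
    z = sum((idx[, 3] - 1) * w) / total)
}

#' Write Grad-CAM artifacts
#'
#' Saves the heatmap as a NIfTI volume and, when a PNG device is available,
#' a per-slice overlay grid (window slices in grey, heatmap in red, both
#' normalized to `[0, 1]` per window).
#'
#' @param cam A `pe_cam_volume`.
#' @param window The input window tensor it explains.
#' @param path_prefix Output path prefix (writes `<prefix>.nii.gz` and
#'   `<prefix>.png`).
#' @return Paths written, invisibly.
#' @export
write_cam_overlay <- function(cam, window, path_prefix) {
  nii <- file.path(paste0(path_prefix, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(cam$values), nii)
  png_path <- paste0(path_prefix, ".png")
  hm <- cam$values / max(max(cam$values), 1e-12)
  ok <- tryCatch({
    grDevices::png(png_path, width = 200 * 5, height = 200 * 2)
    graphics::par(mfrow = c(2, 5), mar = c(0.5, 0.5, 1.5, 0.5))
    for (z in seq_len(dim(hm)[3])) {
      base <- window[, , z, 1]
      col_img <- grDevices::rgb(pmin(1, base + hm[, , z]), base, base)
      dim(col_img) <- dim(base)
      graphics::plot(c(0, 1), c(0, 1), type = "n", axes = FALSE,
                     xlab = "", ylab = "", main = sprintf("slice %d", z))
      graphics::rasterImage(col_img, 0, 0, 1, 1)
    }
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    warn(sprintf("PNG overlay not written: %s", conditionMessage(e)))
    FALSE
  })
  invisible(c(nii, if (ok) png_path))
}
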