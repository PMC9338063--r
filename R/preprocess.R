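# CT-specific preprocessing: raw pixels -> HU -> 1 mm isotropic grid ->
# lung bounding box -> ordered 10-slice windows -> 3-channel [0,1] tensors.

#' Construct a raw CT series
#'
#' Holds per-slice raw integer pixels together with the rescale slope and
#' intercept needed for Hounsfield-unit conversion, per-slice axial
#' positions, and in-plane pixel spacing. Slices may arrive in any order;
#' [to_hounsfield()] sorts them by z (bottom to top), breaking exact ties by
#' `instance_numbers`.
#'
#' @param pixels List of 2D integer matrices (one per slice), all same shape.
#' @param slope,intercept HU rescale: `HU = raw * slope + intercept`.
#' @param z_positions Numeric, per-slice axial position in mm.
#' @param pixel_spacing Numeric pair (y, x) in mm.
#' @param slice_labels Optional per-slice 0/1 PE labels (same order as
#'   `pixels`).
#' @param instance_numbers Optional integer tie-break for duplicate z.
#' @param study_id Character id.
#' @return An object of class `pe_raw_series`.
#' @export
raw_series <- function(pixels, slope, intercept, z_positions, pixel_spacing,
                       slice_labels = NULL, instance_numbers = NULL,
                       study_id = "series") {
  if (length(pixels) == 0) abort("series must contain at least one slice")
  if (length(z_positions) != length(pixels)) {
    abort("z_positions must match the number of slices")
  }
  structure(list(pixels = pixels, slope = slope, intercept = intercept,
                 z_positions = as.numeric(z_positions),
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_labels = slice_labels,
                 instance_numbers = instance_numbers,
                 study_id = study_id),
            class = "pe_raw_series")
}

#' Convert a raw series to Hounsfield units
#'
#' Applies the affine rescale `HU = raw * slope + intercept` voxelwise and
#' stacks slices in ascending z order (bottom to top). The z spacing is
#' taken from the median gap between consecutive slice positions.
#'
#' @param series A [raw_series()].
#' @return An (unresampled) [ct_study()].
#' @export
to_hounsfield <- function(series) {
  stopifnot(inherits(series, "pe_raw_series"))
  if (is.null(series$slope) || is.null(series$intercept) ||
      !is.finite(series$slope) || series$slope == 0) {
    abort("series is missing a finite, nonzero rescale slope/intercept")
  }
  z <- series$z_positions
  ord <- order(z, series$instance_numbers %||% seq_along(z))
  if (anyDuplicated(z) && is.null(series$instance_numbers)) {
    abort("duplicate z positions with no instance numbers to break ties")
  }
  n <- length(series$pixels)
  dims <- dim(series$pixels[[1]])
  vol <- array(NA_real_, dim = c(dims[1], dims[2], n))
  for (i in seq_len(n)) {
    vol[, , i] <- series$pixels[[ord[i]]] * series$slope + series$intercept
  }
  z_spacing <- if (n > 1) stats::median(diff(z[ord])) else 1
  ct_study(series$study_id, vol,
           spacing_mm = c(z_spacing, series$pixel_spacing),
           slice_labels = if (!is.null(series$slice_labels)) {
             series$slice_labels[ord]
           })
}

# Per-axis linear resampling positions under align-centers semantics.
resample_axis_pos <- function(n_in, n_out) {
  s <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * s - 0.5          # 0-based source coordinate
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  frac <- src - lo
  list(lo = as.integer(lo) + 1L, hi = pmin(as.integer(lo) + 2L, n_in),
       frac = frac, scale = s)
}

#' Resample a CT study to isotropic 1 mm spacing
#'
#' Linear interpolation per axis; the output extent on each axis is the
#' input physical extent rounded to whole millimetres. Slice labels are
#' resampled conservatively: an output slice is positive when its source
#' interval overlaps any positive input slice, so resampling never destroys
#' a positive.
#'
#' @param study A [ct_study()] with known positive spacing.
#' @param target_mm Target spacing (default 1 mm on all axes).
#' @return A [ct_study()] with `spacing_mm = (1, 1, 1)` (or `target_mm`).
#' @export
resample_isotropic <- function(study, target_mm = 1) {
  stopifnot(inherits(study, "ct_study"))
  sp <- study$spacing_mm
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    abort("voxel spacing must be positive and finite on all axes")
  }
  d_in <- dim(study$volume)                 # (H, W, D); spacing is (z, y, x)
  n_out <- pmax(1L, as.integer(round(d_in * c(sp[2], sp[3], sp[1]) / target_mm)))
  vol <- study$volume
  if (n_out[1] != d_in[1]) {
    p <- resample_axis_pos(d_in[1], n_out[1])
    vol <- vol[p$lo, , , drop = FALSE] * (1 - p$frac) +
      vol[p$hi, , , drop = FALSE] * p$frac
  }
  if (n_out[2] != dim(vol)[2]) {
    p <- resample_axis_pos(dim(vol)[2], n_out[2])
    fr <- rep(p$frac, each = dim(vol)[1])
    vol <- vol[, p$lo, , drop = FALSE] * (1 - fr) +
      vol[, p$hi, , drop = FALSE] * fr
  }
  labels <- study$slice_labels
  if (n_out[3] != dim(vol)[3]) {
    p <- resample_axis_pos(dim(vol)[3], n_out[3])
    fr <- rep(p$frac, each = dim(vol)[1] * dim(vol)[2])
    new_vol <- vol[, , p$lo, drop = FALSE] * (1 - fr) +
      vol[, , p$hi, drop = FALSE] * fr
    if (!is.null(labels)) {
      labels <- resample_labels_overlap(labels, dim(vol)[3], n_out[3])
    }
    vol <- new_vol
  }
  ct_study(study$study_id, vol, spacing_mm = rep(target_mm, 3),
           slice_labels = labels, study_labels = study$study_labels)
}

# Output slice i (0-based) covers source-index interval [i*s, (i+1)*s);
# positive iff it overlaps any positive source slice interval [j, j+1).
resample_labels_overlap <- function(labels, n_in, n_out) {
  s <- n_in / n_out
  out <- integer(n_out)
  pos <- which(labels == 1) - 1L
  for (i in seq_len(n_out) - 1L) {
    lo <- i * s; hi <- (i + 1) * s
    if (any(pos + 1 > lo & pos < hi)) out[i + 1L] <- 1L
  }
  out
}

#' A 3D lung bounding box
#'
#' 0-based, half-open voxel indices `[lo, hi)` per axis.
#'
#' @param z0,z1,y0,y1,x0,x1 Box bounds.
#' @return An object of class `lung_box`.
#' @export
lung_box <- function(z0, z1, y0, y1, x0, x1) {
  b <- c(z0 = z0, z1 = z1, y0 = y0, y1 = y1, x0 = x0, x1 = x1)
  if (any(b[c(2, 4, 6)] <= b[c(1, 3, 5)])) {
    abort("lung_box must be nonempty on every axis")
  }
  structure(as.integer(b), names = names(b), class = "lung_box")
}

# Per-slice lung mask: air-density threshold, connected components, drop
# components touching the image border, then binary closing. Masks only feed
# the bounding box, so a threshold segmenter is sufficient; swap in a
# stronger one via the `segmenter` argument of compute_lung_bbox().
threshold_lung_mask <- function(slice, threshold = -320, brush_size = 5) {
  mask <- slice < threshold
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  keep <- array(lab %in% setdiff(seq_len(max(lab)), border), dim = dim(mask))
  if (!any(keep)) return(keep)
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(keep * 1), brush)
  array(as.numeric(closed) > 0.5, dim = dim(mask))
}

#' Localize the lungs with a 3D bounding box
#'
#' Segments the lungs on each axial slice and returns the tight bounding box
#' of the union of masks. The default segmenter thresholds at -320 HU,
#' removes connected components touching the slice border, and applies a
#' binary closing.
#'
#' @param study A resampled [ct_study()].
#' @param segmenter Function `(slice_matrix) -> logical mask`; pluggable.
#' @return A [lung_box()].
#' @export
compute_lung_bbox <- function(study, segmenter = threshold_lung_mask) {
  stopifnot(inherits(study, "ct_study"))
  d <- dim(study$volume)
  z_hit <- logical(d[3])
  y_rng <- c(Inf, -Inf); x_rng <- c(Inf, -Inf)
  for (z in seq_len(d[3])) {
    m <- segmenter(study$volume[, , z])
    if (any(m)) {
      z_hit[z] <- TRUE
      ij <- which(m, arr.ind = TRUE)
      y_rng <- c(min(y_rng[1], min(ij[, 1])), max(y_rng[2], max(ij[, 1])))
      x_rng <- c(min(x_rng[1], min(ij[, 2])), max(x_rng[2], max(ij[, 2])))
    }
  }
  if (!any(z_hit)) {
    abort(paste("lung segmentation found no candidate voxels;",
                "use a full-volume lung_box(0, depth, 0, height, 0, width)",
                "as a fallback"))
  }
  lung_box(min(which(z_hit)) - 1L, max(which(z_hit)),
           y_rng[1] - 1L, y_rng[2], x_rng[1] - 1L, x_rng[2])
}

#' Crop a study to a lung bounding box
#'
#' Truncates the volume and the per-slice labels to the box; only labels for
#' slices inside the box remain.
#'
#' @param study A [ct_study()].
#' @param box A [lung_box()].
#' @return The cropped [ct_study()].
#' @export
crop_to_box <- function(study, box) {
  d <- dim(study$volume)
  if (box["z1"] > d[3] || box["y1"] > d[1] || box["x1"] > d[2]) {
    abort("lung_box exceeds the volume bounds")
  }
  vol <- study$volume[(box["y0"] + 1):box["y1"],
                      (box["x0"] + 1):box["x1"],
                      (box["z0"] + 1):box["z1"], drop = FALSE]
  labels <- study$slice_labels
  if (!is.null(labels)) labels <- labels[(box["z0"] + 1):box["z1"]]
  ct_study(study$study_id, vol, study$spacing_mm,
           slice_labels = labels, study_labels = study$study_labels)
}

#' Split a study into consecutive 10-slice windows
#'
#' Partitions the (cropped) z extent into consecutive, non-overlapping
#' blocks of `window_depth` slices. A terminal partial block is padded by
#' replicating its last real slice up to full depth; its label comes from
#' real slices only. Each window's label is the OR of its member slice
#' labels.
#'
#' @param study A [ct_study()] (typically cropped to the lung box).
#' @param window_depth Slices per window (default 10).
#' @return List of raw windows, each a list with `hu` (`H x W x depth`
#'   array), `label`, `span` (half-open real-slice span, 0-based, within the
#'   input volume), `n_real`, `study_id`, `window_index` (0-based).
#' @export
split_into_windows <- function(study, window_depth = 10) {
  d <- dim(study$volume)
  if (d[3] < 1) abort("study has no slices")
  n_win <- ceiling(d[3] / window_depth)
  labels <- study$slice_labels %||% integer(d[3])
  purrr::map(seq_len(n_win), function(w) {
    z0 <- (w - 1) * window_depth              # 0-based
    z1 <- min(z0 + window_depth, d[3])
    idx <- (z0 + 1):z1
    hu <- study$volume[, , idx, drop = FALSE]
    if (length(idx) < window_depth) {
      pad <- window_depth - length(idx)
      hu <- array(c(hu, rep(hu[, , length(idx)], pad)),
                  dim = c(d[1], d[2], window_depth))
    }
    list(hu = hu, label = as.integer(any(labels[idx] == 1)),
         span = c(z0, z1), n_real = length(idx),
         study_id = study$study_id, window_index = w - 1L)
  })
}

#' Window labels from slice labels
#'
#' OR-reduction of per-slice labels over half-open window spans.
#'
#' @param slice_labels 0/1 vector.
#' @param window_spans List of `c(z0, z1)` half-open 0-based spans covering
#'   the label vector.
#' @return Integer 0/1 vector, one element per span.
#' @export
derive_window_labels <- function(slice_labels, window_spans) {
  slice_labels <- check_binary(slice_labels, "slice_labels")
  purrr::map_int(window_spans, function(sp) {
    as.integer(any(slice_labels[(sp[1] + 1):sp[2]] == 1))
  })
}

#' Radiological display windows
#'
#' A display window is the pair (level L, width W) in HU; rendering clips HU
#' to `[L - W/2, L + W/2]` and maps that range linearly onto `[0, 1]`.
#' The defaults are the standard lung (-600, 1500), PE (100, 700) and
#' mediastinal (40, 400) windows.
#'
#' @param level Window level L in HU.
#' @param width Window width W in HU; must be positive.
#' @return `display_window()`: an object of class `display_window`.
#' @export
display_window <- function(level, width) {
  if (width <= 0) abort("display window width must be positive")
  structure(list(level = level, width = width), class = "display_window")
}

#' @rdname display_window
#' @export
default_display_windows <- function() {
  list(lung = display_window(-600, 1500),
       pe = display_window(100, 700),
       mediastinal = display_window(40, 400))
}

#' @rdname display_window
#' @param window A `display_window`.
#' @return `window_clip_bounds()`: numeric `c(lo, hi) = L -/+ W/2`.
#' @export
window_clip_bounds <- function(window) {
  c(lo = window$level - window$width / 2, hi = window$level + window$width / 2)
}

#' Render a raw HU window through three display windows
#'
#' Channel c is `(clip(HU, L_c - W_c/2, L_c + W_c/2) - (L_c - W_c/2)) / W_c`,
#' a value in `[0, 1]` that saturates exactly at the clip bounds.
#'
#' @param window A raw window from [split_into_windows()], or a bare
#'   `H x W x depth` HU array.
#' @param windows A list of three [display_window()]s
#'   (default [default_display_windows()]).
#' @return A window tensor: `H x W x depth x 3` array in `[0, 1]` of class
#'   `pe_window_tensor`, with attributes `label`, `study_id`,
#'   `window_index`, `n_real` when available.
#' @export
render_channels <- function(window, windows = default_display_windows()) {
  if (length(windows) != 3) abort("exactly three display windows required")
  hu <- if (is.list(window) && !is.null(window$hu)) window$hu else window
  d <- dim(hu)
  out <- array(0, dim = c(d[1], d[2], d[3], 3))
  for (c_i in seq_len(3)) {
    b <- window_clip_bounds(windows[[c_i]])
    out[, , , c_i] <- (pmin(pmax(hu, b[1]), b[2]) - b[1]) / windows[[c_i]]$width
  }
  structure(out, class = "pe_window_tensor",
            label = if (is.list(window)) window$label,
            study_id = if (is.list(window)) window$study_id,
            window_index = if (is.list(window)) window$window_index,
            n_real = if (is.list(window)) window$n_real)
}

#' Preprocess one study end to end
#'
#' HU volume (already converted) -> isotropic resampling -> lung bounding
#' box -> crop -> 10-slice windows -> 3-channel tensors. If the lung
#' segmentation is empty the full volume is used, with a warning.
#'
#' @param study A [ct_study()] in HU.
#' @param windows Display windows for channel rendering.
#' @param window_depth Slices per window.
#' @return List with `tensors` (list of `pe_window_tensor`), `manifest`
#'   (tibble: study_id, window_index, span ends, n_real, label) and `box`
#'   (the [lung_box()] used).
#' @export
preprocess_study <- function(study, windows = default_display_windows(),
                             window_depth = 10) {
  iso <- resample_isotropic(study)
  box <- tryCatch(compute_lung_bbox(iso), error = function(e) {
    warn(sprintf("%s: %s", study$study_id, conditionMessage(e)))
    d <- dim(iso$volume)
    lung_box(0, d[3], 0, d[1], 0, d[2])
  })
  cropped <- crop_to_box(iso, box)
  raw_windows <- split_into_windows(cropped, window_depth)
  tensors <- purrr::map(raw_windows, render_channels, windows = windows)
  manifest <- purrr::map_dfr(raw_windows, function(w) {
    tibble(study_id = w$study_id, window_index = w$window_index,
           z0 = w$span[1], z1 = w$span[2], n_real = w$n_real,
           label = w$label)
  })
  list(tensors = tensors, manifest = manifest, box = box)
}
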