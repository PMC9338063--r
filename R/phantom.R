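#' Describe a planted embolus for a phantom study
#'
#' An embolus is a bright sphere in voxel space, restricted to a half-open
#' axial slice span. Coordinates are 0-based voxel indices ordered (z, y, x).
#'
#' @param center Numeric length-3, sphere center (z, y, x) in voxels.
#' @param radius Sphere radius in voxels.
#' @param span Optional half-open slice span `c(z0, z1)`. The default covers
#'   the slices where the sphere's cross-sectional radius is at least one
#'   voxel, so every labeled slice carries recoverable planted signal (the
#'   sphere's extreme caps are sub-voxel and excluded).
#' @return An object of class `pe_embolus`.
#' @export
embolus <- function(center, radius, span = NULL) {
  stopifnot(length(center) == 3, radius > 0)
  if (is.null(span)) {
    half <- sqrt(max(radius^2 - 1, 0))
    span <- c(floor(center[1] - half), floor(center[1] + half) + 1)
  }
  if (span[2] <= span[1]) abort("embolus span must be nonempty (z0 < z1)")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 span = as.numeric(span)), class = "pe_embolus")
}

#' Specify a phantom CT study
#'
#' A phantom is a piecewise-constant Hounsfield-unit volume plus Gaussian
#' noise: soft-tissue background, an axis-aligned low-density lung box, and
#' bright spherical emboli planted inside the lung. It stands in for a real
#' CT pulmonary angiography study so the full pipeline can be exercised
#' without patient data. All boxes are 0-based, half-open voxel coordinates.
#'
#' @param n_slices Number of axial slices (depth).
#' @param slice_shape Integer pair `(height, width)` in voxels.
#' @param spacing_mm Numeric triple `(z, y, x)` voxel spacing in mm.
#' @param lung_extent Length-6 vector `(z0, z1, y0, y1, x0, x1)`, half-open.
#' @param emboli List of [embolus()] objects (possibly empty).
#' @param background_hu,lung_hu,embolus_hu Mean HU of each tissue class.
#'   Defaults: +40 (soft tissue), -800 (aerated lung), +300 (contrast-filled
#'   clot, bright within the PE display window).
#' @param noise_sd Additive Gaussian noise SD in HU.
#' @param seed Integer RNG seed for the noise field.
#' @param indeterminate,chronic,acute_and_chronic,rv_lv_gte_1 Logical flags
#'   for study attributes with no geometric phantom analogue.
#' @return An object of class `pe_phantom_spec`.
#' @export
phantom_spec <- function(n_slices, slice_shape, spacing_mm = c(1, 1, 1),
                         lung_extent, emboli = list(),
                         background_hu = 40, lung_hu = -800, embolus_hu = 300,
                         noise_sd = 20, seed = 1L,
                         indeterminate = FALSE, chronic = FALSE,
                         acute_and_chronic = FALSE, rv_lv_gte_1 = FALSE) {
  spec <- structure(list(
    n_slices = as.integer(n_slices), slice_shape = as.integer(slice_shape),
    spacing_mm = as.numeric(spacing_mm), lung_extent = as.numeric(lung_extent),
    emboli = emboli, background_hu = background_hu, lung_hu = lung_hu,
    embolus_hu = embolus_hu, noise_sd = noise_sd, seed = as.integer(seed),
    flags = c(indeterminate = indeterminate, chronic = chronic,
              acute_and_chronic = acute_and_chronic, rv_lv_gte_1 = rv_lv_gte_1)
  ), class = "pe_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  d <- spec$n_slices; h <- spec$slice_shape[1]; w <- spec$slice_shape[2]
  le <- spec$lung_extent
  if (length(le) != 6) abort("lung_extent must be (z0, z1, y0, y1, x0, x1)")
  lo <- le[c(1, 3, 5)]; hi <- le[c(2, 4, 6)]
  if (any(hi <= lo)) abort("lung_extent must be nonempty on every axis")
  if (any(lo < 0) || any(hi > c(d, h, w))) {
    abort("lung_extent lies outside the volume bounds")
  }
  if (spec$lung_hu >= spec$background_hu) {
    abort("lung_hu must be below background_hu")
  }
  if (spec$embolus_hu <= spec$lung_hu) {
    abort("embolus_hu must be above lung_hu")
  }
  for (e in spec$emboli) {
    c_lo <- e$center - e$radius; c_hi <- e$center + e$radius
    if (any(c_lo < lo) || any(c_hi > hi)) {
      abort(sprintf(
        "embolus at (%s) with radius %.1f extends outside lung_extent",
        paste(round(e$center, 1), collapse = ", "), e$radius))
    }
    if (e$span[1] < 0 || e$span[2] > d) {
      abort("embolus slice span lies outside the volume")
    }
  }
  if (length(spec$emboli) >= 2) {
    for (i in seq_len(length(spec$emboli) - 1)) {
      for (j in seq(i + 1, length(spec$emboli))) {
        ei <- spec$emboli[[i]]; ej <- spec$emboli[[j]]
        if (sqrt(sum((ei$center - ej$center)^2)) <= ei$radius + ej$radius) {
          abort(sprintf("emboli %d and %d overlap in voxel space", i, j))
        }
      }
    }
  }
  invisible(spec)
}

#' Construct a CT study object
#'
#' The package-wide container for one patient study: an HU voxel grid stored
#' as an `height x width x depth` array (slice d is `volume[, , d]`),
#' per-axis spacing in mm ordered (z, y, x), per-slice binary PE labels, and
#' the nine study-level attribute labels.
#'
#' @param study_id Character scalar.
#' @param volume 3D numeric array, `H x W x D`, in Hounsfield units.
#' @param spacing_mm Numeric triple (z, y, x) in mm.
#' @param slice_labels Integer 0/1 vector of length `D`, or `NULL`.
#' @param study_labels Named 0/1 vector over [study_label_names()], or `NULL`.
#' @return An object of class `ct_study`.
#' @export
ct_study <- function(study_id, volume, spacing_mm,
                     slice_labels = NULL, study_labels = NULL) {
  stopifnot(length(dim(volume)) == 3, length(spacing_mm) == 3)
  if (!is.null(slice_labels) && length(slice_labels) != dim(volume)[3]) {
    abort("slice_labels length must equal the number of slices")
  }
  if (!is.null(study_labels)) {
    study_labels <- study_labels[study_label_names()]
    if (anyNA(study_labels)) abort("study_labels must cover all nine labels")
  }
  structure(list(study_id = study_id, volume = volume,
                 spacing_mm = as.numeric(spacing_mm),
                 slice_labels = if (!is.null(slice_labels)) as.integer(slice_labels),
                 study_labels = study_labels),
            class = "ct_study")
}

#' @export
print.ct_study <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<ct_study %s>  %d x %d x %d voxels, spacing (%.2f, %.2f, %.2f) mm\n",
              x$study_id, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  if (!is.null(x$slice_labels)) {
    cat(sprintf("  %d / %d slices PE-positive\n",
                sum(x$slice_labels), length(x$slice_labels)))
  }
  invisible(x)
}

# Derive the nine study labels from phantom geometry: left/right by embolus
# x-center vs. the volume midline, central within a +/- width/8 band; the
# non-geometric attributes come from spec flags. Negative studies carry
# negative_for_pe = 1 and everything else 0.
phantom_study_labels <- function(spec) {
  labs <- setNames(integer(9), study_label_names())
  if (length(spec$emboli) == 0) {
    labs["negative_for_pe"] <- 1L
    return(labs)
  }
  w <- spec$slice_shape[2]
  mid <- (w - 1) / 2
  band <- w / 8
  for (e in spec$emboli) {
    cx <- e$center[3]
    if (abs(cx - mid) <= band) labs["central_pe"] <- 1L
    else if (cx < mid) labs["left_pe"] <- 1L
    else labs["right_pe"] <- 1L
  }
  labs["indeterminate"] <- as.integer(spec$flags[["indeterminate"]])
  labs["chronic"] <- as.integer(spec$flags[["chronic"]])
  labs["acute_and_chronic"] <- as.integer(spec$flags[["acute_and_chronic"]])
  if (spec$flags[["rv_lv_gte_1"]]) labs["rv_lv_gte_1"] <- 1L
  else labs["rv_lv_lt_1"] <- 1L
  labs
}

#' Generate one phantom CT study
#'
#' Renders the piecewise-constant phantom described by a [phantom_spec()]:
#' background soft tissue, the low-density lung box, planted emboli, plus
#' additive Gaussian noise. A slice's PE label is 1 exactly when the slice
#' index falls in some embolus span; study labels follow the phantom label
#' rule (position from embolus x-coordinate, remaining attributes from flags).
#'
#' @param spec A [phantom_spec()].
#' @param study_id Character id; defaults to `"phantom"`.
#' @return A [ct_study()] in HU with per-slice and study labels.
#' @export
make_phantom_study <- function(spec, study_id = "phantom") {
  validate_phantom_spec(spec)
  d <- spec$n_slices; h <- spec$slice_shape[1]; w <- spec$slice_shape[2]
  vol <- array(spec$background_hu, dim = c(h, w, d))
  le <- spec$lung_extent
  vol[(le[3] + 1):le[4], (le[5] + 1):le[6], (le[1] + 1):le[2]] <- spec$lung_hu

  if (length(spec$emboli) > 0) {
    # voxel center coordinates, 0-based
    ys <- seq_len(h) - 1; xs <- seq_len(w) - 1
    for (e in spec$emboli) {
      z_lo <- max(0, ceiling(e$center[1] - e$radius))
      z_hi <- min(d - 1, floor(e$center[1] + e$radius))
      z_lo <- max(z_lo, e$span[1]); z_hi <- min(z_hi, e$span[2] - 1)
      if (z_hi < z_lo) next
      dy2 <- (ys - e$center[2])^2
      dx2 <- (xs - e$center[3])^2
      plane <- outer(dy2, dx2, "+")
      for (z in z_lo:z_hi) {
        r2 <- e$radius^2 - (z - e$center[1])^2
        if (r2 <= 0) next
        sl <- vol[, , z + 1]
        sl[plane <= r2] <- spec$embolus_hu
        vol[, , z + 1] <- sl
      }
    }
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim = dim(vol))
  }

  slice_labels <- integer(d)
  for (e in spec$emboli) {
    idx <- seq.int(e$span[1], e$span[2] - 1) + 1
    slice_labels[idx] <- 1L
  }

  ct_study(study_id, vol, spec$spacing_mm,
           slice_labels = slice_labels,
           study_labels = phantom_study_labels(spec))
}

#' Generate a phantom dataset
#'
#' Builds a collection of phantom studies with the tabular label schema the
#' real-data reader consumes. Each study draws its noise from a seed stream
#' derived from the top-level seed and the study's position, so adding a
#' study never perturbs earlier ones.
#'
#' @param spec_list Nonempty list of [phantom_spec()] objects.
#' @param seed Top-level integer seed.
#' @return A list with `studies` (named list of [ct_study()]),
#'   `slice_labels` (tibble: study_id, slice_index, pe_present) and
#'   `study_labels` (tibble: study_id + nine label columns).
#' @export
make_phantom_dataset <- function(spec_list, seed = 1L) {
  if (length(spec_list) == 0) abort("spec_list must be nonempty")
  ids <- sprintf("study_%03d", seq_along(spec_list))
  studies <- vector("list", length(spec_list))
  for (i in seq_along(spec_list)) {
    sp <- spec_list[[i]]
    sp$seed <- derive_seed(seed, i)
    studies[[i]] <- make_phantom_study(sp, study_id = ids[i])
  }
  names(studies) <- ids
  list(studies = studies,
       slice_labels = slice_label_table(studies),
       study_labels = study_label_table(studies))
}

slice_label_table <- function(studies) {
  purrr::map_dfr(studies, function(s) {
    tibble(study_id = s$study_id,
           slice_index = seq_along(s$slice_labels) - 1L,
           pe_present = s$slice_labels)
  })
}

study_label_table <- function(studies) {
  purrr::map_dfr(studies, function(s) {
    as_tibble(c(list(study_id = s$study_id), as.list(s$study_labels)))
  })
}

#' Default phantom specifications for a small mixed dataset
#'
#' Convenience generator for pipeline demonstrations and tests: a mixture of
#' PE-negative phantoms and phantoms with one or two planted emboli at
#' varying positions. Geometry is randomized within the lung box from the
#' given seed.
#'
#' @param n_studies Number of phantoms.
#' @param n_positive Number with at least one embolus.
#' @param n_slices,slice_shape,spacing_mm Geometry shared by all phantoms.
#' @param noise_sd Noise SD in HU.
#' @param seed Integer seed driving the randomized geometry.
#' @return List of [phantom_spec()].
#' @export
default_phantom_specs <- function(n_studies = 10, n_positive = 5,
                                  n_slices = 36, slice_shape = c(48, 48),
                                  spacing_mm = c(2.5, 1, 1), noise_sd = 15,
                                  seed = 1L) {
  stopifnot(n_positive <= n_studies)
  h <- slice_shape[1]; w <- slice_shape[2]
  lung <- c(round(n_slices * 0.15), round(n_slices * 0.9),
            round(h * 0.15), round(h * 0.85),
            round(w * 0.1), round(w * 0.9))
  purrr::map(seq_len(n_studies), function(i) {
    set.seed(derive_seed(seed, 10000L + i))
    emb <- list()
    if (i <= n_positive) {
      n_emb <- sample(1:2, 1)
      emb <- purrr::map(seq_len(n_emb), function(j) {
        r <- runif(1, 2.5, 4)
        cz <- runif(1, lung[1] + r, lung[2] - r)
        cy <- runif(1, lung[3] + r, lung[4] - r)
        # alternate sides so position labels vary across studies
        side <- if ((i + j) %% 2 == 0) c(lung[5] + r, w / 2 - w / 8 - 1)
                else c(w / 2 + w / 8 + 1, lung[6] - r)
        cx <- runif(1, side[1], side[2])
        embolus(c(cz, cy, cx), r)
      })
      # retry once on the rare overlap draw
      ok <- tryCatch({
        phantom_spec(n_slices, slice_shape, spacing_mm, lung, emb,
                     noise_sd = noise_sd, rv_lv_gte_1 = i %% 3 == 0)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) emb <- emb[1]
    }
    phantom_spec(n_slices, slice_shape, spacing_mm, lung, emb,
                 noise_sd = noise_sd, rv_lv_gte_1 = i %% 3 == 0)
  })
}
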