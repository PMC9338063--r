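#' Specify a synthetic window-feature dataset
#'
#' Emulates the output of the phase-1 feature extractor: per-study ordered
#' sequences of 512-d window features with planted positives. Negative
#' windows draw from a standard normal in each dimension; positive windows
#' add a mean shift. A scalar `positive_shift` is interpreted as the total
#' class-mean separation in SD units and spread evenly over all dimensions
#' (shift vector `s / sqrt(512)` per coordinate, so its L2 norm is `s`);
#' a length-512 vector is used as-is.
#'
#' Positive studies carry one contiguous run of positive windows (a planted
#' embolism span). Study labels follow `label_rule`:
#' * `"position_by_half"` (default): a positive run confined to the first
#'   half of the sequence labels the study left PE, confined to the second
#'   half right PE, straddling both central PE; `rv_lv_lt_1 = 1` for
#'   positive studies; negative studies get `negative_for_pe = 1`.
#'
#' @param n_studies Number of studies.
#' @param windows_range Integer pair: inclusive range of sequence lengths.
#' @param feature_dim Feature dimension; must be 512 to match phase 1.
#' @param positive_shift Scalar separation in SD units, or a length-512
#'   shift vector.
#' @param positive_fraction Fraction of studies with a planted run.
#' @param run_range Inclusive range of planted-run lengths.
#' @param label_rule Study-label rule name (see above).
#' @param seed Integer seed.
#' @return An object of class `pe_feature_spec`.
#' @export
synthetic_feature_spec <- function(n_studies, windows_range = c(8, 20),
                                   feature_dim = 512, positive_shift = 5,
                                   positive_fraction = 1 / 3,
                                   run_range = c(2, 5),
                                   label_rule = "position_by_half",
                                   seed = 1L) {
  if (feature_dim != 512) abort("feature_dim must be 512 to match phase-1 output")
  if (!length(positive_shift) %in% c(1, feature_dim)) {
    abort("positive_shift must be a scalar or a length-512 vector")
  }
  structure(list(n_studies = as.integer(n_studies),
                 windows_range = as.integer(windows_range),
                 feature_dim = 512L,
                 positive_shift = as.numeric(positive_shift),
                 positive_fraction = positive_fraction,
                 run_range = as.integer(run_range),
                 label_rule = label_rule, seed = as.integer(seed)),
            class = "pe_feature_spec")
}

#' Generate a synthetic feature dataset
#'
#' Draws per-study feature sequences and labels per the specification. The
#' result uses the same tabular schema as [extract_feature_table()], so the
#' phase-2 trainer consumes real and synthetic features interchangeably.
#'
#' @param spec A [synthetic_feature_spec()].
#' @return List with `features` (tibble: study_id, window_index, f001..f512),
#'   `window_labels` (tibble: study_id, window_index, pe_present) and
#'   `study_labels` (tibble: study_id + nine label columns).
#' @export
make_feature_dataset <- function(spec) {
  stopifnot(inherits(spec, "pe_feature_spec"))
  p <- spec$feature_dim
  shift <- if (length(spec$positive_shift) == 1) {
    rep(spec$positive_shift / sqrt(p), p)
  } else spec$positive_shift

  ids <- sprintf("study_%04d", seq_len(spec$n_studies))
  n_pos <- round(spec$n_studies * spec$positive_fraction)
  feat_rows <- vector("list", spec$n_studies)
  wlab_rows <- vector("list", spec$n_studies)
  slab_rows <- vector("list", spec$n_studies)

  for (i in seq_len(spec$n_studies)) {
    set.seed(derive_seed(spec$seed, i))
    n_w <- sample_int_range(spec$windows_range[1], spec$windows_range[2])
    x <- matrix(rnorm(n_w * p), nrow = n_w, ncol = p)
    wlab <- integer(n_w)
    if (i <= n_pos) {
      run_len <- sample_int_range(min(spec$run_range[1], n_w),
                                  min(spec$run_range[2], n_w))
      run_start <- sample_int_range(1L, n_w - run_len + 1L)
      pos_idx <- run_start:(run_start + run_len - 1)
      wlab[pos_idx] <- 1L
      x[pos_idx, ] <- x[pos_idx, ] + rep(shift, each = run_len)
    }
    slab <- feature_study_labels(wlab, spec$label_rule)
    feat <- as_tibble(x, .name_repair = ~ sprintf("f%03d", seq_len(p)))
    feat_rows[[i]] <- dplyr::bind_cols(
      tibble(study_id = ids[i], window_index = seq_len(n_w) - 1L), feat)
    wlab_rows[[i]] <- tibble(study_id = ids[i],
                             window_index = seq_len(n_w) - 1L,
                             pe_present = wlab)
    slab_rows[[i]] <- as_tibble(c(list(study_id = ids[i]), as.list(slab)))
  }

  list(features = dplyr::bind_rows(feat_rows),
       window_labels = dplyr::bind_rows(wlab_rows),
       study_labels = dplyr::bind_rows(slab_rows))
}

feature_study_labels <- function(window_labels, label_rule) {
  labs <- setNames(integer(9), study_label_names())
  if (!any(window_labels == 1)) {
    labs["negative_for_pe"] <- 1L
    return(labs)
  }
  if (label_rule != "position_by_half") {
    abort(sprintf("unknown label_rule '%s'", label_rule))
  }
  n <- length(window_labels)
  pos <- which(window_labels == 1)
  first_half <- pos <= n / 2
  if (all(first_half)) labs["left_pe"] <- 1L
  else if (!any(first_half)) labs["right_pe"] <- 1L
  else labs["central_pe"] <- 1L
  labs["rv_lv_lt_1"] <- 1L
  labs
}

#' Split a feature table into per-study matrices
#'
#' @param features Tibble with `study_id`, `window_index` and `f001..f512`
#'   columns, as produced by [make_feature_dataset()] or
#'   [extract_feature_table()].
#' @return Named list of `N_i x 512` matrices ordered by window_index.
#' @export
features_by_study <- function(features) {
  fcols <- grep("^f[0-9]+$", names(features), value = TRUE)
  split_idx <- split(seq_len(nrow(features)), features$study_id)
  purrr::map(split_idx, function(idx) {
    idx <- idx[order(features$window_index[idx])]
    as.matrix(features[idx, fcols])
  })
}
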