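# Disk formats: NIfTI volumes (RNifti) for images, CSV tables for labels,
# features and predictions, JSON for manifests and reports.

#' Write a phantom or real dataset to disk
#'
#' One NIfTI volume per study (`<study_id>.nii.gz`, with voxel spacing in the
#' header) plus the two label tables: `slice_labels.csv`
#' (study_id, slice_index, pe_present) and `study_labels.csv`
#' (study_id + nine label columns).
#'
#' @param dataset A list as returned by [make_phantom_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ct_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in dataset$studies) {
    img <- RNifti::asNifti(s$volume)
    # header pixdim is (x, y, z); our spacing is stored (z, y, x)
    img <- RNifti::`pixdim<-`(img, rev(s$spacing_mm))
    RNifti::writeNifti(img, file.path(dir, paste0(s$study_id, ".nii.gz")))
  }
  readr::write_csv(dataset$slice_labels, file.path(dir, "slice_labels.csv"))
  readr::write_csv(dataset$study_labels, file.path(dir, "study_labels.csv"))
  invisible(dir)
}

#' Read a CT dataset from disk
#'
#' Counterpart of [write_ct_dataset()]: reads every `*.nii`/`*.nii.gz` volume
#' in `dir` and joins the CSV label tables.
#'
#' @param dir Directory holding volumes and label CSVs.
#' @return A list with `studies`, `slice_labels`, `study_labels`.
#' @export
read_ct_dataset <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(paths) == 0) abort(sprintf("no NIfTI volumes found in %s", dir))
  slice_labels <- read_slice_labels(file.path(dir, "slice_labels.csv"))
  study_labels <- read_study_labels(file.path(dir, "study_labels.csv"))
  studies <- purrr::map(paths, function(p) {
    id <- sub("\\.nii(\\.gz)?$", "", basename(p))
    img <- RNifti::readNifti(p)
    vol <- array(as.numeric(img), dim = dim(img))
    spacing <- rev(RNifti::pixdim(img))
    sl <- slice_labels[slice_labels$study_id == id, ]
    slab <- study_labels[study_labels$study_id == id, ]
    ct_study(id, vol, spacing,
             slice_labels = if (nrow(sl)) sl$pe_present[order(sl$slice_index)],
             study_labels = if (nrow(slab)) {
               unlist(slab[1, study_label_names()])
             })
  })
  names(studies) <- purrr::map_chr(studies, "study_id")
  list(studies = studies, slice_labels = slice_labels,
       study_labels = study_labels)
}

#' @rdname read_ct_dataset
#' @param path CSV path.
#' @export
read_slice_labels <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    study_id = readr::col_character(),
    slice_index = readr::col_integer(),
    pe_present = readr::col_integer()))
}

#' @rdname read_ct_dataset
#' @export
read_study_labels <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    study_id = readr::col_character(), .default = readr::col_integer()))
}

#' Read / write a window feature table
#'
#' Columnar CSV keyed by (study_id, window_index) with feature columns
#' `f001..f512`, the interchange format between the two phases.
#'
#' @param features Feature tibble.
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` the tibble.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    study_id = readr::col_character(),
    window_index = readr::col_integer(),
    .default = readr::col_double()))
}
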