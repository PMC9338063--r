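# Configuration and orchestration: glue the stages into the two-phase
# pipeline with per-stage fingerprints (idempotent reruns) and JSON-lines
# logging.

#' Configure a pipeline run
#'
#' One configuration object drives every stage. Defaults use the CPU test
#' profiles of both phases and a small phantom dataset.
#'
#' @param out_dir Output directory for all artifacts.
#' @param n_studies,n_positive Phantom dataset composition.
#' @param phantom_slices,phantom_shape,phantom_spacing,phantom_noise_sd
#'   Phantom geometry (slices, in-plane shape, (z, y, x) spacing in mm,
#'   HU noise SD).
#' @param phase1 A [phase1_config()].
#' @param phase2 A [phase2_config()].
#' @param display_windows Three [display_window()]s for channel rendering.
#' @param split_fractions Named fractions for the study-level
#'   train/val/test split (stratified by study positivity).
#' @param seed Top-level seed; stage seeds derive from it.
#' @return A `pe_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_studies = 10L, n_positive = 5L,
                            phantom_slices = 36L, phantom_shape = c(48L, 48L),
                            phantom_spacing = c(2.5, 1, 1),
                            phantom_noise_sd = 15,
                            phase1 = phase1_config("test"),
                            phase2 = phase2_config("test"),
                            display_windows = default_display_windows(),
                            split_fractions = c(train = 0.5, val = 0.25,
                                                test = 0.25),
                            seed = 1L) {
  structure(list(out_dir = out_dir, n_studies = as.integer(n_studies),
                 n_positive = as.integer(n_positive),
                 phantom_slices = as.integer(phantom_slices),
                 phantom_shape = as.integer(phantom_shape),
                 phantom_spacing = as.numeric(phantom_spacing),
                 phantom_noise_sd = phantom_noise_sd,
                 phase1 = phase1, phase2 = phase2,
                 display_windows = display_windows,
                 split_fractions = split_fractions,
                 seed = as.integer(seed)),
            class = "pe_pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' YAML serialization that round-trips losslessly through the constructors.
#'
#' @param config A `pe_pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- list(
    out_dir = config$out_dir, n_studies = config$n_studies,
    n_positive = config$n_positive, phantom_slices = config$phantom_slices,
    phantom_shape = config$phantom_shape,
    phantom_spacing = config$phantom_spacing,
    phantom_noise_sd = config$phantom_noise_sd,
    split_fractions = as.list(config$split_fractions),
    seed = config$seed,
    phase1 = unclass_deep(config$phase1),
    phase2 = unclass_deep(config$phase2),
    display_windows = purrr::map(config$display_windows, unclass))
  writeLines(yaml::as.yaml(plain), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) purrr::map(unclass(x), unclass_deep) else unname(x)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  p1 <- y$phase1
  p2 <- y$phase2
  pipeline_config(
    out_dir = y$out_dir, n_studies = y$n_studies, n_positive = y$n_positive,
    phantom_slices = y$phantom_slices,
    phantom_shape = unlist(y$phantom_shape),
    phantom_spacing = unlist(y$phantom_spacing),
    phantom_noise_sd = y$phantom_noise_sd,
    phase1 = phase1_config(p1$profile, p1$learning_rate, p1$batch_size,
                           p1$epochs, p1$resize_px, p1$crop_px,
                           p1$rotation_deg,
                           backbone_config(unlist(p1$backbone$channels),
                                           unlist(p1$backbone$blocks),
                                           p1$backbone$stem_channels),
                           seed = p1$seed),
    phase2 = phase2_config(p2$profile, p2$learning_rate, p2$decay_every,
                           p2$decay_factor, p2$batch_size, p2$epochs,
                           tcn_config(p2$tcn$kernel_size, p2$tcn$levels,
                                      p2$tcn$dropout, p2$tcn$out_channels,
                                      p2$tcn$in_channels),
                           p2$hidden, p2$w, unlist(p2$w_k), p2$q_floor,
                           seed = p2$seed),
    display_windows = purrr::map(y$display_windows,
                                 ~ display_window(.x$level, .x$width)),
    split_fractions = unlist(y$split_fractions),
    seed = y$seed)
}

log_event <- function(out_dir, stage, event, ...) {
  line <- jsonlite::toJSON(c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                  stage = stage, event = event), list(...)),
                           auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(out_dir, "pipeline.log.jsonl"),
      append = TRUE)
}

stage_fingerprint_path <- function(out_dir, stage) {
  file.path(out_dir, sprintf("%s.fingerprint", stage))
}

stage_up_to_date <- function(out_dir, stage, fp) {
  p <- stage_fingerprint_path(out_dir, stage)
  file.exists(p) && identical(readLines(p, warn = FALSE)[1], fp)
}

mark_stage_done <- function(out_dir, stage, fp) {
  writeLines(fp, stage_fingerprint_path(out_dir, stage))
}

require_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    abort(sprintf(
      "stage '%s' requires output of stage '%s' (%s); run that stage first",
      needed_by, stage, path))
  }
  path
}

# Stratified deterministic study split by positivity.
split_studies <- function(study_labels, fractions, seed) {
  pos <- study_labels$study_id[study_labels$negative_for_pe == 0]
  neg <- study_labels$study_id[study_labels$negative_for_pe == 1]
  set.seed(derive_seed(seed, 31L))
  assign_group <- function(ids) {
    ids <- sample(ids)
    n <- length(ids)
    n_train <- max(0, min(max(1, round(n * fractions[["train"]])), n - 2))
    n_val <- max(0, min(max(1, round(n * fractions[["val"]])),
                        n - n_train - 1))
    grp <- rep("test", n)
    grp[seq_len(n_train)] <- "train"
    grp[n_train + seq_len(n_val)] <- "val"
    setNames(grp, ids)
  }
  c(assign_group(pos), assign_group(neg))
}

subset_feature_data <- function(data, ids) {
  list(features = data$features[data$features$study_id %in% ids, ],
       window_labels = data$window_labels[data$window_labels$study_id %in% ids, ],
       study_labels = data$study_labels[data$study_labels$study_id %in% ids, ])
}

#' Run the two-phase pipeline
#'
#' Executes the requested stages in order: `simulate` (phantom dataset),
#' `preprocess` (window tensors + manifest), `train-phase1`,
#' `extract-features`, `train-phase2`, `predict` (held-out test studies),
#' `evaluate` (thresholds from validation predictions, metrics on test) and
#' `interpret` (attention saliency + Grad-CAM for one positive test study).
#' Each stage records a fingerprint of its configuration and upstream
#' fingerprints; rerunning a completed stage with an unchanged
#' configuration is a no-op.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run (default: all, in
#'   order).
#' @param verbose Print progress.
#' @return Invisibly, a list of artifact paths plus the evaluation report
#'   when the `evaluate` stage ran.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "train-phase1",
                                    "extract-features", "train-phase2",
                                    "predict", "evaluate", "interpret"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pe_pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  art <- list(out_dir = out)
  report <- NULL

  data_dir <- file.path(out, "data")
  tensors_rds <- file.path(out, "tensors.rds")
  manifest_csv <- file.path(out, "window_manifest.csv")
  ckpt1_rds <- file.path(out, "phase1_checkpoint.rds")
  features_csv <- file.path(out, "features.csv")
  ckpt2_rds <- file.path(out, "phase2_checkpoint.rds")
  split_csv <- file.path(out, "study_split.csv")

  fp_of <- function(...) rlang::hash(list(...))
  read_fp <- function(stage) {
    p <- stage_fingerprint_path(out, stage)
    if (file.exists(p)) readLines(p, warn = FALSE)[1] else ""
  }

  run_stage <- function(stage, fp, fun) {
    if (!stage %in% stages) return(invisible(NULL))
    if (stage_up_to_date(out, stage, fp)) {
      log_event(out, stage, "skipped_up_to_date")
      if (verbose) message(sprintf("[%s] up to date, skipping", stage))
      return(invisible(NULL))
    }
    if (verbose) message(sprintf("[%s] running", stage))
    log_event(out, stage, "start")
    fun()
    mark_stage_done(out, stage, fp)
    log_event(out, stage, "done")
  }

  # --- simulate ---------------------------------------------------------
  sim_cfg <- list(config$n_studies, config$n_positive, config$phantom_slices,
                  config$phantom_shape, config$phantom_spacing,
                  config$phantom_noise_sd, config$seed)
  run_stage("simulate", fp_of("simulate", sim_cfg), function() {
    specs <- default_phantom_specs(config$n_studies, config$n_positive,
                                   config$phantom_slices, config$phantom_shape,
                                   config$phantom_spacing,
                                   config$phantom_noise_sd,
                                   seed = derive_seed(config$seed, 1L))
    ds <- make_phantom_dataset(specs, seed = derive_seed(config$seed, 2L))
    write_ct_dataset(ds, data_dir)
  })
  art$data_dir <- data_dir

  # --- preprocess -------------------------------------------------------
  pre_fp <- fp_of("preprocess", read_fp("simulate"),
                  purrr::map(config$display_windows, unclass))
  run_stage("preprocess", pre_fp, function() {
    require_artifact(file.path(data_dir, "study_labels.csv"), "simulate",
                     "preprocess")
    ds <- read_ct_dataset(data_dir)
    all_tensors <- list(); manifests <- list()
    for (s in ds$studies) {
      pp <- preprocess_study(s, windows = config$display_windows)
      all_tensors <- c(all_tensors, pp$tensors)
      manifests[[s$study_id]] <- pp$manifest
    }
    saveRDS(all_tensors, tensors_rds)
    manifest <- dplyr::bind_rows(manifests)
    readr::write_csv(manifest, manifest_csv)
    jsonlite::write_json(manifest, file.path(out, "window_manifest.json"))
  })
  art$manifest <- manifest_csv

  # --- split (derived when needed) -------------------------------------
  get_split <- function() {
    slabs <- read_study_labels(file.path(data_dir, "study_labels.csv"))
    if (!file.exists(split_csv)) {
      grp <- split_studies(slabs, config$split_fractions, config$seed)
      readr::write_csv(tibble(study_id = names(grp), split = grp), split_csv)
    }
    readr::read_csv(split_csv, col_types = "cc")
  }

  # --- train-phase1 -----------------------------------------------------
  p1_fp <- fp_of("train-phase1", read_fp("preprocess"),
                 unclass_deep(config$phase1), config$split_fractions)
  run_stage("train-phase1", p1_fp, function() {
    require_artifact(tensors_rds, "preprocess", "train-phase1")
    tensors <- readRDS(tensors_rds)
    split <- get_split()
    sid <- purrr::map_chr(tensors, ~ attr(.x, "study_id"))
    grp <- setNames(split$split, split$study_id)[sid]
    ckpt <- train_phase1(tensors[grp == "train"], tensors[grp == "val"],
                         config$phase1, verbose = verbose)
    saveRDS(ckpt, ckpt1_rds)
  })
  art$phase1_checkpoint <- ckpt1_rds

  # --- extract-features -------------------------------------------------
  feat_fp <- fp_of("extract-features", read_fp("train-phase1"))
  run_stage("extract-features", feat_fp, function() {
    require_artifact(ckpt1_rds, "train-phase1", "extract-features")
    tensors <- readRDS(tensors_rds)
    ckpt <- readRDS(ckpt1_rds)
    write_feature_table(extract_feature_table(tensors, ckpt), features_csv)
  })
  art$features <- features_csv

  # --- train-phase2 -----------------------------------------------------
  p2_fp <- fp_of("train-phase2", read_fp("extract-features"),
                 unclass_deep(config$phase2))
  run_stage("train-phase2", p2_fp, function() {
    require_artifact(features_csv, "extract-features", "train-phase2")
    fdata <- pipeline_feature_data(out, data_dir)
    split <- get_split()
    grp <- setNames(split$split, split$study_id)
    train <- subset_feature_data(fdata, names(grp)[grp == "train"])
    val <- subset_feature_data(fdata, names(grp)[grp == "val"])
    ckpt <- train_phase2(train, val, config$phase2, verbose = verbose)
    saveRDS(ckpt, ckpt2_rds)
  })
  art$phase2_checkpoint <- ckpt2_rds

  # --- predict ----------------------------------------------------------
  pred_fp <- fp_of("predict", read_fp("train-phase2"))
  run_stage("predict", pred_fp, function() {
    require_artifact(ckpt2_rds, "train-phase2", "predict")
    fdata <- pipeline_feature_data(out, data_dir)
    split <- get_split()
    grp <- setNames(split$split, split$study_id)
    ckpt <- readRDS(ckpt2_rds)
    for (part in c("val", "test")) {
      sub <- subset_feature_data(fdata, names(grp)[grp == part])
      pred <- predict_studies(ckpt, sub)
      readr::write_csv(pred$study_probs,
                       file.path(out, sprintf("study_probs_%s.csv", part)))
      readr::write_csv(pred$window_probs,
                       file.path(out, sprintf("window_probs_%s.csv", part)))
      saveRDS(pred, file.path(out, sprintf("predictions_%s.rds", part)))
    }
  })
  art$predictions <- file.path(out, "predictions_test.rds")

  # --- evaluate ---------------------------------------------------------
  eval_fp <- fp_of("evaluate", read_fp("predict"))
  run_stage("evaluate", eval_fp, function() {
    require_artifact(file.path(out, "predictions_test.rds"), "predict",
                     "evaluate")
    fdata <- pipeline_feature_data(out, data_dir)
    split <- get_split()
    grp <- setNames(split$split, split$study_id)
    pred_val <- readRDS(file.path(out, "predictions_val.rds"))
    val_data <- subset_feature_data(fdata, names(grp)[grp == "val"])
    val_report <- evaluate_predictions(pred_val, val_data)
    thresholds <- setNames(val_report$metrics$threshold,
                           val_report$metrics$label)
    thresholds <- thresholds[!is.na(thresholds)]
    pred_test <- readRDS(file.path(out, "predictions_test.rds"))
    test_data <- subset_feature_data(fdata, names(grp)[grp == "test"])
    rep <- evaluate_predictions(pred_test, test_data,
                                thresholds = thresholds)
    readr::write_csv(rep$metrics, file.path(out, "eval_metrics.csv"))
    jsonlite::write_json(rep$metrics, file.path(out, "eval_report.json"),
                         dataframe = "rows", na = "null")
    tryCatch({
      p <- autoplot(rep)
      ggplot2::ggsave(file.path(out, "roc_curves.png"), p,
                      width = 8, height = 6, dpi = 96)
    }, error = function(e) warn(sprintf("ROC plot not written: %s",
                                        conditionMessage(e))))
  })
  art$eval_metrics <- file.path(out, "eval_metrics.csv")
  if (file.exists(file.path(out, "eval_metrics.csv")) &&
      "evaluate" %in% stages) {
    report <- readr::read_csv(file.path(out, "eval_metrics.csv"),
                              show_col_types = FALSE)
  }

  # --- interpret --------------------------------------------------------
  int_fp <- fp_of("interpret", read_fp("predict"), read_fp("train-phase1"))
  run_stage("interpret", int_fp, function() {
    require_artifact(file.path(out, "predictions_test.rds"), "predict",
                     "interpret")
    pred <- readRDS(file.path(out, "predictions_test.rds"))
    fdata <- pipeline_feature_data(out, data_dir)
    # pick the test study with the most positive windows; fall back to any
    wl <- pred$window_probs
    pos_count <- tapply(wl$pe_present, wl$study_id, sum)
    sid <- names(sort(pos_count, decreasing = TRUE))[1]
    sp <- pred$predictions[[sid]]
    sal_rows <- purrr::map_dfr(study_label_names(), function(lab) {
      sal <- attention_heatmap(sp, lab)
      tibble(study_id = sid, label = lab,
             window = seq_along(sal$weights) - 1L, weight = sal$weights)
    })
    readr::write_csv(sal_rows, file.path(out, "attention_saliency.csv"))
    # Grad-CAM on the highlighted window of the PE-most-relevant label
    ckpt1 <- readRDS(ckpt1_rds)
    tensors <- readRDS(tensors_rds)
    keys <- purrr::map_chr(tensors, ~ paste(attr(.x, "study_id"),
                                            attr(.x, "window_index")))
    widx <- which.max(wl$prob[wl$study_id == sid]) - 1L
    t_sel <- tensors[[match(paste(sid, widx), keys)]]
    t_eval <- augment_window(t_sel, ckpt1$config, train = FALSE)
    cam <- grad_cam_3d(t_eval, ckpt1)
    write_cam_overlay(cam, t_eval,
                      file.path(out, sprintf("gradcam_%s_w%02d", sid, widx)))
  })
  art$saliency <- file.path(out, "attention_saliency.csv")

  invisible(c(art, list(report = report)))
}

# Assemble the feature dataset consumed by phase 2 from pipeline artifacts.
pipeline_feature_data <- function(out, data_dir) {
  features <- read_feature_table(file.path(out, "features.csv"))
  manifest <- readr::read_csv(file.path(out, "window_manifest.csv"),
                              show_col_types = FALSE)
  list(features = features,
       window_labels = tibble(study_id = manifest$study_id,
                              window_index = manifest$window_index,
                              pe_present = manifest$label),
       study_labels = read_study_labels(file.path(data_dir,
                                                  "study_labels.csv")))
}
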