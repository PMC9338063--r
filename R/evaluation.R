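# ROC/AUROC with DeLong confidence intervals, sensitivity/specificity
# threshold selection, and feature-space separation statistics.

#' ROC curve and AUROC
#'
#' AUROC equals the Mann-Whitney statistic (ties counted 1/2), computed
#' from midranks in O(n log n). The ROC table reports sensitivity
#' (TP / (TP + FN)) and specificity (TN / (TN + FP)) at every distinct
#' score threshold, predicting positive when `score >= threshold`.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 truth vector.
#' @return List with `auroc` and `roc` (tibble: threshold, sensitivity,
#'   specificity, fpr).
#' @export
roc_curve_auc <- function(scores, labels) {
  labels <- check_binary(labels)
  if (length(scores) != length(labels)) abort("scores/labels length mismatch")
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) abort("both classes must be present")
  r <- rank(scores)                           # midranks
  auroc <- (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- purrr::map_dbl(thr, ~ mean(scores[labels == 1] >= .x))
  spec <- purrr::map_dbl(thr, ~ mean(scores[labels == 0] < .x))
  roc <- tibble(threshold = thr, sensitivity = sens, specificity = spec,
                fpr = 1 - spec)
  list(auroc = auroc, roc = roc)
}

# DeLong placement values via midranks (Sun & Xu fast formulation)
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos); r_neg <- rank(neg)
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auroc = mean(v10))
}

#' DeLong confidence interval for an AUROC
#'
#' Normal-approximation interval from the DeLong variance of placement
#' values, truncated to `[0, 1]`.
#'
#' @param scores,labels As in [roc_curve_auc()]; both classes need at least
#'   two members.
#' @param level Confidence level (default 0.95).
#' @return Named numeric: `auroc`, `lo`, `hi`, `se`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- check_binary(labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m < 2 || n < 2) abort("both classes need at least two members")
  pl <- delong_placements(scores, labels)
  v <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(v)
  c(auroc = pl$auroc, lo = max(0, pl$auroc - half),
    hi = min(1, pl$auroc + half), se = sqrt(v))
}

#' Select a probability threshold on validation data
#'
#' Operationalizes "maximize both sensitivity and specificity" as Youden's
#' J = sensitivity + specificity - 1 over a 0.05-granularity probability
#' grid. Ties prefer the higher sensitivity, then the lower threshold.
#'
#' @param scores,labels Validation scores and 0/1 truth.
#' @param grid Candidate thresholds (default `seq(0, 1, by = 0.05)`).
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden_j`
#'   and `table` (per-grid-point tibble).
#' @export
threshold_select <- function(scores, labels, grid = seq(0, 1, by = 0.05)) {
  labels <- check_binary(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  tab <- purrr::map_dfr(grid, function(t) {
    pred <- as.integer(scores >= t)
    tibble(threshold = t,
           sensitivity = sum(pred == 1 & labels == 1) / sum(labels == 1),
           specificity = sum(pred == 0 & labels == 0) / sum(labels == 0))
  })
  tab$youden_j <- tab$sensitivity + tab$specificity - 1
  # round before ordering so float noise cannot break the documented ties
  ord <- order(-round(tab$youden_j, 10), -round(tab$sensitivity, 10),
               tab$threshold)
  sel <- tab[ord[1], ]
  list(threshold = sel$threshold, sensitivity = sel$sensitivity,
       specificity = sel$specificity, youden_j = sel$youden_j, table = tab)
}

#' Feature-space class separation
#'
#' Class centroids CP (positive) and CN (negative) in the 512-d feature
#' space, mean Manhattan (L1) distance of each class to its centroid, and
#' the Manhattan distance between centroids. For plotting, a 2-D embedding
#' of a subsample is computed by classical multidimensional scaling of the
#' Manhattan distance matrix.
#'
#' @param features Numeric matrix (rows = windows) or a feature tibble with
#'   `f...` columns.
#' @param labels 0/1 vector per row.
#' @param embed_max Max points used for the 2-D embedding.
#' @return A `pe_separation_stats`: `centroid_pos`, `centroid_neg`,
#'   `mean_dist_pos`, `mean_dist_neg`, `centroid_dist`, `embedding`
#'   (tibble: dim1, dim2, label).
#' @export
cluster_separation <- function(features, labels, embed_max = 300L) {
  if (is.data.frame(features)) {
    fcols <- grep("^f[0-9]+$", names(features), value = TRUE)
    features <- as.matrix(features[, fcols])
  }
  labels <- check_binary(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  cp <- colMeans(features[labels == 1, , drop = FALSE])
  cn <- colMeans(features[labels == 0, , drop = FALSE])
  l1_to <- function(x, c_) rowSums(abs(sweep(x, 2, c_)))
  mp <- mean(l1_to(features[labels == 1, , drop = FALSE], cp))
  mn <- mean(l1_to(features[labels == 0, , drop = FALSE], cn))
  cd <- sum(abs(cp - cn))

  idx <- seq_len(nrow(features))
  if (length(idx) > embed_max) {
    set.seed(0L)
    idx <- sort(sample(idx, embed_max))
  }
  d <- stats::dist(features[idx, , drop = FALSE], method = "manhattan")
  emb <- stats::cmdscale(d, k = 2)
  structure(list(centroid_pos = cp, centroid_neg = cn,
                 mean_dist_pos = mp, mean_dist_neg = mn, centroid_dist = cd,
                 embedding = tibble(dim1 = emb[, 1], dim2 = emb[, 2],
                                    label = factor(labels[idx]))),
            class = "pe_separation_stats")
}

#' @export
print.pe_separation_stats <- function(x, ...) {
  cat(sprintf(paste0("<pe_separation_stats>\n",
                     "  mean L1 distance to centroid: pos %.2f, neg %.2f\n",
                     "  L1 distance between centroids: %.2f\n"),
              x$mean_dist_pos, x$mean_dist_neg, x$centroid_dist))
  invisible(x)
}

#' Evaluate study- and window-level predictions
#'
#' Per-label ROC/AUROC with 95% DeLong confidence intervals and a selected
#' probability threshold with its sensitivity/specificity. Thresholds come
#' from `thresholds` when supplied (e.g. selected on a validation set) and
#' are otherwise selected on the evaluated data itself. Labels with a
#' single observed class are reported with `NA` metrics.
#'
#' @param pred A prediction list from [predict_studies()].
#' @param data The matching feature/label dataset (for ground truth).
#' @param thresholds Optional named numeric vector of per-label thresholds.
#' @param level CI level.
#' @return A `pe_eval_report` with per-label metrics (including the
#'   window-level row `pe_present_window`) and ROC tables.
#' @export
evaluate_predictions <- function(pred, data, thresholds = NULL,
                                 level = 0.95) {
  truth <- data$study_labels
  sp <- dplyr::inner_join(pred$study_probs, truth, by = "study_id",
                          suffix = c("_prob", "_true"))
  rocs <- list()
  rows <- list()
  eval_one <- function(label, scores, y) {
    if (length(unique(y)) < 2) {
      return(tibble(label = label, auroc = NA_real_, ci_lo = NA_real_,
                    ci_hi = NA_real_, threshold = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    n_pos = sum(y == 1), n_neg = sum(y == 0)))
    }
    rc <- roc_curve_auc(scores, y)
    ci <- if (sum(y == 1) >= 2 && sum(y == 0) >= 2) {
      delong_ci(scores, y, level)
    } else {
      c(lo = NA_real_, hi = NA_real_)
    }
    thr <- if (!is.null(thresholds) && label %in% names(thresholds)) {
      t0 <- thresholds[[label]]
      tibble(threshold = t0,
             sensitivity = mean(scores[y == 1] >= t0),
             specificity = mean(scores[y == 0] < t0))
    } else {
      ts <- threshold_select(scores, y)
      tibble(threshold = ts$threshold, sensitivity = ts$sensitivity,
             specificity = ts$specificity)
    }
    rocs[[label]] <<- rc$roc
    tibble(label = label, auroc = rc$auroc, ci_lo = ci[["lo"]],
           ci_hi = ci[["hi"]], threshold = thr$threshold,
           sensitivity = thr$sensitivity, specificity = thr$specificity,
           n_pos = sum(y == 1), n_neg = sum(y == 0))
  }
  if (!is.null(pred$window_probs)) {
    rows[["pe_present_window"]] <- eval_one(
      "pe_present_window", pred$window_probs$prob,
      pred$window_probs$pe_present)
  }
  for (lab in study_label_names()) {
    rows[[lab]] <- eval_one(lab, sp[[paste0(lab, "_prob")]],
                            sp[[paste0(lab, "_true")]])
  }
  structure(list(metrics = dplyr::bind_rows(rows), roc = rocs,
                 level = level),
            class = "pe_eval_report")
}

#' @export
print.pe_eval_report <- function(x, ...) {
  cat("<pe_eval_report>\n")
  print(x$metrics, n = nrow(x$metrics))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `pe_eval_report`.
#' @param ... Unused.
#' @return Per-label tibble of AUROC, DeLong CI, threshold, sensitivity and
#'   specificity.
#' @importFrom generics tidy
#' @export
tidy.pe_eval_report <- function(x, ...) x$metrics

#' Summarize an evaluation report
#'
#' @param x A `pe_eval_report`.
#' @param ... Unused.
#' @return One-row tibble: number of evaluable labels, mean/min/max AUROC.
#' @importFrom generics glance
#' @export
glance.pe_eval_report <- function(x, ...) {
  m <- x$metrics[!is.na(x$metrics$auroc), ]
  tibble(n_labels = nrow(m), mean_auroc = mean(m$auroc),
         min_auroc = min(m$auroc), max_auroc = max(m$auroc))
}

#' Plot ROC curves of an evaluation report
#'
#' @param object A `pe_eval_report`.
#' @param ... Unused.
#' @return A ggplot with one ROC panel per evaluable label.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pe_eval_report <- function(object, ...) {
  df <- purrr::imap_dfr(object$roc, ~ dplyr::mutate(.x, label = .y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = "ROC curves") +
    ggplot2::theme_minimal()
}

#' Plot the 2-D embedding of separation statistics
#'
#' @param object A `pe_separation_stats`.
#' @param ... Unused.
#' @return A ggplot scatter of the MDS embedding colored by class.
#' @export
autoplot.pe_separation_stats <- function(object, ...) {
  ggplot2::ggplot(object$embedding,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               color = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = "Feature-space separation (MDS of L1 distances)",
                  color = "PE window") +
    ggplot2::theme_minimal()
}
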