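test_that("AUROC equals all-pairs enumeration including ties", {
  # perfectly separated
  expect_equal(roc_curve_auc(c(0.9, 0.8, 0.2, 0.1),
                             c(1, 1, 0, 0))$auroc, 1)
  # reversed scores map AUROC -> 1 - AUROC
  s <- c(0.9, 0.8, 0.2, 0.4); y <- c(1, 0, 0, 1)
  expect_equal(roc_curve_auc(-s, y)$auroc,
               1 - roc_curve_auc(s, y)$auroc)
  # 20-point toy set with ties: exact agreement with pair counting
  withr::with_seed(19, {
    for (rep in 1:10) {
      n <- sample(c(20, 51, 200), 1)
      scores <- round(runif(n), 2)        # force ties
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      expect_equal(roc_curve_auc(scores, labels)$auroc,
                   oracle_auroc_pairs(scores, labels), tolerance = 1e-12)
    }
  })
  # null: labels independent of scores
  withr::with_seed(20, {
    scores <- runif(4000); labels <- rbinom(4000, 1, 0.5)
    expect_lt(abs(roc_curve_auc(scores, labels)$auroc - 0.5), 0.05)
  })
  expect_error(roc_curve_auc(1:4, c(1, 1, 1, 1)), "both classes")

  # ROC table is internally consistent at every threshold
  rc <- roc_curve_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_true(all(rc$roc$sensitivity >= 0 & rc$roc$sensitivity <= 1))
  expect_equal(rc$roc$fpr, 1 - rc$roc$specificity)
})

test_that("fast DeLong equals the naive structural-components computation", {
  withr::with_seed(23, {
    for (rep in 1:8) {
      n <- sample(20:120, 1)
      y <- c(rep(1, ceiling(n / 3)), rep(0, n - ceiling(n / 3)))
      s <- rnorm(n, mean = y)
      s[sample(n, 5)] <- round(s[sample(n, 5)], 1)   # some ties
      ci <- delong_ci(s, y)
      want <- oracle_delong_var(s, y)
      expect_equal(unname(ci["auroc"]), want$auroc, tolerance = 1e-12)
      expect_equal(unname(ci["se"]), sqrt(want$var), tolerance = 1e-10)
    }
  })
})

test_that("AUROC and DeLong interval agree with the pROC reference", {
  withr::with_seed(27, {
    y <- rbinom(150, 1, 0.45)
    s <- rnorm(150, mean = 1.2 * y)
    ci <- delong_ci(s, y)
    ref <- pROC::ci.auc(pROC::roc(y, s, direction = "<",
                                  levels = c(0, 1), quiet = TRUE),
                        method = "delong")
    expect_equal(unname(ci["auroc"]), as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(unname(ci["lo"]), as.numeric(ref[1]), tolerance = 1e-8)
    expect_equal(unname(ci["hi"]), as.numeric(ref[3]), tolerance = 1e-8)
    expect_equal(roc_curve_auc(s, y)$auroc, as.numeric(ref[2]),
                 tolerance = 1e-10)
  })
})

test_that("DeLong interval behaves at the boundaries and under duplication", {
  y <- c(rep(1, 10), rep(0, 10))
  s <- c(rnorm(10, 5), rnorm(10, -5))
  ci <- delong_ci(s, y)
  expect_equal(unname(ci["hi"]), 1)         # truncated at 1
  expect_true(ci["lo"] >= 0 && ci["lo"] <= ci["auroc"])

  withr::with_seed(29, {
    y2 <- rbinom(60, 1, 0.5); s2 <- rnorm(60, mean = 0.8 * y2)
    ci_once <- delong_ci(s2, y2)
    ci_twice <- delong_ci(c(s2, s2), c(y2, y2))
    expect_equal(unname(ci_twice["auroc"]), unname(ci_once["auroc"]),
                 tolerance = 1e-12)
    expect_lt(ci_twice["hi"] - ci_twice["lo"],
              ci_once["hi"] - ci_once["lo"])
  })
  expect_error(delong_ci(c(1, 2, 3), c(1, 0, 0)), "two members")
})

test_that("threshold selection maximizes Youden's J on the 0.05 grid", {
  # scores equal to labels: every interior threshold reaches J = 1; the tie
  # rule returns the lowest qualifying grid point
  y <- c(1, 1, 0, 0, 1, 0)
  ts <- threshold_select(as.numeric(y), y)
  expect_equal(ts$threshold, 0.05)
  expect_equal(ts$sensitivity, 1)
  expect_equal(ts$specificity, 1)

  # toy set vs exhaustive grid-search oracle
  withr::with_seed(31, {
    for (rep in 1:6) {
      s <- runif(10); y <- rbinom(10, 1, 0.5)
      if (length(unique(y)) < 2) next
      ts <- threshold_select(s, y)
      grid <- seq(0, 1, by = 0.05)
      best <- -Inf; best_sens <- -Inf; best_t <- NA
      for (t in grid) {
        sens <- mean(s[y == 1] >= t); spec <- mean(s[y == 0] < t)
        j <- sens + spec - 1
        if (j > best + 1e-12 ||
            (abs(j - best) < 1e-12 && sens > best_sens + 1e-12)) {
          best <- j; best_sens <- sens; best_t <- t
        }
      }
      expect_equal(ts$threshold, best_t)
      expect_equal(ts$youden_j, best, tolerance = 1e-12)
      # reported pair recomputes exactly from the confusion matrix
      expect_equal(ts$sensitivity, mean(s[y == 1] >= ts$threshold))
      expect_equal(ts$specificity, mean(s[y == 0] < ts$threshold))
    }
  })
  expect_error(threshold_select(runif(5), rep(1, 5)), "both classes")
})

test_that("separation statistics: point masses, symmetry, planted signal", {
  # two point masses: zero within-class spread, L1 centroid distance
  u <- c(1, 2, 3); v <- c(4, 0, 3)
  x <- rbind(u, u, v, v, v)
  y <- c(1, 1, 0, 0, 0)
  st <- cluster_separation(x, y)
  expect_equal(st$mean_dist_pos, 0)
  expect_equal(st$mean_dist_neg, 0)
  expect_equal(st$centroid_dist, sum(abs(u - v)))

  # label flip swaps the class fields exactly
  withr::with_seed(37, {
    x2 <- matrix(rnorm(60 * 8), 60, 8); y2 <- rbinom(60, 1, 0.5)
    a <- cluster_separation(x2, y2)
    b <- cluster_separation(x2, 1 - y2)
    expect_equal(a$mean_dist_pos, b$mean_dist_neg)
    expect_equal(a$centroid_pos, b$centroid_neg)
    expect_equal(a$centroid_dist, b$centroid_dist)
  })

  # strong planted signal: centroids separate beyond within-class spread
  fd <- make_feature_dataset(synthetic_feature_spec(
    40, positive_shift = 40, positive_fraction = 0.5, seed = 41))
  ss <- cluster_separation(fd$features, fd$window_labels$pe_present)
  expect_gt(ss$centroid_dist, max(ss$mean_dist_pos, ss$mean_dist_neg))
  expect_lte(nrow(ss$embedding), 300)
  expect_error(cluster_separation(x, rep(1, 5)), "both classes")
})

test_that("evaluation reports are well-formed with broom-style accessors", {
  withr::with_seed(43, {
    n <- 40
    probs <- matrix(runif(n * 9), n, 9,
                    dimnames = list(NULL, study_label_names()))
    truth <- tibble::tibble(study_id = sprintf("s%02d", 1:n))
    for (nm in study_label_names()) {
      truth[[nm]] <- rbinom(n, 1, 0.4)
    }
    truth$indeterminate <- 0L                 # a single-class label
    pred <- list(
      study_probs = dplyr::bind_cols(tibble::tibble(study_id = truth$study_id),
                                     tibble::as_tibble(probs)),
      window_probs = tibble::tibble(study_id = "s01",
                                    window_index = 0:19,
                                    prob = runif(20),
                                    pe_present = rbinom(20, 1, 0.5)))
    rep <- evaluate_predictions(pred, list(study_labels = truth))
    td <- tidy(rep)
    expect_equal(nrow(td), 10)                # window row + nine labels
    expect_true(all(td$auroc >= 0 & td$auroc <= 1, na.rm = TRUE))
    expect_true(all(td$ci_lo <= td$auroc & td$auroc <= td$ci_hi,
                    na.rm = TRUE))
    expect_true(is.na(td$auroc[td$label == "indeterminate"]))
    g <- glance(rep)
    expect_equal(g$n_labels, sum(!is.na(td$auroc)))
    p <- ggplot2::autoplot(rep)
    expect_s3_class(p, "ggplot")

    # supplied thresholds are honored instead of re-selected
    thr <- c(left_pe = 0.5)
    rep2 <- evaluate_predictions(pred, list(study_labels = truth),
                                 thresholds = thr)
    expect_equal(tidy(rep2)$threshold[tidy(rep2)$label == "left_pe"], 0.5)
  })
})
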