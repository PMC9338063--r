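pe <- asNamespace("peflow")

test_that("augmentation produces the configured shapes and is reproducible", {
  t0 <- structure(array(runif(48 * 48 * 10 * 3), dim = c(48, 48, 10, 3)),
                  class = "pe_window_tensor", label = 1L, study_id = "s",
                  window_index = 0L)
  cfg_paper <- phase1_config("paper")
  # training: 224 resize then random 3D crop + rotation down to 192
  a_train <- augment_window(t0, cfg_paper, train = TRUE, seed = 5)
  expect_equal(dim(a_train), c(192, 192, 10, 3))
  expect_true(all(a_train >= 0 & a_train <= 1))
  # eval: deterministic direct resize, no crop/rotation
  a_eval <- augment_window(t0, cfg_paper, train = FALSE)
  expect_equal(dim(a_eval), c(192, 192, 10, 3))
  expect_identical(a_eval, augment_window(t0, cfg_paper, train = FALSE))
  # fixed seed -> identical augmented output twice
  expect_identical(augment_window(t0, cfg_paper, train = TRUE, seed = 9),
                   augment_window(t0, cfg_paper, train = TRUE, seed = 9))
  # label and provenance attributes survive
  expect_equal(attr(a_train, "label"), 1L)

  # zero rotation with resize == crop: training transform reduces to the
  # deterministic resize
  cfg_id <- phase1_config("test", resize_px = 32, crop_px = 32,
                          rotation_deg = 0)
  expect_equal(as.vector(augment_window(t0, cfg_id, train = TRUE, seed = 1)),
               as.vector(augment_window(t0, cfg_id, train = FALSE)),
               tolerance = 1e-12)
})

test_that("phase-1 loss equals the analytic BCE oracle", {
  expect_equal(phase1_batch_loss(c(0, 0), c(1, 0)), log(2))
  # saturated correct prediction drives the loss to zero
  expect_lt(phase1_batch_loss(30, 1), 1e-10)
  expect_gt(phase1_batch_loss(-30, 1), 20)
  withr::with_seed(11, {
    for (rep in 1:5) {
      z <- rnorm(16, sd = 3)
      y <- rbinom(16, 1, 0.5)
      expect_equal(phase1_batch_loss(z, y), mean(oracle_bce(z, y)),
                   tolerance = 1e-6)
      expect_gte(phase1_batch_loss(z, y), 0)
    }
  })
  expect_error(phase1_batch_loss(numeric(0), numeric(0)), "empty")
  expect_error(phase1_batch_loss(c(0, 1), c(1)), "mismatch")
})

test_that("forward_features honors the 512-d contract deterministically", {
  m <- backbone_init(backbone_config(channels = c(4L, 6L),
                                     blocks = c(1L, 1L)), seed = 2)
  x <- array(runif(16 * 16 * 10 * 3), dim = c(16, 16, 10, 3))
  f1 <- forward_features(m, x)
  f2 <- forward_features(m, x)
  expect_length(f1$feature, 512)
  expect_true(all(is.finite(f1$feature)))
  expect_length(f1$logit, 1)
  expect_identical(f1$logit, f2$logit)
  expect_identical(f1$feature, f2$feature)
  expect_error(forward_features(m, array(0, c(8, 8, 10))), "array")
})

test_that("training selects the best-validation epoch reproducibly and the
          feature table is ordered and lossless", {
  tensors <- tiny_window_set(n_studies = 4, n_positive = 2, seed = 6)
  labs <- vapply(tensors, function(t) attr(t, "label"), 0L)
  sids <- vapply(tensors, function(t) attr(t, "study_id"), "")
  # split by study: first two studies train, last two validation
  tr <- tensors[sids %in% c("study_001", "study_003")]
  va <- tensors[sids %in% c("study_002", "study_004")]
  cfg <- phase1_config("test", epochs = 2, batch_size = 8, seed = 3,
                       backbone = backbone_config(channels = c(4L, 6L),
                                                  blocks = c(1L, 1L)))
  ck1 <- train_phase1(tr, va, cfg)
  ck2 <- train_phase1(tr, va, cfg)
  expect_identical(ck1$selected_epoch, ck2$selected_epoch)
  expect_identical(ck1$model$stem$W, ck2$model$stem$W)
  expect_equal(nrow(ck1$trace), 2)

  ft <- extract_feature_table(tensors, ck1)
  expect_equal(nrow(ft), length(tensors))
  expect_equal(ncol(ft), 514)
  expect_false(is.unsorted(ft$study_id))
  # round-trips through the feature reader losslessly
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12)

  expect_error(train_phase1(list(), va, cfg), "nonempty")
})
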