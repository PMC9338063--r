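make_series <- function(raw_list, slope = 1, intercept = -1024,
                        z = NULL, labels = NULL) {
  raw_series(raw_list, slope, intercept,
             z_positions = z %||% seq_along(raw_list) * 2.5,
             pixel_spacing = c(1, 1), slice_labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Hounsfield conversion applies the affine rescale and z ordering", {
  px <- list(matrix(0L, 4, 4), matrix(1424L, 4, 4), matrix(100L, 4, 4))
  st <- to_hounsfield(make_series(px))
  expect_equal(unique(as.vector(st$volume[, , 1])), -1024)
  expect_equal(unique(as.vector(st$volume[, , 2])), 400)

  st2 <- to_hounsfield(make_series(list(matrix(100L, 2, 2)), slope = 2,
                                   intercept = 0, z = 0))
  expect_equal(unique(as.vector(st2$volume)), 200)

  # slices arrive out of order; sorted bottom-to-top by z
  sr <- raw_series(list(matrix(2L, 2, 2), matrix(1L, 2, 2)),
                   slope = 1, intercept = 0, z_positions = c(10, 5),
                   pixel_spacing = c(1, 1), slice_labels = c(1L, 0L))
  st3 <- to_hounsfield(sr)
  expect_equal(as.vector(st3$volume[1, 1, ]), c(1, 2))
  expect_equal(st3$slice_labels, c(0L, 1L))

  # conversion is affine and invertible: recover raw from HU
  expect_equal((st2$volume * 1 - 0) / 2,
               array(100, dim = dim(st2$volume)))

  bad <- make_series(px)
  bad$slope <- 0
  expect_error(to_hounsfield(bad), "slope")
  dup <- raw_series(px, 1, 0, z_positions = c(1, 1, 2),
                    pixel_spacing = c(1, 1))
  expect_error(to_hounsfield(dup), "duplicate z")
})

test_that("isotropic resampling matches the physical extent", {
  vol <- array(rnorm(8 * 8 * 100), dim = c(8, 8, 100))
  st <- ct_study("s", vol, c(2.5, 1, 1), slice_labels = integer(100))
  out <- resample_isotropic(st)
  expect_equal(dim(out$volume), c(8, 8, 250))
  expect_equal(out$spacing_mm, c(1, 1, 1))
  expect_length(out$slice_labels, 250)

  # already-isotropic input is returned voxel-identical
  iso <- ct_study("s", vol, c(1, 1, 1))
  expect_identical(resample_isotropic(iso)$volume, vol)

  expect_error(resample_isotropic(ct_study("s", vol, c(0, 1, 1))),
               "positive")
})

test_that("label resampling follows the interval-overlap rule", {
  # brute-force oracle: output slice i covers [i*s, (i+1)*s) in source index
  # units; positive iff it overlaps any positive source slice [j, j+1)
  oracle <- function(labels, n_out) {
    n_in <- length(labels)
    s <- n_in / n_out
    vapply(seq_len(n_out) - 1, function(i) {
      hits <- vapply(which(labels == 1) - 1, function(j) {
        (j + 1) > i * s && j < (i + 1) * s
      }, logical(1))
      as.integer(any(hits))
    }, integer(1))
  }
  withr::with_seed(4, {
    for (rep in 1:20) {
      n_in <- sample(5:60, 1)
      spacing <- sample(c(0.5, 1.5, 2, 2.5, 3), 1)
      labels <- rbinom(n_in, 1, 0.2)
      vol <- array(0, dim = c(4, 4, n_in))
      st <- ct_study("s", vol, c(spacing, 1, 1), slice_labels = labels)
      out <- resample_isotropic(st)
      expect_equal(out$slice_labels, oracle(labels, dim(out$volume)[3]))
      # conservative: positives never destroyed
      if (any(labels == 1)) expect_true(any(out$slice_labels == 1))
    }
  })

  # a positive at input index 10 under 2.5 mm spacing maps to the output
  # slices whose source interval overlaps slice 10
  labels <- integer(20); labels[11] <- 1L
  st <- ct_study("s", array(0, c(4, 4, 20)), c(2.5, 1, 1),
                 slice_labels = labels)
  out <- resample_isotropic(st)
  expect_equal(which(out$slice_labels == 1) - 1L,
               which(oracle(labels, 50) == 1) - 1L)
})

test_that("lung bounding box is recovered from phantom geometry", {
  sp <- tiny_phantom_spec(noise_sd = 0, spacing_mm = c(1, 1, 1))
  st <- make_phantom_study(sp)
  box <- compute_lung_bbox(st)
  # phantom lung extent is z [5, 32), y [7, 41), x [5, 43)
  expect_lte(abs(box[["z0"]] - 5), 2)
  expect_lte(abs(box[["z1"]] - 32), 2)
  expect_lte(abs(box[["y0"]] - 7), 2)
  expect_lte(abs(box[["x1"]] - 43), 2)
  d <- dim(st$volume)
  expect_true(box[["z1"]] <= d[3] && box[["y1"]] <= d[1] &&
                box[["x1"]] <= d[2])
  expect_true(all(box[c("z1", "y1", "x1")] > box[c("z0", "y0", "x0")]))

  uniform <- ct_study("u", array(40, dim = c(16, 16, 8)), c(1, 1, 1))
  expect_error(compute_lung_bbox(uniform), "full-volume")
})

test_that("window splitting partitions the cropped extent with OR labels", {
  labels <- integer(25); labels[13] <- 1L       # slice z = 12, 0-based
  st <- ct_study("s", array(rnorm(4 * 4 * 25), c(4, 4, 25)), c(1, 1, 1),
                 slice_labels = labels)
  wins <- split_into_windows(st)
  expect_length(wins, 3)
  expect_true(all(vapply(wins, function(w) dim(w$hu)[3], 0) == 10))
  expect_equal(vapply(wins, function(w) w$label, 0L), c(0L, 1L, 0L))
  expect_equal(wins[[3]]$n_real, 5)
  # terminal padding replicates the last real slice
  expect_equal(wins[[3]]$hu[, , 6], wins[[3]]$hu[, , 5])
  expect_equal(wins[[3]]$hu[, , 10], wins[[3]]$hu[, , 5])
  # spans partition the cropped z extent
  spans <- purrr::map(wins, "span")
  expect_equal(unlist(spans), c(0, 10, 10, 20, 20, 25))

  all_zero <- split_into_windows(ct_study("s", st$volume, c(1, 1, 1),
                                          slice_labels = integer(25)))
  expect_true(all(vapply(all_zero, function(w) w$label, 0L) == 0))
})

test_that("derive_window_labels equals brute-force OR reduction", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- sample(10:50, 1)
      labels <- rbinom(n, 1, 0.3)
      cuts <- seq(0, n, by = 10)
      if (cuts[length(cuts)] < n) cuts <- c(cuts, n)
      spans <- purrr::map(seq_len(length(cuts) - 1),
                          ~ c(cuts[.x], cuts[.x + 1]))
      got <- derive_window_labels(labels, spans)
      want <- vapply(spans, function(sp) {
        any_pos <- FALSE
        for (j in (sp[1] + 1):sp[2]) any_pos <- any_pos || labels[j] == 1
        as.integer(any_pos)
      }, integer(1))
      expect_identical(got, want)
    }
  })
  expect_true(all(derive_window_labels(rep(1L, 20),
                                       list(c(0, 10), c(10, 20))) == 1))
})

test_that("display-window clip bounds match the standard L +/- W/2 tuples", {
  dw <- default_display_windows()
  expect_equal(unname(window_clip_bounds(dw$lung)), c(-1350, 150))
  expect_equal(unname(window_clip_bounds(dw$pe)), c(-250, 450))
  expect_equal(unname(window_clip_bounds(dw$mediastinal)), c(-160, 240))
  expect_error(display_window(0, -5), "positive")
})

test_that("channel rendering is a monotone [0,1] map saturating at bounds", {
  hu <- array(c(-2000, -1350, -600, 100, 150, 450, 1000),
              dim = c(7, 1, 1))
  t3 <- render_channels(hu)
  expect_true(all(t3 >= 0 & t3 <= 1))
  # lung channel: -1350 -> 0, 150 -> 1
  expect_equal(t3[2, 1, 1, 1], 0)
  expect_equal(t3[5, 1, 1, 1], 1)
  # PE channel: level 100 maps to the midpoint 0.5
  expect_equal(t3[4, 1, 1, 2], 0.5)
  # saturation below/above the printed bounds
  expect_equal(t3[1, 1, 1, 1], 0)
  expect_equal(t3[7, 1, 1, 1], 1)
  # monotone nondecreasing in HU per channel
  grid <- array(seq(-1500, 600, length.out = 64), dim = c(64, 1, 1))
  tg <- render_channels(grid)
  for (ch in 1:3) expect_true(all(diff(tg[, 1, 1, ch]) >= 0))
})

test_that("full preprocessing is deterministic and window labels trace back", {
  st <- make_phantom_study(one_embolus_spec())
  p1 <- preprocess_study(st)
  p2 <- preprocess_study(st)
  expect_identical(p1$manifest, p2$manifest)
  expect_identical(p1$tensors[[2]], p2$tensors[[2]])
  expect_true(any(p1$manifest$label == 1))
  # window label = OR of cropped slice labels over each span
  iso <- resample_isotropic(st)
  cropped <- crop_to_box(iso, p1$box)
  spans <- purrr::map(seq_len(nrow(p1$manifest)),
                      ~ c(p1$manifest$z0[.x], p1$manifest$z1[.x]))
  expect_equal(derive_window_labels(cropped$slice_labels, spans),
               p1$manifest$label)
})
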