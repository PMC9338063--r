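pe <- asNamespace("peflow")

toy_model <- function(seed = 1L) {
  phase2_init(phase2_config("test", seed = seed))
}

test_that("TCN preserves sequence length and emits 128-d embeddings", {
  withr::with_seed(2, {
    m <- toy_model()
    z <- matrix(rnorm(40 * 1536, sd = 0.3), 40, 1536)
    x1 <- tcn_forward(m, z)
    expect_equal(dim(x1), c(40, 128))
    expect_true(all(is.finite(x1)))
    # dropout disabled outside training: identical outputs
    expect_identical(x1, tcn_forward(m, z))
    expect_error(tcn_forward(m, z[1:20, ]), "40 x 1536")

    # config invariants
    cfg <- tcn_config()
    expect_equal(cfg$dilations, c(1L, 2L))
    expect_equal(cfg$out_channels, 128L)
  })
})

test_that("zeroed convolutions trace the residual path only", {
  withr::with_seed(5, {
    m <- toy_model()
    # weight-normed convs vanish when their gains and biases are zero
    for (i in seq_along(m$levels)) {
      m$levels[[i]]$conv1$g[] <- 0; m$levels[[i]]$conv1$b[] <- 0
      m$levels[[i]]$conv2$g[] <- 0; m$levels[[i]]$conv2$b[] <- 0
    }
    proj <- matrix(rnorm(1536 * 128, sd = 0.05), 1536, 128)
    m$levels[[1]]$proj$W <- proj
    m$levels[[1]]$proj$b[] <- 0
    z <- matrix(rnorm(40 * 1536), 40, 1536)
    got <- tcn_forward(m, z)
    # level 1 reduces to relu(proj(z)); level 2 (identity residual) passes
    # the nonnegative activations through unchanged
    want <- pmax(z %*% proj, 0)
    expect_equal(got, want, tolerance = 1e-12)
  })
})

test_that("attention weights are probability vectors with the uniform and
          concentrated limits", {
  withr::with_seed(8, {
    X <- matrix(rnorm(40 * 128), 40, 128)
    w_q <- rnorm(128)
    ap <- attention_pool(X, w_q)
    expect_equal(sum(ap$a), 1, tolerance = 1e-9)
    expect_true(all(ap$a >= 0))
    expect_equal(ap$e, as.numeric(crossprod(X, ap$a)), tolerance = 1e-12)

    # constant scores -> exactly uniform 1/40 and e = column means
    Xc <- matrix(rnorm(128), 40, 128, byrow = TRUE)
    apc <- attention_pool(Xc, w_q)
    expect_equal(apc$a, rep(1 / 40, 40), tolerance = 1e-12)
    expect_equal(apc$e, colMeans(Xc), tolerance = 1e-12)

    # masked positions get zero weight, rest renormalizes
    mask <- c(rep(TRUE, 25), rep(FALSE, 15))
    apm <- attention_pool(X, w_q, mask)
    expect_true(all(apm$a[26:40] == 0))
    expect_equal(sum(apm$a), 1, tolerance = 1e-9)
    expect_error(attention_pool(X, w_q, rep(FALSE, 40)), "masked")
  })
})

test_that("attention matches a 3-row scalar oracle and is permutation
          equivariant", {
  X <- matrix(c(0.5, -1, 2,
                1, 0, -0.5,
                -2, 1, 0.25), 3, 3, byrow = TRUE)
  w_q <- c(0.3, -0.7, 0.2)
  # elementwise scalar computation
  s <- tanh(as.numeric(X %*% w_q))
  a_want <- exp(s) / sum(exp(s))
  e_want <- as.numeric(t(X) %*% a_want)
  ap <- attention_pool(X, w_q)
  expect_equal(ap$a, a_want, tolerance = 1e-6)
  expect_equal(ap$e, e_want, tolerance = 1e-6)

  # permuting rows permutes a identically and leaves e unchanged
  perm <- c(3, 1, 2)
  app <- attention_pool(X[perm, ], w_q)
  expect_equal(app$a, ap$a[perm], tolerance = 1e-12)
  expect_equal(app$e, ap$e, tolerance = 1e-12)
})

test_that("predict_heads emits nine named study logits deterministically", {
  withr::with_seed(4, {
    m <- toy_model()
    X <- matrix(rnorm(40 * 128), 40, 128)
    mask <- c(rep(TRUE, 18), rep(FALSE, 22))
    p1 <- predict_heads(m, X, mask, study_id = "s1")
    expect_s3_class(p1, "pe_study_prediction")
    expect_named(p1$study_logits, study_label_names())
    expect_equal(dim(p1$attention_weights), c(9, 40))
    expect_true(all(abs(rowSums(p1$attention_weights) - 1) < 1e-6))
    expect_true(all(p1$attention_weights[, !mask] == 0))
    expect_true(all(is.na(p1$window_logits[!mask])))
    p2 <- predict_heads(m, X, mask, study_id = "s1")
    expect_identical(p1$study_logits, p2$study_logits)
  })
})

test_that("loss terms reproduce the printed multitask formulas", {
  # q = 0: every window term is exactly zero
  terms0 <- phase2_loss_terms(rnorm(5), rep(0L, 5), q = 0,
                              rnorm(9), rbinom(9, 1, 0.5))
  expect_identical(terms0$window, rep(0, 5))
  # w_k = 1, z = 0: study term = ln 2 regardless of the label
  terms1 <- phase2_loss_terms(0, 1L, q = 1, rep(0, 9), rep(1L, 9))
  expect_equal(terms1$study, rep(log(2), 9), tolerance = 1e-12)
  terms2 <- phase2_loss_terms(0, 1L, q = 1, rep(0, 9), rep(0L, 9))
  expect_equal(terms2$study, rep(log(2), 9), tolerance = 1e-12)

  withr::with_seed(6, {
    for (rep in 1:5) {
      nw <- sample(3:20, 1)
      zw <- rnorm(nw, sd = 2); yw <- rbinom(nw, 1, 0.4)
      zs <- rnorm(9, sd = 2); ys <- rbinom(9, 1, 0.4)
      q <- mean(yw); w <- runif(1, 0.2, 2); wk <- runif(9, 0.1, 2)
      terms <- phase2_loss_terms(zw, yw, q, zs, ys, w, wk)
      expect_equal(terms$window, w * q * oracle_bce(zw, yw),
                   tolerance = 1e-6)
      expect_equal(terms$study, wk * oracle_bce(zs, ys), tolerance = 1e-6)
    }
  })
  expect_error(phase2_loss_terms(0, 2L, 1, rep(0, 9), rep(0L, 9)), "0/1")
})

test_that("batch loss normalizes by sum(N_i + 9) and ignores study order", {
  # M = 1, N = 3 -> denominator 12
  t1 <- list(window = c(1, 2, 3), study = rep(0, 9))
  expect_equal(phase2_batch_loss(list(t1)), 6 / 12)
  # all-zero terms
  expect_equal(phase2_batch_loss(list(list(window = rep(0, 7),
                                           study = rep(0, 9)))), 0)
  # two-study batch, hand-computed
  zw1 <- c(0.5, -1); yw1 <- c(1L, 0L)
  zw2 <- c(2, 0, -2); yw2 <- c(1L, 1L, 0L)
  zs1 <- seq(-2, 2, length.out = 9); ys1 <- rep(c(0L, 1L), length.out = 9)
  zs2 <- rev(zs1); ys2 <- rev(ys1)
  terms <- list(
    phase2_loss_terms(zw1, yw1, mean(yw1), zs1, ys1),
    phase2_loss_terms(zw2, yw2, mean(yw2), zs2, ys2))
  hand <- (sum(0.5 * oracle_bce(zw1, yw1)) + sum(oracle_bce(zs1, ys1)) +
             sum(2 / 3 * oracle_bce(zw2, yw2)) + sum(oracle_bce(zs2, ys2))) /
    ((2 + 9) + (3 + 9))
  expect_equal(phase2_batch_loss(terms), hand, tolerance = 1e-6)
  expect_equal(phase2_batch_loss(rev(terms)), phase2_batch_loss(terms),
               tolerance = 1e-12)
  expect_error(phase2_batch_loss(list()), "empty")
})

test_that("the batched training path agrees with the single-sequence ops", {
  withr::with_seed(10, {
    fd <- make_feature_dataset(synthetic_feature_spec(
      3, windows_range = c(6, 50), positive_shift = 2,
      positive_fraction = 0.7, seed = 14))
    seqs <- pe$prepare_sequences(fd)
    m <- toy_model(3)
    batch <- pe$stack_batch(seqs)
    fw <- pe$phase2_forward_batch(m, batch, train = FALSE)
    for (b in seq_along(seqs)) {
      sq <- seqs[[b]]
      X_single <- tcn_forward(m, sq$canonical)
      rows <- (b - 1) * 40 + seq_len(40)
      expect_equal(fw$X[rows, ], X_single, tolerance = 1e-10)
      p <- predict_heads(m, X_single, sq$valid_mask, sq$study_id)
      expect_equal(unname(fw$study_logits[b, ]), unname(p$study_logits),
                   tolerance = 1e-10)
      expect_equal(fw$window_logits[rows][sq$valid_mask],
                   p$window_logits[sq$valid_mask], tolerance = 1e-10)
    }
    # and the batched loss agrees with the exported per-study formulas
    lg <- pe$phase2_loss_and_grads(m, batch, fw, w = 1, w_k = rep(1, 9))
    terms <- purrr::map(seq_along(seqs), function(b) {
      sq <- seqs[[b]]
      rows <- (b - 1) * 40 + which(sq$valid_mask)
      labs <- sq$canonical_labels[sq$valid_mask]
      phase2_loss_terms(fw$window_logits[rows], labs, sq$q,
                        fw$study_logits[b, ], sq$study_labels)
    })
    expect_equal(lg$loss, phase2_batch_loss(terms), tolerance = 1e-10)
  })
})

test_that("phase-2 model gradients match finite differences", {
  withr::with_seed(15, {
    fd <- make_feature_dataset(synthetic_feature_spec(
      2, windows_range = c(5, 12), positive_shift = 2,
      positive_fraction = 1, seed = 4))
    seqs <- pe$prepare_sequences(fd)
    m <- toy_model(11)
    batch <- pe$stack_batch(seqs)
    loss_of <- function(mm) {
      f <- pe$phase2_forward_batch(mm, batch, train = FALSE)
      pe$phase2_loss_and_grads(mm, batch, f, 1, rep(1, 9))$loss
    }
    fw <- pe$phase2_forward_batch(m, batch, train = FALSE)
    lg <- pe$phase2_loss_and_grads(m, batch, fw, 1, rep(1, 9))
    eps <- 1e-5
    chk <- function(set, gval) {
      num <- (loss_of(set(m, eps)) - loss_of(set(m, -eps))) / (2 * eps)
      expect_equal(num, gval, tolerance = 1e-4)
    }
    chk(function(mm, d) {
      mm$levels[[1]]$conv1$v[100, 5] <- mm$levels[[1]]$conv1$v[100, 5] + d; mm
    }, lg$grads$levels[[1]]$conv1$v[100, 5])
    chk(function(mm, d) {
      mm$levels[[1]]$conv1$g[5] <- mm$levels[[1]]$conv1$g[5] + d; mm
    }, lg$grads$levels[[1]]$conv1$g[5])
    chk(function(mm, d) {
      mm$levels[[2]]$conv2$v[50, 8] <- mm$levels[[2]]$conv2$v[50, 8] + d; mm
    }, lg$grads$levels[[2]]$conv2$v[50, 8])
    chk(function(mm, d) {
      mm$heads[[3]]$w_q[7] <- mm$heads[[3]]$w_q[7] + d; mm
    }, lg$grads$heads[[3]]$w_q[7])
    chk(function(mm, d) {
      mm$heads[[6]]$mlp1$W[20, 4] <- mm$heads[[6]]$mlp1$W[20, 4] + d; mm
    }, lg$grads$heads[[6]]$mlp1$W[20, 4])
    chk(function(mm, d) {
      mm$win$W[10, 1] <- mm$win$W[10, 1] + d; mm
    }, lg$grads$win$W[10, 1])
  })
})

test_that("training is reproducible and learns a null-signal dataset to
          chance only", {
  tr <- make_feature_dataset(synthetic_feature_spec(
    24, positive_shift = 0, positive_fraction = 0.5, seed = 31))
  va <- make_feature_dataset(synthetic_feature_spec(
    12, positive_shift = 0, positive_fraction = 0.5, seed = 32))
  te <- make_feature_dataset(synthetic_feature_spec(
    200, positive_shift = 0, positive_fraction = 0.5, seed = 33))
  cfg <- phase2_config("test", epochs = 2, seed = 21)
  ck1 <- train_phase2(tr, va, cfg)
  ck2 <- train_phase2(tr, va, cfg)
  expect_identical(ck1$selected_epoch, ck2$selected_epoch)
  expect_identical(ck1$model$win$W, ck2$model$win$W)
  # zero-signal features: held-out window AUROC stays near chance
  pred <- predict_studies(ck1, te)
  auc <- roc_curve_auc(pred$window_probs$prob,
                       pred$window_probs$pe_present)$auroc
  expect_lt(abs(auc - 0.5), 0.08)
  expect_error(train_phase2(list(features = tr$features[0, ],
                                 window_labels = tr$window_labels[0, ],
                                 study_labels = tr$study_labels[0, ]),
                            va, cfg), "nonempty")
})
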