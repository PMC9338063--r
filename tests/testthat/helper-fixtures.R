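# Shared fixtures: small phantoms and reduced configs, built in code.

tiny_phantom_spec <- function(emboli = list(), n_slices = 36L,
                              slice_shape = c(48L, 48L),
                              spacing_mm = c(2.5, 1, 1), noise_sd = 10,
                              seed = 1L, ...) {
  phantom_spec(n_slices, slice_shape, spacing_mm,
               lung_extent = c(5, 32, 7, 41, 5, 43),
               emboli = emboli, noise_sd = noise_sd, seed = seed, ...)
}

one_embolus_spec <- function(center = c(15, 24, 14), radius = 3, ...) {
  tiny_phantom_spec(emboli = list(embolus(center, radius)), ...)
}

# a handful of labeled window tensors at test-profile size
tiny_window_set <- function(n_studies = 4, n_positive = 2, seed = 1L) {
  specs <- default_phantom_specs(n_studies, n_positive, n_slices = 24,
                                 slice_shape = c(32, 32),
                                 spacing_mm = c(2, 1, 1), seed = seed)
  ds <- make_phantom_dataset(specs, seed = seed)
  tensors <- list()
  for (s in ds$studies) {
    pp <- preprocess_study(s)
    tensors <- c(tensors, pp$tensors)
  }
  tensors
}

# independent scalar BCE oracle, written without the package helpers
oracle_bce <- function(z, y) {
  s <- 1 / (1 + exp(-z))
  -(y * log(s) + (1 - y) * log(1 - s))
}

# all-pairs AUROC enumeration oracle (ties count 1/2)
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# naive DeLong structural components (O(m*n)) for cross-checking
oracle_delong_var <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(vapply(neg, function(y) psi(x, y), 0)), 0)
  v01 <- vapply(neg, function(y) mean(vapply(pos, function(x) psi(x, y), 0)), 0)
  list(auroc = mean(v10), var = var(v10) / m + var(v01) / n)
}
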