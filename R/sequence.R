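# Canonicalization of per-study feature sequences for the sequential model.

CANONICAL_LEN <- 40L

#' Assemble a canonical feature sequence
#'
#' Turns an ordered `N x 512` window-feature matrix into the fixed-shape
#' phase-2 input. Each position is augmented with its differences to both
#' neighbors, `[f, f - f_prev, f - f_next]` (1536-d); at the sequence ends
#' the missing neighbor is replicated, so the corresponding difference block
#' is zero. Sequences shorter than 40 are zero-padded at the end (tracked by
#' `valid_mask`); longer sequences are resized to length 40 by per-column
#' linear interpolation. Window labels, when given, are reduced onto the
#' canonical grid by an OR over an equal 40-way partition of the source
#' windows, so a positive window is never lost.
#'
#' @param raw `N x 512` numeric matrix, windows in z order.
#' @param study_id Character id.
#' @param window_labels Optional 0/1 vector of length `N`.
#' @return An object of class `pe_feature_sequence`: `canonical`
#'   (`40 x 1536`), `valid_mask` (length-40 logical), `n_windows`,
#'   `canonical_labels` (length-40, `NA` on padding when labels given),
#'   `q` (fraction of positive windows among the `N` real ones), `raw`.
#' @export
assemble_sequence <- function(raw, study_id = "study", window_labels = NULL) {
  if (is.null(dim(raw)) || nrow(raw) < 1) abort("feature sequence is empty")
  n <- nrow(raw)
  if (!is.null(window_labels) && length(window_labels) != n) {
    abort("window_labels length must equal the number of feature rows")
  }
  prev <- raw[c(1, seq_len(n - 1)), , drop = FALSE]
  nxt <- raw[c(seq_len(n)[-1], n), , drop = FALSE]
  feats <- cbind(raw, raw - prev, raw - nxt)         # N x 1536

  if (n <= CANONICAL_LEN) {
    canonical <- matrix(0, CANONICAL_LEN, ncol(feats))
    canonical[seq_len(n), ] <- feats
    valid <- c(rep(TRUE, n), rep(FALSE, CANONICAL_LEN - n))
    labels <- if (!is.null(window_labels)) {
      c(as.integer(window_labels), rep(NA_integer_, CANONICAL_LEN - n))
    }
  } else {
    canonical <- interp_columns(feats, CANONICAL_LEN)
    valid <- rep(TRUE, CANONICAL_LEN)
    labels <- if (!is.null(window_labels)) {
      reduce_labels_partition(as.integer(window_labels), CANONICAL_LEN)
    }
  }
  structure(list(study_id = study_id, raw = raw, canonical = canonical,
                 valid_mask = valid, n_windows = n,
                 canonical_labels = labels,
                 q = if (!is.null(window_labels)) mean(window_labels == 1)),
            class = "pe_feature_sequence")
}

# per-column 1-D linear interpolation onto n_out equally spaced positions
# spanning the full source index range (align-endpoints semantics)
interp_columns <- function(x, n_out) {
  n <- nrow(x)
  src <- seq(0, n - 1, length.out = n_out)
  lo <- pmin(floor(src), n - 2)
  fr <- src - lo
  x[lo + 1, , drop = FALSE] * (1 - fr) + x[lo + 2, , drop = FALSE] * fr
}

# OR-reduce labels over an equal n_out-way partition of [0, n)
reduce_labels_partition <- function(labels, n_out) {
  n <- length(labels)
  out <- integer(n_out)
  for (j in seq_len(n_out)) {
    lo <- floor((j - 1) * n / n_out)
    hi <- max(lo, ceiling(j * n / n_out) - 1)
    out[j] <- as.integer(any(labels[(lo:hi) + 1] == 1))
  }
  out
}
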