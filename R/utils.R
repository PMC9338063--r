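#' @importFrom rlang abort warn hash .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif setNames approx
NULL

# The nine study-level attribute labels, in canonical column order.
#' Study-level label names
#'
#' Returns the canonical names of the nine per-study PE attribute labels:
#' negative for PE, indeterminate, chronic, acute-and-chronic, central/left/
#' right PE, and the two right-to-left-ventricle diameter ratio classes.
#'
#' @return Character vector of length 9.
#' @export
study_label_names <- function() {
  c("negative_for_pe", "indeterminate", "chronic", "acute_and_chronic",
    "central_pe", "left_pe", "right_pe", "rv_lv_gte_1", "rv_lv_lt_1")
}

# Deterministic per-item seed streams below 2^31, so adding a study does not
# perturb the RNG draws of earlier ones.
derive_seed <- function(seed, index) {
  h <- rlang::hash(list(as.integer(seed), as.integer(index)))
  (strtoi(substr(h, 1, 7), base = 16L) %% 2147483562L) + 1L
}

check_binary <- function(x, what = "labels") {
  if (length(x) == 0 || !all(x %in% c(0, 1))) {
    abort(sprintf("%s must be a nonempty vector of 0/1 values", what))
  }
  as.integer(x)
}

# sigmoid / log-sigmoid, numerically stable for large |z|
sigmoid <- function(z) 1 / (1 + exp(-z))

log_sigmoid <- function(z) ifelse(z >= 0, -log1p(exp(-z)), z - log1p(exp(z)))

# Stable elementwise BCE-with-logits: -[y log s(z) + (1-y) log(1-s(z))]
bce_with_logits <- function(z, y) {
  -(y * log_sigmoid(z) + (1 - y) * log_sigmoid(-z))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform draw from a:b that is safe when a == b (unlike sample(a:b, 1))
sample_int_range <- function(a, b) {
  if (a >= b) return(as.integer(a))
  sample(a:b, 1L)
}
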