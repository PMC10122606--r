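# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' Expands one user-facing seed into independent per-stage seeds by hashing
#' the stage label, so that adding a stage to a workflow never perturbs the
#' random stream of earlier stages.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(paste(label, collapse = ""))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

# Column-standardize a numeric matrix; constant columns get sd 1 so they map
# to zero rather than NaN.  Returns list(x, center, scale).
standardize_cols <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(x = scale(x, center = ctr, scale = scl), center = ctr, scale = scl)
}

# Stratified bootstrap indices: resamples within each class, preserving class
# counts, so no resample can lose a class.
stratified_bootstrap <- function(labels) {
  idx <- seq_along(labels)
  unlist(lapply(split(idx, labels), function(i) {
    sample(i, length(i), replace = TRUE)
  }), use.names = FALSE)
}

stop_input <- function(...) stop(..., call. = FALSE)
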