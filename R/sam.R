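# SAM-style moderated difference statistic used as a noise prefilter before
# marker selection.  For gene i with two label groups, d_i = (mean1 - mean0)
# / (s_i + s0), where s_i is the pooled standard error and s0 a
# variance-stabilizing fudge constant (median of the s_i) that keeps genes
# with tiny variance from dominating the ranking.  A permutation null over
# label reassignments provides per-gene significance.

sam_d_statistic <- function(values, labels, s0 = NULL) {
  g1 <- labels == 1L
  g0 <- labels == 0L
  n1 <- sum(g1); n0 <- sum(g0)
  m1 <- rowMeans(values[, g1, drop = FALSE])
  m0 <- rowMeans(values[, g0, drop = FALSE])
  ss1 <- rowSums((values[, g1, drop = FALSE] - m1)^2)
  ss0 <- rowSums((values[, g0, drop = FALSE] - m0)^2)
  pooled_var <- (ss1 + ss0) / (n1 + n0 - 2)
  s <- sqrt((1 / n1 + 1 / n0) * pooled_var)
  if (is.null(s0)) s0 <- stats::median(s)
  list(d = (m1 - m0) / (s + s0), s = s, s0 = s0)
}

#' SAM prefilter: rank genes by a moderated difference statistic
#'
#' Screens out noise genes before marker selection by ranking every gene's
#' moderated two-group difference statistic and retaining the strongest.
#' Significance of each gene's statistic is assessed against a permutation
#' null built by reshuffling the labels.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Binary vector (0/1, NA allowed) aligned with the samples;
#'   NA-labeled samples are ignored.
#' @param n_permutations Number of label permutations for the null.
#' @param top_k Retain the `top_k` genes with largest `|d|` (default 2000,
#'   capped at the gene count).  Ignored when `delta` is given.
#' @param delta Optional absolute-statistic cutoff: retain genes with
#'   `|d| >= delta` instead of a fixed count.
#' @param seed Seed for the permutation null.
#' @return A `sam_result`: data.frame `table` (gene, d, null_p) sorted by
#'   `|d|` descending, the fudge constant `s0`, and `selected` gene ids.
#' @export
sam_prefilter <- function(expr, labels, n_permutations = 100L, top_k = 2000L,
                          delta = NULL, seed = NULL) {
  stopifnot(length(labels) == ncol(expr))
  keep <- !is.na(labels)
  labels <- as.integer(labels[keep])
  values <- expr[, keep, drop = FALSE]
  if (!all(labels %in% c(0L, 1L))) stop_input("labels must be binary 0/1")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop_input("both label classes must be non-empty")
  if (n_permutations < 1L) stop_input("n_permutations must be >= 1")

  obs <- sam_d_statistic(values, labels)
  if (!is.null(seed)) set.seed(seed)
  exceed <- rep(0L, nrow(values))
  for (b in seq_len(n_permutations)) {
    perm <- sample(labels)
    dp <- sam_d_statistic(values, perm, s0 = obs$s0)$d
    exceed <- exceed + (abs(dp) >= abs(obs$d))
  }
  null_p <- (exceed + 1) / (n_permutations + 1)

  ord <- order(-abs(obs$d), rownames(values))
  tab <- data.frame(gene = rownames(values)[ord], d = obs$d[ord],
                    null_p = null_p[ord], row.names = NULL,
                    stringsAsFactors = FALSE)
  selected <- if (!is.null(delta)) {
    tab$gene[abs(tab$d) >= delta]
  } else {
    tab$gene[seq_len(min(top_k, nrow(tab)))]
  }
  structure(list(table = tab, s0 = obs$s0, selected = selected,
                 n_permutations = n_permutations),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("<sam_result> %d genes scored, %d retained (s0 = %.4g)\n",
              nrow(x$table), length(x$selected), x$s0))
  invisible(x)
}
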