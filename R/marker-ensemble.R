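# Bagged elastic-net stability selection for binary clinical markers.
#
# An ensemble of elastic-net-penalized logistic classifiers is trained on
# bootstrap resamples of the labeled samples.  Each member's non-null
# coefficient support marks the genes it considers associated with the
# marker; the stability index of gene i is s_i = n_gi / NB, the fraction of
# resamples in which the gene received a non-null coefficient.  Marker
# status of new samples is predicted by majority vote across members.

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

rank_auc <- function(prob, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(prob)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Elastic-net lambda grid: 50 log-spaced values from the data-derived
# maximum (the smallest lambda whose solution is all-zero) down 4 decades.
lambda_grid <- function(x_std, y, alpha, n_lambda = 50L, decades = 4) {
  n <- length(y)
  lmax <- max(abs(crossprod(x_std, y - mean(y)))) / (n * max(alpha, 1e-3))
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = n_lambda))
}

#' Fit a bagged elastic-net ensemble for one binary marker
#'
#' For each of `nb` bootstrap resamples of the labeled samples (resample
#' size equal to the number of labeled samples, drawn with replacement
#' within each class so neither class can vanish), an elastic-net logistic
#' regression is fitted on per-resample standardized expression.  The
#' penalty weight lambda is chosen per resample by an inner
#' cross-validation loop maximizing held-out binomial log-likelihood; an
#' outer loop re-estimates held-out AUC at the chosen lambda.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Binary 0/1 vector aligned with samples; NA = unlabeled
#'   (excluded from training).
#' @param nb Number of bootstrap resamples.
#' @param alpha Elastic-net mixing parameter in `[0,1]` (0 = ridge,
#'   1 = lasso).
#' @param inner_folds Folds of the inner lambda-selection loop.
#' @param outer_folds Folds of the outer AUC loop.
#' @param record_auc Estimate per-resample held-out AUC (adds
#'   `outer_folds` extra fits per resample).
#' @param seed Integer seed.
#' @param marker Marker name carried into the result.
#' @return A `marker_ensemble` with members (sparse standardized
#'   coefficients + standardization moments), per-gene selection counts and
#'   the trained gene order.
#' @export
fit_marker_ensemble <- function(expr, labels, nb = 100L, alpha = 0.8,
                                inner_folds = 5L, outer_folds = 5L,
                                record_auc = TRUE, seed = NULL,
                                marker = "marker") {
  stopifnot(length(labels) == ncol(expr))
  if (nb < 1L) stop_input("nb must be >= 1")
  if (alpha < 0 || alpha > 1) stop_input("alpha must lie in [0,1]")
  keep <- !is.na(labels)
  y <- labels[keep]
  if (!all(y %in% c(0, 1))) stop_input("labels must be binary 0/1")
  y <- as.integer(y)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop_input("both label classes must have at least 2 labeled samples")
  if (nrow(expr) < 2L) stop_input("need at least 2 genes")
  x <- t(expr[, keep, drop = FALSE])
  genes <- rownames(expr)
  if (!is.null(seed)) set.seed(seed)

  counts <- stats::setNames(integer(length(genes)), genes)
  members <- vector("list", nb)
  for (j in seq_len(nb)) {
    idx <- stratified_bootstrap(y)
    xj <- x[idx, , drop = FALSE]
    yj <- y[idx]
    std <- standardize_cols(xj)
    grid <- lambda_grid(std$x, yj, alpha)
    foldid <- stratified_folds(yj, inner_folds)
    cvfit <- glmnet::cv.glmnet(std$x, yj, family = "binomial", alpha = alpha,
                               lambda = grid, foldid = foldid,
                               standardize = FALSE,
                               type.measure = "deviance")
    lam <- cvfit$lambda.min
    cf <- as.numeric(stats::coef(cvfit, s = lam))
    beta <- cf[-1L]
    support <- which(abs(beta) > 1e-12)
    counts[support] <- counts[support] + 1L

    auc_j <- NA_real_
    if (record_auc) {
      ofold <- stratified_folds(yj, outer_folds)
      prob <- rep(NA_real_, length(yj))
      for (k in seq_len(outer_folds)) {
        tr <- ofold != k
        std_k <- standardize_cols(xj[tr, , drop = FALSE])
        fit_k <- glmnet::glmnet(std_k$x, yj[tr], family = "binomial",
                                alpha = alpha, lambda = grid,
                                standardize = FALSE)
        xt <- scale(xj[!tr, , drop = FALSE], std_k$center, std_k$scale)
        prob[!tr] <- stats::predict(fit_k, xt, s = lam, type = "response")
      }
      auc_j <- rank_auc(prob, yj)
    }

    members[[j]] <- list(
      intercept = cf[1L], lambda = lam, auc = auc_j,
      genes = genes[support], beta = beta[support],
      center = std$center[support], scale = std$scale[support])
  }

  structure(list(marker = marker, nb = nb, alpha = alpha,
                 genes = genes, selection_counts = counts,
                 members = members,
                 inner_folds = inner_folds, outer_folds = outer_folds),
            class = "marker_ensemble")
}

#' @export
print.marker_ensemble <- function(x, ...) {
  aucs <- vapply(x$members, `[[`, numeric(1), "auc")
  cat(sprintf("<marker_ensemble> marker '%s': NB = %d, alpha = %.2f, %d genes\n",
              x$marker, x$nb, x$alpha, length(x$genes)))
  if (any(!is.na(aucs)))
    cat(sprintf("  median held-out AUC: %.3f\n", stats::median(aucs, na.rm = TRUE)))
  cat(sprintf("  genes ever selected: %d\n", sum(x$selection_counts > 0L)))
  invisible(x)
}

#' Stability table of a fitted marker ensemble
#'
#' @param ensemble A [fit_marker_ensemble()] result.
#' @return data.frame (gene, ngi, si, rank) sorted by stability index
#'   descending, ties broken by gene id.
#' @export
stability_table <- function(ensemble) {
  stopifnot(inherits(ensemble, "marker_ensemble"))
  si <- ensemble$selection_counts / ensemble$nb
  ord <- order(-si, names(si))
  data.frame(gene = names(si)[ord],
             ngi = unname(ensemble$selection_counts[ord]),
             si = unname(si[ord]),
             rank = seq_along(si),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select genes whose stability index exceeds a threshold
#'
#' Retains genes with stability index strictly greater than the threshold,
#' in rank order.
#'
#' @param table A [stability_table()].
#' @param threshold Stability cutoff in `[0,1]` (default 0.10).
#' @param name Name for the returned signature.
#' @return A [gene_signature()]; empty (with a warning) when nothing passes.
#' @export
select_stable_genes <- function(table, threshold = 0.10, name = "stable") {
  if (threshold < 0 || threshold > 1) stop_input("threshold must lie in [0,1]")
  genes <- table$gene[table$si > threshold]
  if (length(genes) == 0L)
    warning("no gene exceeds stability threshold ", threshold, call. = FALSE)
  gene_signature(name, genes, allow_empty = TRUE)
}

#' Predict binary marker status by ensemble vote
#'
#' Each member votes the class of its predicted probability; the majority
#' wins, and an exact tie is broken by the ensemble-average probability
#' (>= 0.5 votes positive).
#'
#' @param ensemble A [fit_marker_ensemble()] result.
#' @param expr_new Expression matrix containing all trained genes.
#' @param type `"class"` for 0/1 votes, `"prob"` for the ensemble-average
#'   predicted probability.
#' @return Named vector over the samples of `expr_new`.
#' @export
predict_marker_status <- function(ensemble, expr_new,
                                  type = c("class", "prob")) {
  type <- match.arg(type)
  stopifnot(inherits(ensemble, "marker_ensemble"))
  missing <- setdiff(ensemble$genes, rownames(expr_new))
  if (length(missing) > 0L)
    stop_input("expression matrix is missing trained gene(s): ",
               paste(missing, collapse = ", "))
  n <- ncol(expr_new)
  votes <- matrix(0, nrow = length(ensemble$members), ncol = n)
  probs <- matrix(0, nrow = length(ensemble$members), ncol = n)
  for (j in seq_along(ensemble$members)) {
    m <- ensemble$members[[j]]
    eta <- rep(m$intercept, n)
    if (length(m$genes) > 0L) {
      z <- (expr_new[m$genes, , drop = FALSE] - m$center) / m$scale
      eta <- eta + as.numeric(crossprod(z, m$beta))
    }
    p <- stats::plogis(eta)
    probs[j, ] <- p
    votes[j, ] <- as.integer(p > 0.5)
  }
  mean_prob <- colMeans(probs)
  if (type == "prob") return(stats::setNames(mean_prob, colnames(expr_new)))
  share <- colMeans(votes)
  cls <- ifelse(share > 0.5, 1L,
                ifelse(share < 0.5, 0L, as.integer(mean_prob >= 0.5)))
  stats::setNames(as.integer(cls), colnames(expr_new))
}
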