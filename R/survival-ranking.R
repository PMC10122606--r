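# Survival ranking of candidate marker genes.
#
# Three views of each gene's association with survival:
#   * bootstrapped univariate Cox regression, summarized by the median
#     coefficient and median Wald p across resamples;
#   * the optimal-split log-rank p: the minimized two-group log-rank p over
#     all admissible cutpoints of the gene's expression;
#   * the separable L1-penalized multivariate Cox fit, reported as the mean
#     and standard deviation of each gene's coefficient across outer
#     cross-validation folds.
# The three are merged into a per-marker survival table sorted by the
# univariate Wald p, the layout used to report candidate survival markers.

#' Bootstrapped univariate Cox regression per gene
#'
#' For each gene, fits a one-covariate Cox proportional-hazards model
#' (Efron tie handling) on per-resample standardized expression for each of
#' `nb` bootstrap resamples, and summarizes the coefficient and its Wald p
#' by the median across resamples.  A negative coefficient means high
#' expression lowers the hazard (protective marker).
#'
#' @param expr Expression matrix restricted to the genes of interest.
#' @param time,event Survival time and event indicator per sample.
#' @param nb Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param bootstrap Set `FALSE` to fit on the original sample in every
#'   "resample" (so `nb = 1` reduces to the plain univariate fit).
#' @param min_events Minimum events per resample; offending resamples are
#'   redrawn (bounded retries) and skipped thereafter.
#' @return data.frame (gene, beta_unicox, wald_p, n_used); zero-variance
#'   genes get NA statistics rather than an error.
#' @export
bootstrap_unicox <- function(expr, time, event, nb = 100L, seed = NULL,
                             bootstrap = TRUE, min_events = 2L) {
  stopifnot(ncol(expr) == length(time), length(time) == length(event))
  if (nb < 1L) stop_input("nb must be >= 1")
  if (sum(event) < min_events) stop_input("fewer than ", min_events, " events")
  if (!is.null(seed)) set.seed(seed)
  n <- length(time)
  draws <- vector("list", nb)
  for (j in seq_len(nb)) {
    if (!bootstrap) { draws[[j]] <- seq_len(n); next }
    for (try in 1:20) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(event[idx]) >= min_events) break
      idx <- NULL
    }
    draws[[j]] <- idx                 # NULL = skipped degenerate resample
  }
  out <- lapply(rownames(expr), function(g) {
    x <- expr[g, ]
    if (stats::sd(x) < .Machine$double.eps) {
      return(data.frame(gene = g, beta_unicox = NA_real_, wald_p = NA_real_,
                        n_used = 0L, stringsAsFactors = FALSE))
    }
    betas <- ps <- rep(NA_real_, nb)
    for (j in seq_len(nb)) {
      idx <- draws[[j]]
      if (is.null(idx)) next
      z <- x[idx]
      sz <- stats::sd(z)
      if (sz < .Machine$double.eps) next
      z <- (z - mean(z)) / sz
      fit <- survival::coxph(survival::Surv(time[idx], event[idx]) ~ z,
                             ties = "efron")
      s <- summary(fit)
      betas[j] <- unname(fit$coefficients)
      ps[j] <- s$coefficients[1L, "Pr(>|z|)"]
    }
    data.frame(gene = g,
               beta_unicox = stats::median(betas, na.rm = TRUE),
               wald_p = stats::median(ps, na.rm = TRUE),
               n_used = sum(!is.na(betas)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Optimal-split log-rank p-value of a single gene
#'
#' Scans every admissible cutpoint of the gene's expression (the maximally
#' selected log-rank statistic) and returns the minimized two-group
#' log-rank p, measuring the gene's ability to stratify patients by
#' expression level alone.
#'
#' @param expr_gene Expression values per sample.
#' @param time,event Survival data.
#' @param min_group_fraction Smallest admissible group share (default 0.1).
#' @return The minimal log-rank p, or NA when no admissible split exists
#'   (e.g. constant expression).
#' @export
gene_logrank_optimal_p <- function(expr_gene, time, event,
                                   min_group_fraction = 0.1) {
  scan <- tryCatch(
    optimal_threshold(expr_gene, time, event,
                      min_group_fraction = min_group_fraction),
    error = function(e) NULL)
  if (is.null(scan)) NA_real_ else scan$best_p
}

#' Separable L1-penalized multivariate Cox with double-nested cross-validation
#'
#' The penalized partial-likelihood objective decomposes gene-wise, so each
#' gene has its own one-dimensional fit at a shared penalty `lambda`.  The
#' inner cross-validation loop chooses `lambda` on a log-spaced grid by
#' maximizing the cross-validated partial log-likelihood; the outer loop
#' refits on each training part and emits every sample's risk score
#' `f(X) = beta' X` from the model not trained on it.  Reported per-gene
#' coefficients are the mean across outer-fold fits, with their standard
#' deviation as a stability measure.
#'
#' @param expr Expression matrix restricted to the candidate genes.
#' @param time,event Survival data.
#' @param outer_folds,inner_folds Fold counts of the two loops (default 10).
#' @param seed Integer seed for fold assignment.
#' @param n_lambda,decades Penalty grid: `n_lambda` log-spaced values from
#'   the all-zero bound down `decades` decades.
#' @param standardize Standardize each gene on the training part before
#'   fitting (default TRUE); coefficients are then per standardized unit.
#' @return List with `multicox` (data.frame gene, beta_multicox, sd_beta),
#'   `risk_scores` (out-of-fold, named per sample), `fold_id`, per-fold
#'   `lambda`, and `final` (coefficients refit on all data at the selected
#'   lambda, with standardization moments).
#' @export
penalized_separable_cox <- function(expr, time, event, outer_folds = 10L,
                                    inner_folds = 10L, seed = NULL,
                                    n_lambda = 50L, decades = 4,
                                    standardize = TRUE) {
  stopifnot(ncol(expr) == length(time), length(time) == length(event))
  if (nrow(expr) < 1L) stop_input("candidate gene set is empty")
  if (sum(event) < 2L) stop_input("need at least 2 events")
  if (!is.null(seed)) set.seed(seed)
  n <- length(time)
  genes <- rownames(expr)
  xall <- t(expr)

  std_fit <- function(idx) {
    x <- xall[idx, , drop = FALSE]
    if (standardize) {
      std <- standardize_cols(x)
      list(x = std$x, center = std$center, scale = std$scale)
    } else {
      list(x = x, center = rep(0, ncol(x)),
           scale = rep(1, ncol(x)))
    }
  }

  # Shared lambda grid from the full-data all-zero bound.
  full <- std_fit(seq_len(n))
  lmax <- cox_sep_lambda_max(cox_sep_prepare(full$x, time, event))
  grid <- exp(seq(log(lmax), log(lmax) - decades * log(10),
                  length.out = n_lambda))

  # Cross-validated partial log-likelihood (Verweij-van Houwelingen):
  # sum over folds of l_allTrain(beta_-f) - l_trainMinusF(beta_-f).
  cv_lambda <- function(idx_train) {
    tt <- time[idx_train]; ee <- event[idx_train]
    fold <- stratified_folds(ee, inner_folds)
    cvl <- numeric(length(grid))
    std_tr <- std_fit(idx_train)
    prep_all <- cox_sep_prepare(std_tr$x, tt, ee)
    for (f in seq_len(inner_folds)) {
      sub <- fold != f
      if (sum(ee[sub]) < 1L) {          # fewer events than folds
        warning("inner fold without events skipped", call. = FALSE)
        next
      }
      prep_sub <- cox_sep_prepare(std_tr$x[sub, , drop = FALSE],
                                  tt[sub], ee[sub])
      b <- NULL
      for (li in seq_along(grid)) {
        fit <- cox_sep_fit(prep_sub, grid[li], beta_init = b)
        b <- fit$beta
        cvl[li] <- cvl[li] +
          sum(cox_sep_loglik(prep_all, b)) -
          sum(cox_sep_loglik(prep_sub, b))
      }
    }
    grid[which.max(cvl)]
  }

  fold_id <- stratified_folds(event, outer_folds)
  betas <- matrix(NA_real_, nrow = outer_folds, ncol = length(genes),
                  dimnames = list(NULL, genes))
  lambdas <- numeric(outer_folds)
  scores <- stats::setNames(rep(NA_real_, n), colnames(expr))
  for (k in seq_len(outer_folds)) {
    tr <- which(fold_id != k)
    te <- which(fold_id == k)
    lam <- cv_lambda(tr)
    lambdas[k] <- lam
    std_tr <- std_fit(tr)
    prep <- cox_sep_prepare(std_tr$x, time[tr], event[tr])
    fit <- cox_sep_fit(prep, lam)
    betas[k, ] <- fit$beta
    zte <- scale(xall[te, , drop = FALSE], std_tr$center, std_tr$scale)
    scores[te] <- as.numeric(zte %*% fit$beta)
  }

  lam_final <- grid[which.min(abs(log(grid) - stats::median(log(lambdas))))]
  fit_final <- cox_sep_fit(cox_sep_prepare(full$x, time, event), lam_final)
  if (all(abs(fit_final$beta) < 1e-12))
    warning("penalized Cox model is empty: all coefficients shrunk to zero",
            call. = FALSE)

  list(multicox = data.frame(gene = genes,
                             beta_multicox = colMeans(betas),
                             sd_beta = apply(betas, 2L, stats::sd),
                             row.names = NULL, stringsAsFactors = FALSE),
       risk_scores = scores, fold_id = fold_id, lambda = lambdas,
       final = list(lambda = lam_final, beta = stats::setNames(fit_final$beta, genes),
                    center = stats::setNames(full$center, genes),
                    scale = stats::setNames(full$scale, genes)),
       lambda_grid = grid)
}

#' Merge univariate, optimal-split and multivariate survival statistics
#'
#' @param unicox [bootstrap_unicox()] output.
#' @param multicox The `multicox` data.frame of [penalized_separable_cox()].
#' @param logrank Named numeric vector of per-gene optimal-split log-rank p.
#' @return A `survival_marker_table` data.frame (gene, logrank_p,
#'   beta_unicox, wald_p, beta_multicox, sd_beta) sorted by `wald_p`.
#' @export
build_marker_table <- function(unicox, multicox, logrank) {
  gs <- sort(unicox$gene)
  if (!identical(gs, sort(multicox$gene)) ||
      !identical(gs, sort(names(logrank))))
    stop_input("gene sets of the three inputs do not match")
  tab <- merge(unicox[, c("gene", "beta_unicox", "wald_p")],
               multicox[, c("gene", "beta_multicox", "sd_beta")], by = "gene")
  tab$logrank_p <- unname(logrank[tab$gene])
  tab <- tab[order(tab$wald_p, tab$gene),
             c("gene", "logrank_p", "beta_unicox", "wald_p",
               "beta_multicox", "sd_beta")]
  rownames(tab) <- NULL
  class(tab) <- c("survival_marker_table", "data.frame")
  tab
}

#' Select survival markers from a marker table
#'
#' Keeps genes whose chosen statistic falls below a p-value cut, preserving
#' the table's sort order.
#'
#' @param table A [build_marker_table()] result.
#' @param p_cut P-value cut (applied as strictly-below).
#' @param statistic `"logrank_p"` (default) or `"wald_p"`.
#' @param name Signature name.
#' @return A [gene_signature()] (possibly empty, with a warning).
#' @export
select_survival_markers <- function(table, p_cut = 0.05,
                                    statistic = c("logrank_p", "wald_p"),
                                    name = "survival_markers") {
  statistic <- match.arg(statistic)
  keep <- !is.na(table[[statistic]]) & table[[statistic]] < p_cut
  if (!any(keep))
    warning("no gene passes ", statistic, " < ", p_cut, call. = FALSE)
  gene_signature(name, table$gene[keep], allow_empty = TRUE)
}

#' Pool per-marker survival signatures into one gene set
#'
#' Unions the per-marker selections (duplicates collapsed, first-seen order)
#' and appends extra genes such as proliferation indicators.
#'
#' @param signatures List of [gene_signature()] objects.
#' @param extra_genes Genes appended after the union (e.g. AURKA, MKI67).
#' @param name Name of the pooled signature.
#' @return A [gene_signature()].
#' @export
pool_signatures <- function(signatures, extra_genes = character(0),
                            name = "pooled") {
  genes <- unique(c(unlist(lapply(signatures, `[[`, "genes")),
                    as.character(extra_genes)))
  gene_signature(name, genes, allow_empty = TRUE)
}
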