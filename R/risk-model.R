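# Risk model: linear risk score over a gene signature plus an optimal
# two-group stratification threshold.
#
# The threshold scan evaluates every observed risk score as a candidate
# cutpoint (low risk: score <= threshold; high risk: score > threshold),
# computes the two-group log-rank p at each admissible candidate, and keeps
# the minimizer (the maximally selected log-rank statistic).  The scan p is
# reported raw, uncorrected for the multiple candidate thresholds; the
# recommended workflow fits the threshold on training data and applies it
# to an independent cohort.

#' Linear risk scores of samples under a fitted risk model
#'
#' `f(X) = beta' X` on expression standardized with the model's stored
#' training moments.
#'
#' @param model A [fit_risk_model()] result.
#' @param expr Expression matrix containing all signature genes.
#' @return Named numeric vector of risk scores.
#' @export
risk_scores <- function(model, expr) {
  stopifnot(inherits(model, "risk_model"))
  genes <- names(model$coefficients)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    stop_input("expression matrix is missing signature gene(s): ",
               paste(missing, collapse = ", "))
  z <- (expr[genes, , drop = FALSE] - model$center) / model$scale
  stats::setNames(as.numeric(crossprod(z, model$coefficients)), colnames(expr))
}

#' Optimal two-group risk threshold by log-rank maximization
#'
#' Ranks the observed scores, takes each as a candidate threshold, computes
#' the two-group log-rank p for every admissible split (both groups at
#' least `min_group_fraction` of the samples), and returns the full p-curve
#' with the admissible minimizer.  Ties in p are broken toward the more
#' balanced split, then toward the lower threshold.
#'
#' @param scores Numeric risk scores (at least two distinct values).
#' @param time,event Survival data aligned with `scores`.
#' @param min_group_fraction Minimum admissible group share (default 0.1;
#'   set 0 to allow any non-empty split).
#' @return A `threshold_scan`: candidate `thresholds`, `p_values`,
#'   `admissible` flags, group sizes, `best_threshold` (the fitted gamma),
#'   `best_p` and the group sizes at the optimum.
#' @export
optimal_threshold <- function(scores, time, event, min_group_fraction = 0.1) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  n <- length(scores)
  cand <- sort(unique(scores))
  if (length(cand) < 2L)
    stop_input("need at least 2 distinct scores to place a threshold")
  if (sum(event) < 2L) stop_input("need at least 2 events")
  min_size <- max(1L, ceiling(min_group_fraction * n))

  # Vectorized log-rank over all candidate splits: for each distinct event
  # time t_k let n_k be the at-risk count, d_k the event count, and for
  # candidate threshold c let n_k1, d_k1 be the same counts in the
  # high-risk group (score > c).  Then U(c) = sum_k (d_k1 - d_k n_k1/n_k)
  # and V(c) is the hypergeometric variance; the statistic is U^2/V.
  et <- sort(unique(time[event == 1L]))
  risk <- outer(time, et, `>=`) * 1
  died <- outer(time, et, `==`) * event
  n_k <- colSums(risk)
  d_k <- colSums(died)
  grp_of <- match(scores, cand)
  cum_risk <- apply(rowsum(risk, grp_of), 2L, cumsum)   # low-group counts
  cum_died <- apply(rowsum(died, grp_of), 2L, cumsum)
  if (is.null(dim(cum_risk))) {
    cum_risk <- matrix(cum_risk, nrow = length(cand))
    cum_died <- matrix(cum_died, nrow = length(cand))
  }
  n_k1 <- matrix(n_k, nrow = length(cand), ncol = length(et),
                 byrow = TRUE) - cum_risk
  d_k1 <- matrix(d_k, nrow = length(cand), ncol = length(et),
                 byrow = TRUE) - cum_died
  frac <- sweep(n_k1, 2L, n_k, `/`)
  u <- rowSums(d_k1 - sweep(frac, 2L, d_k, `*`))
  vfac <- ifelse(n_k > 1, d_k * (n_k - d_k) / (n_k - 1), 0)
  v <- rowSums(sweep(frac * (1 - frac), 2L, vfac, `*`))
  stat <- unname(ifelse(v > 0, u^2 / v, NA_real_))
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)

  n_low_c <- cumsum(tabulate(grp_of, nbins = length(cand)))
  n_high <- n - n_low_c
  p[n_high < min_size | n_low_c < min_size] <- NA_real_
  admissible <- !is.na(p)
  if (!any(admissible))
    stop_input("no admissible split: both groups must contain at least ",
               min_size, " samples")
  pmin_v <- min(p[admissible])
  tied <- which(admissible & p == pmin_v)
  balance <- abs(n - 2L * n_high[tied])
  tied <- tied[order(balance, cand[tied])]
  best <- tied[1L]
  structure(list(thresholds = cand, p_values = p, admissible = admissible,
                 n_high = n_high, n_low = n - n_high,
                 best_index = best, best_threshold = cand[best],
                 best_p = p[best], best_n_high = n_high[best],
                 best_n_low = n - n_high[best],
                 min_group_fraction = min_group_fraction),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf(
    "<threshold_scan> %d candidates, gamma = %.4g (log-rank p = %.3g; %d low / %d high)\n",
    length(x$thresholds), x$best_threshold, x$best_p, x$best_n_low, x$best_n_high))
  invisible(x)
}

#' Assign samples to risk groups at a fitted threshold
#'
#' @param scan A [optimal_threshold()] result.
#' @param scores Risk scores to classify.
#' @return Integer vector, 1 = high risk (score strictly above the
#'   threshold), 0 = low risk.
#' @export
stratify <- function(scan, scores) {
  stopifnot(inherits(scan, "threshold_scan"))
  stats::setNames(as.integer(scores > scan$best_threshold), names(scores))
}

#' Fit a risk model on a cohort and a gene signature
#'
#' Runs the separable L1-penalized Cox fit restricted to the signature,
#' places the optimal threshold on the out-of-fold risk scores, and stores
#' the final coefficients (refit on all samples at the selected penalty)
#' together with the training standardization moments and the threshold.
#'
#' @param expr,clin Aligned expression matrix and clinical table.
#' @param signature A [gene_signature()]; all genes must be present.
#' @param outer_folds,inner_folds Cross-validation fold counts.
#' @param seed Integer seed.
#' @param min_group_fraction Admissibility constraint of the threshold scan.
#' @return A `risk_model`: signature, named `coefficients`, training
#'   `center`/`scale`, `threshold` (gamma), the threshold `scan`, per-fold
#'   penalty values and the out-of-fold `risk_scores`.
#' @export
fit_risk_model <- function(expr, clin, signature, outer_folds = 10L,
                           inner_folds = 10L, seed = NULL,
                           min_group_fraction = 0.1) {
  stopifnot(inherits(signature, "gene_signature"))
  missing <- setdiff(signature$genes, rownames(expr))
  if (length(missing) > 0L)
    stop_input("expression matrix is missing signature gene(s): ",
               paste(missing, collapse = ", "))
  if (!identical(colnames(expr), clin$sample_id))
    stop_input("expression and clinical samples are not aligned; see align_cohort()")
  sub <- expr[signature$genes, , drop = FALSE]
  psc <- penalized_separable_cox(sub, clin$time, clin$event,
                                 outer_folds = outer_folds,
                                 inner_folds = inner_folds, seed = seed)
  if (all(abs(psc$final$beta) < 1e-12))
    stop_input("risk model is empty (all coefficients zero); ",
               "use a larger signature or a smaller penalty")
  scan <- optimal_threshold(psc$risk_scores, clin$time, clin$event,
                            min_group_fraction = min_group_fraction)
  structure(list(signature = signature,
                 coefficients = psc$final$beta,
                 center = psc$final$center, scale = psc$final$scale,
                 lambda = psc$final$lambda, fold_lambda = psc$lambda,
                 threshold = scan$best_threshold, scan = scan,
                 multicox = psc$multicox,
                 risk_scores = psc$risk_scores),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> signature '%s' (%d genes), %d non-zero coefficients\n",
              x$signature$name, length(x$signature$genes),
              sum(abs(x$coefficients) > 1e-12)))
  cat(sprintf("  threshold gamma = %.4g (training log-rank p = %.3g; %d low / %d high)\n",
              x$threshold, x$scan$best_p, x$scan$best_n_low, x$scan$best_n_high))
  invisible(x)
}

#' Classify new samples against a fitted risk model
#'
#' Computes risk scores with the stored coefficients and training moments
#' and compares them to the fitted threshold; a score exactly at the
#' threshold goes to the low-risk group.
#'
#' @param model A [fit_risk_model()] result.
#' @param expr_new Expression matrix of the new samples.
#' @return Integer vector, 1 = high risk, 0 = low risk.
#' @export
classify_new <- function(model, expr_new) {
  sc <- risk_scores(model, expr_new)
  stats::setNames(as.integer(sc > model$threshold), names(sc))
}

#' Serialize a risk model to versioned JSON
#'
#' @param model A `risk_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  obj <- list(format = "survmarkers/risk_model", version = 1L,
              signature = list(name = model$signature$name,
                               genes = model$signature$genes),
              coefficients = as.list(model$coefficients),
              center = as.list(model$center), scale = as.list(model$scale),
              lambda = model$lambda, threshold = model$threshold,
              training = list(logrank_p = model$scan$best_p,
                              n_low = model$scan$best_n_low,
                              n_high = model$scan$best_n_high))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a risk model written by [write_risk_model()]
#' @param path JSON path.
#' @return A `risk_model` (without the full threshold scan).
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "survmarkers/risk_model"))
    stop_input("not a risk_model file: ", path)
  structure(list(signature = gene_signature(obj$signature$name,
                                            obj$signature$genes),
                 coefficients = unlist(obj$coefficients),
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 lambda = obj$lambda, threshold = obj$threshold,
                 scan = list(best_p = obj$training$logrank_p,
                             best_n_low = obj$training$n_low,
                             best_n_high = obj$training$n_high)),
            class = "risk_model")
}
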