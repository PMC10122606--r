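# Evaluation utilities: Kaplan-Meier curves, the two-group log-rank test,
# hazard ratios with Wald confidence intervals, classification accuracy
# with a Wilson binomial interval, and the multi-signature comparison
# harness that refits the identical risk-model procedure per signature so
# differences reflect gene content only.

#' Kaplan-Meier (product-limit) survival estimate
#'
#' @param time,event Survival data (times > 0).
#' @return A `km_curve`: distinct event times, the survival estimate just
#'   after each, and at-risk / event counts.  With no events the grid is
#'   empty and the estimate is identically 1.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop_input("empty survival data")
  if (any(time <= 0)) stop_input("times must be positive")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$n.event > 0
  structure(list(time = sf$time[keep], surv = sf$surv[keep],
                 n_risk = sf$n.risk[keep], n_event = sf$n.event[keep],
                 n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d distinct event times\n",
              x$n, length(x$time)))
  if (length(x$time) > 0L)
    print(utils::head(data.frame(time = x$time, surv = x$surv,
                                 n_risk = x$n_risk), 10L))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with hypergeometric
#' variance and its one-degree-of-freedom p-value.
#'
#' @param time,event Survival data.
#' @param groups Two-level group labels (both levels non-empty).
#' @return List with `statistic`, `p`, and per-group observed/expected
#'   event counts.
#' @export
logrank_test <- function(time, event, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop_input("exactly two non-empty groups required")
  if (sum(event) < 1L) stop_input("no events: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Hazard ratio between two groups with 95% confidence interval
#'
#' HR = exp(beta) from a one-covariate Cox fit on the indicator of the
#' second group level, with the Wald interval exp(beta +/- 1.96 SE), and
#' the log-rank p bundled alongside.
#'
#' @param time,event Survival data.
#' @param groups Two-level labels; the HR is for the second level (for 0/1
#'   risk groups: high vs low risk).
#' @param conf_level Confidence level (default 0.95).
#' @return A `group_comparison`: `logrank_p`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, group sizes and event counts; `unbounded_ci` flags a group
#'   without events (HR not estimable at finite precision).
#' @export
hazard_ratio <- function(time, event, groups, conf_level = 0.95) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop_input("exactly two non-empty groups required")
  if (sum(event) < 2L) stop_input("need at least 2 events")
  ind <- as.integer(g == levels(g)[2L])
  ev_by <- tapply(event, ind, sum)
  unbounded <- any(ev_by == 0)
  fit <- survival::coxph(survival::Surv(time, event) ~ ind, ties = "efron")
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1L, 1L]))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  lr <- logrank_test(time, event, g)
  structure(list(logrank_p = lr$p, hazard_ratio = exp(beta),
                 ci_low = exp(beta - zq * se), ci_high = exp(beta + zq * se),
                 n = as.integer(table(ind)[c("0", "1")]),
                 events = as.integer(ev_by[c("0", "1")]),
                 unbounded_ci = unbounded, conf_level = conf_level),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> HR = %.2f (%.2f-%.2f), log-rank p = %.3g%s\n",
              x$hazard_ratio, x$ci_low, x$ci_high, x$logrank_p,
              if (x$unbounded_ci) " [one group has no events: CI unreliable]" else ""))
  cat(sprintf("  groups: %d vs %d (events %d vs %d)\n",
              x$n[1L], x$n[2L], x$events[1L], x$events[2L]))
  invisible(x)
}

#' Classification accuracy with a Wilson 95% confidence interval
#'
#' @param predicted,truth Binary vectors of equal non-zero length.
#' @param conf_level Confidence level (default 0.95).
#' @return An `accuracy_report`: `accuracy`, `ci_low`, `ci_high`, `n`.
#' @export
accuracy_with_ci <- function(predicted, truth, conf_level = 0.95) {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    stop_input("predicted and truth must have equal non-zero length")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop_input("inputs must be binary 0/1")
  n <- length(truth)
  k <- sum(predicted == truth)
  phat <- k / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  structure(list(accuracy = phat, ci_low = max(0, centre - half),
                 ci_high = min(1, centre + half), n = n,
                 conf_level = conf_level),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("%.2f (%.2f-%.2f), n = %d\n",
              x$accuracy, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Compare gene signatures under one identical risk-model procedure
#'
#' Fits [fit_risk_model()] with the same folds and seed for every
#' signature, stratifies the cohort at each fitted threshold using the
#' out-of-fold risk scores, and reports log-rank p, hazard ratio and its
#' confidence interval per signature.  Signature genes absent from the
#' matrix are dropped with a warning (a signature with no present genes is
#' an error).  A signature whose penalized fit shrinks every coefficient to
#' zero carries no survival signal and is reported as a non-stratifying NA
#' row (with a warning) so the remaining signatures can still be compared.
#'
#' @param expr,clin Aligned cohort.
#' @param signatures List of [gene_signature()] objects.
#' @param outer_folds,inner_folds Fold counts passed to the risk model.
#' @param seed Integer seed (identical across signatures).
#' @param min_group_fraction Threshold-scan admissibility constraint.
#' @return data.frame: signature, n_genes_used, p_logrank, HR, HR_CI_low,
#'   HR_CI_high, n_low, n_high.
#' @export
compare_signatures <- function(expr, clin, signatures, outer_folds = 10L,
                               inner_folds = 10L, seed = 1L,
                               min_group_fraction = 0.1) {
  rows <- lapply(signatures, function(sig) {
    present <- intersect(sig$genes, rownames(expr))
    dropped <- setdiff(sig$genes, present)
    if (length(present) == 0L)
      stop_input("signature '", sig$name, "' has no genes in the matrix")
    if (length(dropped) > 0L)
      warning("signature '", sig$name, "': dropping absent gene(s) ",
              paste(dropped, collapse = ", "), call. = FALSE)
    use <- gene_signature(sig$name, present)
    model <- tryCatch(
      fit_risk_model(expr, clin, use, outer_folds = outer_folds,
                     inner_folds = inner_folds, seed = seed,
                     min_group_fraction = min_group_fraction),
      error = function(e) {
        if (!grepl("empty", conditionMessage(e))) stop(e)
        warning("signature '", sig$name, "' yields an empty risk model ",
                "(no survival signal); reported as non-stratifying",
                call. = FALSE)
        NULL
      })
    if (is.null(model)) {
      return(data.frame(signature = sig$name,
                        n_genes_used = length(present),
                        p_logrank = NA_real_, HR = NA_real_,
                        HR_CI_low = NA_real_, HR_CI_high = NA_real_,
                        n_low = NA_integer_, n_high = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    groups <- stratify(model$scan, model$risk_scores)
    cmp <- hazard_ratio(clin$time, clin$event, groups)
    data.frame(signature = sig$name, n_genes_used = length(present),
               p_logrank = cmp$logrank_p, HR = cmp$hazard_ratio,
               HR_CI_low = cmp$ci_low, HR_CI_high = cmp$ci_high,
               n_low = sum(groups == 0L), n_high = sum(groups == 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
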