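# Independent oracle implementations used to verify the package's survival
# machinery.  These are deliberately naive, loop-based textbook formulas,
# kept separate from any code path they check.

# Two-group log-rank statistic: loop over distinct event times, observed
# minus expected events in group 1 with the hypergeometric variance.
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- group == sort(unique(group))[2L]
  ev_times <- sort(unique(time[event == 1]))
  u <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    u <- u + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- u^2 / v
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Product-limit estimator by explicit loop over distinct event times.
oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  list(time = ev_times, surv = surv)
}

# Wilson score interval for a binomial proportion.
oracle_wilson <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(low = centre - half, high = centre + half)
}

# Unpenalized Cox partial log-likelihood for a single covariate (Breslow
# form; oracle datasets are tie-free, where Breslow and Efron coincide).
oracle_plik_1d <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    rs <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[rs] * beta)))
  }
  ll
}

# Dense 1-D grid-search maximizer of the partial likelihood.
oracle_grid_max_1d <- function(x, time, event, lo = -5, hi = 5, by = 1e-4) {
  grid <- seq(lo, hi, by = by)
  ll <- vapply(grid, oracle_plik_1d, numeric(1), x = x, time = time,
               event = event)
  grid[which.max(ll)]
}

# Exhaustive maximally-selected log-rank scan with the independent
# log-rank implementation above.
oracle_threshold_scan <- function(scores, time, event, min_group_fraction) {
  n <- length(scores)
  min_size <- max(1L, ceiling(min_group_fraction * n))
  cand <- sort(unique(scores))
  p <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    hi <- scores > cand[i]
    if (sum(hi) < min_size || sum(!hi) < min_size) next
    d1 <- sum(event[hi]); d0 <- sum(event[!hi])
    if (d1 + d0 < 1L) next
    res <- oracle_logrank(time, event, as.integer(hi))
    p[i] <- res$p
  }
  list(thresholds = cand, p = p)
}

# Best single-gene threshold classifier: for one gene, the cutpoint (and
# direction) maximizing training accuracy; used as the baseline that an
# ensemble predictor should beat.
oracle_single_gene_classifier <- function(x_train, y_train) {
  ord <- order(x_train)
  x <- x_train[ord]; y <- y_train[ord]
  n <- length(y); pos <- sum(y)
  cum <- c(0, cumsum(y))                       # positives among the low side
  k <- 0:n
  acc_hi <- ((pos - cum) + (k - cum)) / n      # predict 1 above the cut
  acc_lo <- ((n - k - (pos - cum)) + cum) / n  # predict 1 below the cut
  best_k <- which.max(pmax(acc_hi, acc_lo)) - 1L
  dir <- if (acc_hi[best_k + 1L] >= acc_lo[best_k + 1L]) 1L else -1L
  cut <- if (best_k == 0L) -Inf else if (best_k == n) Inf else
    (x[best_k] + x[best_k + 1L]) / 2
  list(acc = max(acc_hi[best_k + 1L], acc_lo[best_k + 1L]),
       cut = cut, dir = dir)
}

# Best single gene over a whole matrix (genes x samples), evaluated on a
# held-out set: the Table-2-style baseline.
oracle_best_single_gene_accuracy <- function(x_train, y_train, x_test,
                                             y_test) {
  fits <- lapply(rownames(x_train), function(g) {
    oracle_single_gene_classifier(x_train[g, ], y_train)
  })
  accs <- vapply(fits, `[[`, numeric(1), "acc")
  best <- which.max(accs)
  f <- fits[[best]]
  g <- rownames(x_train)[best]
  pred <- as.integer(f$dir * x_test[g, ] > f$dir * f$cut)
  mean(pred == y_test)
}

# Small reproducible survival dataset without ties.
make_surv_data <- function(n, seed, event_p = 0.7, rate = 0.1) {
  set.seed(seed)
  list(time = stats::rexp(n, rate), event = stats::rbinom(n, 1L, event_p))
}
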