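test_that("the product-limit estimate matches hand computation", {
  km <- km_estimate(c(1, 2, 3, 4), c(1L, 0L, 1L, 1L))
  expect_equal(km$time, c(1, 3, 4))
  expect_equal(km$surv, c(3 / 4, 3 / 8, 0))
  # no events: estimate identically 1 (empty event grid)
  km0 <- km_estimate(c(1, 2, 3), c(0L, 0L, 0L))
  expect_length(km0$time, 0L)
  # duplicating every observation leaves the curve unchanged
  km2 <- km_estimate(rep(c(1, 2, 3, 4), 2L), rep(c(1L, 0L, 1L, 1L), 2L))
  expect_equal(km2$time, km$time)
  expect_equal(km2$surv, km$surv)
  expect_error(km_estimate(numeric(0), integer(0)), "empty")
})

test_that("KM agrees with the textbook oracle on random small datasets", {
  for (s in 1:10) {
    d <- make_surv_data(sample(5:30, 1L), seed = 500L + s)
    if (sum(d$event) == 0L) next
    km <- km_estimate(d$time, d$event)
    orc <- oracle_km(d$time, d$event)
    expect_equal(km$time, orc$time, tolerance = 1e-12)
    expect_equal(km$surv, orc$surv, tolerance = 1e-10)
  }
})

test_that("the two-subject log-rank case gives statistic 1", {
  res <- logrank_test(c(1, 2), c(1L, 1L), c("A", "B"))
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pnorm(-1), tolerance = 1e-6)
  # label swap leaves the statistic unchanged
  res2 <- logrank_test(c(1, 2), c(1L, 1L), c("B", "A"))
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
  expect_error(logrank_test(c(1, 2), c(0L, 0L), c("A", "B")), "events")
  expect_error(logrank_test(c(1, 2), c(1L, 1L), c("A", "A")), "two")
})

test_that("log-rank agrees with the textbook oracle on random small datasets", {
  set.seed(60)
  for (s in 1:20) {
    n <- sample(6:30, 1L)
    tm <- rexp(n, 0.2)
    ev <- rbinom(n, 1L, 0.7)
    grp <- rbinom(n, 1L, 0.5)
    if (sum(ev) == 0L || length(unique(grp)) < 2L) next
    mine <- logrank_test(tm, ev, grp)
    orc <- oracle_logrank(tm, ev, grp)
    expect_equal(mine$statistic, orc$statistic, tolerance = 1e-10)
    expect_equal(mine$p, orc$p, tolerance = 1e-10)
  }
})

test_that("null log-rank p-values are approximately uniform", {
  set.seed(61)
  pvals <- replicate(500L, {
    tm <- rexp(100L, 0.1)
    ev <- rbinom(100L, 1L, 0.7)
    grp <- rep(c(0L, 1L), 50L)
    logrank_test(tm, ev, grp)$p
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("hazard ratio inverts under label swap and brackets the truth", {
  set.seed(62)
  n <- 500L
  grp <- rep(c(0L, 1L), each = n)
  tm <- c(rexp(n, 0.1), rexp(n, 0.2))
  cens <- rexp(2L * n, 0.02)
  ev <- as.integer(tm <= cens)
  obs <- pmin(tm, cens)
  cmp <- hazard_ratio(obs, ev, grp)
  expect_true(cmp$ci_low <= cmp$hazard_ratio &
                cmp$hazard_ratio <= cmp$ci_high)
  expect_true(cmp$ci_low <= 2 & 2 <= cmp$ci_high)   # true rate ratio
  swapped <- hazard_ratio(obs, ev, 1L - grp)
  expect_equal(swapped$hazard_ratio, 1 / cmp$hazard_ratio, tolerance = 1e-8)
  expect_equal(swapped$ci_low, 1 / cmp$ci_high, tolerance = 1e-8)
  expect_equal(swapped$ci_high, 1 / cmp$ci_low, tolerance = 1e-8)
})

test_that("a group without events is flagged as unbounded", {
  tm <- c(1, 2, 3, 4, 5, 6)
  ev <- c(1L, 1L, 1L, 0L, 0L, 0L)
  grp <- c(0L, 0L, 0L, 1L, 1L, 1L)
  expect_warning(cmp <- hazard_ratio(tm, ev, grp))  # coxph convergence
  expect_true(cmp$unbounded_ci)
})

test_that("accuracy reports use the Wilson interval", {
  rep_all <- accuracy_with_ci(rep(1L, 50L), rep(1L, 50L))
  expect_equal(rep_all$accuracy, 1)
  expect_lte(rep_all$ci_high, 1)
  pred <- c(rep(1L, 90L), rep(0L, 10L))
  truth <- rep(1L, 100L)
  rep90 <- accuracy_with_ci(pred, truth)
  orc <- oracle_wilson(90L, 100L)
  expect_equal(rep90$accuracy, 0.9)
  expect_equal(rep90$ci_low, unname(orc["low"]), tolerance = 1e-12)
  expect_equal(rep90$ci_high, unname(orc["high"]), tolerance = 1e-12)
  expect_output(print(rep90), "0.90 \\(0.83-0.94\\)")
  expect_error(accuracy_with_ci(integer(0), integer(0)), "non-zero")
})

test_that("compare_signatures is deterministic and tolerates absent genes", {
  cfg <- cohort_config(n_samples = 150L, n_genes = 15L,
                       markers = list(marker_spec("er", 0.5, 1:4, 1)),
                       survival_genes = data.frame(gene = 1:3, coef = 0.8),
                       labeled_fraction = 1, seed = 70L)
  coh <- generate_cohort(cfg)
  sig <- gene_signature("sig", sprintf("g%04d", 1:5))
  tab <- compare_signatures(coh$expr, coh$clin, list(sig, sig),
                            outer_folds = 5L, inner_folds = 5L, seed = 3L)
  expect_equal(tab[1L, -1L], tab[2L, -1L], ignore_attr = TRUE)
  sig_extra <- gene_signature("extra", c(sprintf("g%04d", 1:5), "ABSENT"))
  expect_warning(
    tab2 <- compare_signatures(coh$expr, coh$clin, list(sig_extra),
                               outer_folds = 5L, inner_folds = 5L, seed = 3L),
    "ABSENT")
  expect_identical(tab2$n_genes_used, 5L)
  sig_none <- gene_signature("none", c("NOPE1", "NOPE2"))
  expect_error(compare_signatures(coh$expr, coh$clin, list(sig_none),
                                  outer_folds = 5L, inner_folds = 5L,
                                  seed = 3L),
               "no genes")
})
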