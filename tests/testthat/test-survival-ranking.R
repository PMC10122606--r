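test_that("bootstrap_unicox with identity resampling reduces to the plain fit", {
  set.seed(20)
  n <- 80L
  x <- matrix(rnorm(2L * n), 2L, n,
              dimnames = list(c("gA", "gB"), paste0("s", 1:n)))
  tm <- rexp(n, 0.1); ev <- rbinom(n, 1L, 0.7)
  res <- bootstrap_unicox(x, tm, ev, nb = 1L, bootstrap = FALSE)
  for (g in c("gA", "gB")) {
    z <- scale(x[g, ])[, 1L]
    cph <- summary(survival::coxph(survival::Surv(tm, ev) ~ z,
                                   ties = "efron"))
    expect_equal(res$beta_unicox[res$gene == g],
                 unname(cph$coefficients[1L, "coef"]), tolerance = 1e-8)
    expect_equal(res$wald_p[res$gene == g],
                 unname(cph$coefficients[1L, "Pr(>|z|)"]), tolerance = 1e-8)
  }
})

test_that("constant genes are flagged undefined instead of crashing", {
  n <- 40L
  x <- matrix(c(rep(1, n), rnorm(n)), 2L, n, byrow = TRUE,
              dimnames = list(c("flat", "ok"), paste0("s", 1:n)))
  tm <- rexp(n, 0.1); ev <- rbinom(n, 1L, 0.8)
  res <- bootstrap_unicox(x, tm, ev, nb = 3L, seed = 1L)
  expect_true(is.na(res$beta_unicox[res$gene == "flat"]))
  expect_identical(res$n_used[res$gene == "flat"], 0L)
  expect_false(is.na(res$beta_unicox[res$gene == "ok"]))
})

test_that("the median bootstrap coefficient recovers the true hazard effect", {
  cfg <- cohort_config(n_samples = 500L, n_genes = 5L,
                       markers = list(marker_spec("er", 0.5, 1:2, 1)),
                       survival_genes = data.frame(gene = 3L, coef = 0.7),
                       labeled_fraction = 1, seed = 55L)
  coh <- generate_cohort(cfg)
  res <- bootstrap_unicox(coh$expr[3L, , drop = FALSE], coh$clin$time,
                          coh$clin$event, nb = 50L, seed = 8L)
  z <- scale(coh$expr[3L, ])[, 1L]
  full <- summary(survival::coxph(
    survival::Surv(coh$clin$time, coh$clin$event) ~ z, ties = "efron"))
  se <- full$coefficients[1L, "se(coef)"]
  expect_lt(abs(res$beta_unicox - 0.7), 3 * se)
})

test_that("a protective gene gets a negative coefficient", {
  cfg <- cohort_config(n_samples = 400L, n_genes = 5L,
                       markers = list(marker_spec("er", 0.5, 1:2, 1)),
                       survival_genes = data.frame(gene = 4L, coef = -0.8),
                       labeled_fraction = 1, seed = 66L)
  coh <- generate_cohort(cfg)
  res <- bootstrap_unicox(coh$expr[4L, , drop = FALSE], coh$clin$time,
                          coh$clin$event, nb = 20L, seed = 9L)
  expect_lt(res$beta_unicox, 0)
})

test_that("optimal-split log-rank p behaves as a scan minimum", {
  set.seed(30)
  n <- 60L
  x <- rnorm(n)
  tm <- rexp(n, 0.1); ev <- rbinom(n, 1L, 0.8)
  p_opt <- gene_logrank_optimal_p(x, tm, ev, min_group_fraction = 0.1)
  med_grp <- as.integer(x > stats::median(x))
  p_med <- logrank_test(tm, ev, med_grp)$p
  expect_lte(p_opt, p_med)
  # constant expression: no admissible split
  expect_true(is.na(gene_logrank_optimal_p(rep(1, n), tm, ev)))
})

test_that("perfect separation is found by the scan", {
  # low expression: events at t=1..5; high expression: censored at t=50..54
  x <- c(1:5, 11:15)
  tm <- c(1:5, 50:54)
  ev <- c(rep(1L, 5L), rep(0L, 5L))
  p_opt <- gene_logrank_optimal_p(x, tm, ev, min_group_fraction = 0.2)
  orc <- oracle_threshold_scan(x, tm, ev, min_group_fraction = 0.2)
  expect_equal(p_opt, min(orc$p, na.rm = TRUE), tolerance = 1e-12)
  # and it is at least as extreme as the separating split itself
  expect_lte(p_opt, logrank_test(tm, ev, as.integer(x > 5))$p)
})

# Published per-marker survival tables are sorted by the univariate Wald p;
# rebuilding one from shuffled rows must restore that order.
test_that("marker tables sort by univariate Wald p as printed", {
  genes <- c("TBC1D9", "SUSD3", "SLC39A6", "GFRA1", "SOX11", "GATA3")
  wald <- c(0.000067, 0.000080, 0.001527, 0.001640, 0.003205, 0.012805)
  lr <- c(0.00000057, 0.0000088, 0.00006319, 0.00000189, 0.00000027,
          0.00249397)
  beta_u <- c(-0.273, -0.298, -0.225, -0.177, 0.154, -0.154)
  beta_m <- c(-0.0461, -0.0490, -0.0374, -0.0260, 0.0250, -0.0254)
  sd_m <- c(0.0119, 0.0146, 0.0127, 0.0079, 0.0097, 0.0100)
  shuffle <- c(4L, 1L, 6L, 3L, 2L, 5L)
  uni <- data.frame(gene = genes, beta_unicox = beta_u,
                    wald_p = wald)[shuffle, ]
  multi <- data.frame(gene = genes, beta_multicox = beta_m,
                      sd_beta = sd_m)[rev(shuffle), ]
  logrank <- stats::setNames(lr, genes)[shuffle]
  tab <- build_marker_table(uni, multi, logrank)
  expect_identical(tab$gene, genes)
  expect_equal(tab$logrank_p, lr)
  expect_equal(tab$beta_multicox, beta_m)
  expect_error(build_marker_table(uni[-1L, ], multi, logrank), "match")
})

test_that("survival-marker selection filters, unions and pools correctly", {
  tab <- data.frame(gene = c("a", "b", "c"),
                    logrank_p = c(0.001, 0.05, 0.5),
                    beta_unicox = 1:3, wald_p = c(0.01, 0.2, 0.9),
                    beta_multicox = 1:3, sd_beta = 0)
  class(tab) <- c("survival_marker_table", "data.frame")
  sel <- select_survival_markers(tab, p_cut = 0.01)
  expect_identical(sel$genes, "a")
  s1 <- gene_signature("m1", c("a", "b"))
  s2 <- gene_signature("m2", c("b", "c"))
  pooled <- pool_signatures(list(s1, s2), extra_genes = c("x", "y"))
  expect_identical(pooled$genes, c("a", "b", "c", "x", "y"))
  # per-marker survival lists plus the two proliferation genes pool to 34
  sigs <- load_reference_signatures()
  pool34 <- pool_signatures(sigs[c("er", "pr", "her2")],
                            extra_genes = sigs$proliferation$genes)
  expect_length(pool34$genes, 34L)
})
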