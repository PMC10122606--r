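# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: binary clinical
# marker status (ER/PR/HER2-like) drives the mean expression of small gene
# blocks among thousands of noise genes; within-block noise is equicorrelated;
# survival times follow a proportional-hazards model whose log-hazard is
# linear in the standardized expression of a subset of marker genes, with
# independent exponential right-censoring.  Only a configurable fraction of
# samples carries marker labels, mirroring cohorts in which
# immunohistochemistry status is known for a subset of patients.

#' Describe one binary clinical marker and its associated gene block
#'
#' @param name Marker name (e.g. `"er"`).
#' @param prevalence Probability that a sample is marker-positive, in (0,1).
#' @param gene_indices Integer indices (into the cohort's gene list) of the
#'   genes whose expression shifts with marker status.
#' @param effect_sizes Mean expression shift per gene when the marker is
#'   positive; recycled to `length(gene_indices)`.
#' @param within_block_correlation Equicorrelation of the noise among the
#'   block's genes, in `[0, 1)`.
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(name, prevalence, gene_indices, effect_sizes,
                        within_block_correlation = 0.3) {
  if (length(gene_indices) == 0L)
    stop_input("marker '", name, "' has an empty gene block")
  if (prevalence <= 0 || prevalence >= 1)
    stop_input("prevalence must lie in (0,1)")
  if (within_block_correlation < 0 || within_block_correlation >= 1)
    stop_input("within_block_correlation must lie in [0,1)")
  structure(list(name = name, prevalence = prevalence,
                 gene_indices = as.integer(gene_indices),
                 effect_sizes = rep_len(effect_sizes, length(gene_indices)),
                 within_block_correlation = within_block_correlation),
            class = "marker_spec")
}

#' Configure a synthetic cohort
#'
#' Defaults mirror a discovery cohort of 1024 tumor samples of which 380
#' (about 37%) carry marker labels, with three markers at breast-cancer-like
#' prevalences and a handful of survival-informative genes inside the marker
#' blocks.  Tests and examples use reduced sizes.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param markers List of [marker_spec()] objects; blocks must be disjoint
#'   unless `allow_overlap = TRUE`.
#' @param survival_genes Two-column data.frame (`gene` index, `coef` true
#'   log-hazard coefficient per standardized expression unit), or NULL for a
#'   survival-null cohort.
#' @param baseline_hazard Exponential baseline hazard rate.
#' @param censoring_rate Rate of the independent exponential censoring time.
#' @param labeled_fraction Fraction of samples with observed marker status.
#' @param noise_sd Standard deviation of the expression noise.
#' @param seed Integer seed making the cohort fully reproducible.
#' @param allow_overlap Allow marker gene blocks to share genes (effects add).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 1024L,
                          n_genes = 5000L,
                          markers = default_markers(n_genes),
                          survival_genes = NULL,
                          baseline_hazard = 0.05,
                          censoring_rate = 0.10,
                          labeled_fraction = 380 / 1024,
                          noise_sd = 1,
                          seed = 1L,
                          allow_overlap = FALSE) {
  if (n_samples < 2L || n_genes < 1L)
    stop_input("degenerate cohort dimensions")
  if (baseline_hazard <= 0 || censoring_rate <= 0 || noise_sd <= 0)
    stop_input("rates and noise_sd must be positive")
  if (labeled_fraction < 0 || labeled_fraction > 1)
    stop_input("labeled_fraction must lie in [0,1]")
  for (m in markers) {
    if (!inherits(m, "marker_spec")) stop_input("markers must be marker_spec objects")
    if (any(m$gene_indices < 1L | m$gene_indices > n_genes))
      stop_input("marker '", m$name, "' indexes genes outside 1..n_genes")
  }
  all_idx <- unlist(lapply(markers, `[[`, "gene_indices"))
  if (!allow_overlap && anyDuplicated(all_idx))
    stop_input("marker gene blocks overlap; set allow_overlap = TRUE if intended")
  if (!is.null(survival_genes)) {
    survival_genes <- as.data.frame(survival_genes)
    stopifnot(all(c("gene", "coef") %in% names(survival_genes)))
    if (any(survival_genes$gene < 1L | survival_genes$gene > n_genes))
      stop_input("survival gene index outside 1..n_genes")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes), markers = markers,
                 survival_genes = survival_genes,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 labeled_fraction = labeled_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default three-marker layout used by [cohort_config()]
#'
#' ER-like (prevalence 0.70), PR-like (0.60) and HER2-like (0.20) markers,
#' each shifting a block of 10 genes by twice the noise standard deviation.
#'
#' @param n_genes Total gene count (blocks occupy the first 30 indices).
#' @param block_size Genes per marker block.
#' @param effect Expression shift in marker-positive samples.
#' @return List of three [marker_spec()] objects.
#' @export
default_markers <- function(n_genes, block_size = 10L, effect = 2) {
  if (n_genes < 3L * block_size)
    stop_input("n_genes too small for the default three-marker layout")
  list(marker_spec("er", 0.70, seq_len(block_size), effect),
       marker_spec("pr", 0.60, block_size + seq_len(block_size), effect),
       marker_spec("her2", 0.20, 2L * block_size + seq_len(block_size), effect))
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param config A [cohort_config()].
#' @return `list(expr, clin, truth)`: expression matrix, clinical table
#'   (marker status NA outside the labeled subset), and a truth record with
#'   the full marker status, the marker gene sets, the true survival
#'   coefficients and each sample's true risk score (linear predictor).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(p))
  sample_ids <- sprintf("s%05d", seq_len(n))

  values <- matrix(stats::rnorm(p * n, sd = config$noise_sd), nrow = p,
                   dimnames = list(gene_ids, sample_ids))
  status <- list()
  for (m in config$markers) {
    st <- stats::rbinom(n, 1L, m$prevalence)
    status[[m$name]] <- st
    rho <- m$within_block_correlation
    blk <- m$gene_indices
    if (rho > 0) {
      shared <- stats::rnorm(n)
      indiv <- matrix(stats::rnorm(length(blk) * n), nrow = length(blk))
      noise <- sqrt(rho) * matrix(shared, nrow = length(blk), ncol = n,
                                  byrow = TRUE) + sqrt(1 - rho) * indiv
      values[blk, ] <- config$noise_sd * noise
    }
    values[blk, ] <- values[blk, ] +
      outer(m$effect_sizes, st)
  }

  # Proportional-hazards event times by inverse transform from the
  # exponential baseline: T = -log(U) / (h0 * exp(eta)).
  eta <- rep(0, n)
  if (!is.null(config$survival_genes) && nrow(config$survival_genes) > 0L) {
    for (k in seq_len(nrow(config$survival_genes))) {
      g <- config$survival_genes$gene[k]
      x <- values[g, ]
      z <- (x - mean(x)) / stats::sd(x)
      eta <- eta + config$survival_genes$coef[k] * z
    }
  }
  t_event <- -log(stats::runif(n)) / (config$baseline_hazard * exp(eta))
  t_cens <- -log(stats::runif(n)) / config$censoring_rate
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  labeled <- sort(sample.int(n, round(config$labeled_fraction * n)))
  clin_df <- data.frame(sample_id = sample_ids, time = time, event = event,
                        stringsAsFactors = FALSE)
  for (nm in names(status)) {
    col <- rep(NA_integer_, n)
    col[labeled] <- status[[nm]][labeled]
    clin_df[[nm]] <- col
  }
  clin <- clinical_table(clin_df, markers = names(status))

  truth <- list(
    marker_status = as.data.frame(c(list(sample_id = sample_ids), status),
                                  stringsAsFactors = FALSE),
    marker_genes = lapply(config$markers, function(m) gene_ids[m$gene_indices]),
    survival_genes = if (is.null(config$survival_genes)) NULL else
      data.frame(gene = gene_ids[config$survival_genes$gene],
                 coef = config$survival_genes$coef,
                 stringsAsFactors = FALSE),
    risk_score = stats::setNames(eta, sample_ids),
    labeled_samples = sample_ids[labeled])
  names(truth$marker_genes) <- vapply(config$markers, `[[`, character(1), "name")

  list(expr = expression_matrix(values), clin = clin, truth = truth)
}

#' Split a cohort into disjoint training and test parts
#'
#' @param expr,clin,truth Cohort pieces as returned by [generate_cohort()]
#'   (`truth` may be NULL).
#' @param train_fraction Fraction of samples assigned to training, in (0,1).
#' @param seed Integer seed for the random split.
#' @return `list(train = list(expr, clin, truth), test = list(...))`.
#' @export
split_cohort <- function(expr, clin, truth = NULL, train_fraction = 0.5,
                         seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_input("train_fraction must lie strictly in (0,1)")
  n <- ncol(expr)
  n_train <- round(train_fraction * n)
  if (n_train < 1L || n_train >= n)
    stop_input("train_fraction yields an empty split")
  set.seed(seed)
  tr <- sort(sample.int(n, n_train))
  take <- function(idx) {
    ids <- colnames(expr)[idx]
    tru <- if (is.null(truth)) NULL else {
      t2 <- truth
      t2$marker_status <- truth$marker_status[
        truth$marker_status$sample_id %in% ids, , drop = FALSE]
      t2$risk_score <- truth$risk_score[ids]
      t2$labeled_samples <- intersect(truth$labeled_samples, ids)
      t2
    }
    al <- align_cohort(expr[, idx, drop = FALSE],
                       clin[clin$sample_id %in% ids, , drop = FALSE])
    list(expr = al$expr, clin = al$clin, truth = tru)
  }
  list(train = take(tr), test = take(setdiff(seq_len(n), tr)))
}
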