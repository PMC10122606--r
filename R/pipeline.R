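# End-to-end pipeline: cohort input (files or simulation) -> SAM prefilter
# -> per-marker stability selection -> survival ranking -> pooled signature
# -> risk model -> validation stratification and signature comparison.
#
# One master seed is expanded into independent per-stage seeds (hash of the
# stage label), so adding a stage never perturbs the random stream of
# earlier ones; re-running a config reproduces every output byte for byte.

as_cohort_config <- function(x) {
  if (inherits(x, "cohort_config")) return(x)
  if (!is.null(x$markers))
    x$markers <- lapply(x$markers, function(m) {
      if (inherits(m, "marker_spec")) m else do.call(marker_spec, m)
    })
  if (!is.null(x$survival_genes))
    x$survival_genes <- as.data.frame(lapply(as.data.frame(x$survival_genes),
                                             unlist))
  do.call(cohort_config, x)
}

load_pipeline_cohort <- function(spec_part, master_seed, label) {
  if (!is.null(spec_part$simulate)) {
    cfg <- spec_part$simulate
    if (!inherits(cfg, "cohort_config")) {
      cfg$seed <- cfg$seed %||% derive_seed(master_seed, paste0("simulate/", label))
      cfg <- as_cohort_config(cfg)
    }
    generate_cohort(cfg)
  } else if (!is.null(spec_part$expr) && !is.null(spec_part$clin)) {
    al <- align_cohort(read_expression(spec_part$expr),
                       read_clinical(spec_part$clin))
    list(expr = al$expr, clin = al$clin, truth = NULL)
  } else {
    stop_input("cohort spec '", label,
               "' needs either $simulate or $expr + $clin")
  }
}

#' Run the full marker-discovery and risk-stratification pipeline
#'
#' Stages: (1) load or simulate the training cohort (and optionally a
#' validation cohort); (2) SAM prefilter on the labeled training samples,
#' per marker; (3) bagged elastic-net stability selection per marker;
#' (4) survival ranking of the stable genes (bootstrapped univariate Cox,
#' optimal-split log-rank, penalized multivariate Cox); (5) pooling of the
#' per-marker survival markers plus configured extra genes into one
#' signature; (6) risk-model fit with optimal threshold; (7) stratification
#' of the validation cohort and signature comparison.  All result tables,
#' the fitted model and a manifest with per-file checksums are written to
#' the output directory.
#'
#' @param config Named list or path to a YAML file.  Required: `seed`,
#'   `training` (either `simulate:` a cohort configuration, or `expr:` +
#'   `clin:` file paths).  Optional: `validation` (same form), `markers`
#'   (default: every marker column), `sam` (`enabled`, `top_k`,
#'   `n_permutations`), `nb`, `alpha`, `record_auc` (log per-member
#'   held-out AUC, off by default), `stability_threshold`,
#'   `unicox_nb`, `survival_p_cut`, `survival_statistic`, `extra_genes`,
#'   `outer_folds`, `inner_folds`, `min_group_fraction`, `compare`
#'   (named list of extra gene vectors for the comparison table).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-stage results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop_input("config$seed is mandatory")
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE, fileEncoding = "UTF-8")
    written <<- c(written, path)
    path
  }

  nb <- config$nb %||% 100L
  alpha <- config$alpha %||% 0.8
  stab_thr <- config$stability_threshold %||% 0.10
  unicox_nb <- config$unicox_nb %||% nb
  p_cut <- config$survival_p_cut %||% 0.05
  p_stat <- config$survival_statistic %||% "logrank_p"
  outer_folds <- config$outer_folds %||% 10L
  inner_folds <- config$inner_folds %||% 10L
  mgf <- config$min_group_fraction %||% 0.1
  sam_cfg <- utils::modifyList(list(enabled = TRUE, top_k = 2000L,
                                    n_permutations = 100L),
                               config$sam %||% list())

  message("stage: load training cohort")
  train <- load_pipeline_cohort(config$training, seed, "training")
  validation <- if (!is.null(config$validation)) {
    message("stage: load validation cohort")
    load_pipeline_cohort(config$validation, seed, "validation")
  }
  markers <- config$markers %||% clinical_markers(train$clin)
  if (length(markers) == 0L) stop_input("no marker columns to analyze")

  per_marker <- list()
  selected <- list()
  for (m in markers) {
    message("stage: marker selection [", m, "]")
    labels <- train$clin[[m]]
    expr_m <- train$expr
    if (isTRUE(sam_cfg$enabled)) {
      sam <- sam_prefilter(expr_m, labels,
                           n_permutations = sam_cfg$n_permutations,
                           top_k = sam_cfg$top_k,
                           seed = derive_seed(seed, paste0("sam/", m)))
      expr_m <- expr_m[sam$selected, , drop = FALSE]
    }
    ens <- fit_marker_ensemble(expr_m, labels, nb = nb, alpha = alpha,
                               record_auc = isTRUE(config$record_auc),
                               seed = derive_seed(seed, paste0("ensemble/", m)),
                               marker = m)
    stab <- stability_table(ens)
    emit(stab, paste0("stability_", m, ".tsv"))
    emit(data.frame(member = seq_along(ens$members),
                    lambda = sprintf("%.8g", vapply(ens$members, `[[`,
                                                    numeric(1), "lambda")),
                    auc = vapply(ens$members, `[[`, numeric(1), "auc"),
                    n_selected = vapply(ens$members,
                                        function(mm) length(mm$genes),
                                        integer(1)),
                    stringsAsFactors = FALSE),
         paste0("ensemble_log_", m, ".tsv"))
    sig <- select_stable_genes(stab, threshold = stab_thr, name = m)
    writeLines(sig$genes, file.path(out_dir, paste0("stable_genes_", m, ".txt")))
    written <- c(written, file.path(out_dir, paste0("stable_genes_", m, ".txt")))

    surv_sig <- NULL
    surv_tab <- NULL
    if (length(sig$genes) >= 1L) {
      message("stage: survival ranking [", m, "] (", length(sig$genes), " genes)")
      sub <- train$expr[sig$genes, , drop = FALSE]
      uni <- bootstrap_unicox(sub, train$clin$time, train$clin$event,
                              nb = unicox_nb,
                              seed = derive_seed(seed, paste0("unicox/", m)))
      lr <- vapply(sig$genes, function(g) {
        gene_logrank_optimal_p(sub[g, ], train$clin$time, train$clin$event,
                               min_group_fraction = mgf)
      }, numeric(1))
      if (length(sig$genes) >= 2L && sum(train$clin$event) >= 2L) {
        psc <- penalized_separable_cox(sub, train$clin$time, train$clin$event,
                                       outer_folds = outer_folds,
                                       inner_folds = inner_folds,
                                       seed = derive_seed(seed, paste0("multicox/", m)))
        mc <- psc$multicox
      } else {
        mc <- data.frame(gene = sig$genes, beta_multicox = NA_real_,
                         sd_beta = NA_real_, stringsAsFactors = FALSE)
      }
      surv_tab <- build_marker_table(uni, mc, lr)
      emit(as.data.frame(surv_tab), paste0("survival_table_", m, ".tsv"))
      surv_sig <- select_survival_markers(surv_tab, p_cut = p_cut,
                                          statistic = p_stat, name = m)
    }
    per_marker[[m]] <- list(ensemble = ens, stability = stab,
                            stable = sig, survival_table = surv_tab,
                            survival_markers = surv_sig)
    if (!is.null(surv_sig)) selected[[m]] <- surv_sig
  }

  message("stage: pool signature")
  pooled <- pool_signatures(selected,
                            extra_genes = intersect(config$extra_genes %||% character(0),
                                                    rownames(train$expr)),
                            name = "pooled")
  if (length(pooled$genes) == 0L)
    stop_input("pooled signature is empty; relax survival_p_cut or stability_threshold")
  writeLines(pooled$genes, file.path(out_dir, "pooled_signature.txt"))
  written <- c(written, file.path(out_dir, "pooled_signature.txt"))

  message("stage: risk model (", length(pooled$genes), " genes)")
  model <- fit_risk_model(train$expr, train$clin, pooled,
                          outer_folds = outer_folds, inner_folds = inner_folds,
                          seed = derive_seed(seed, "riskmodel"),
                          min_group_fraction = mgf)
  write_risk_model(model, file.path(out_dir, "risk_model.json"))
  written <- c(written, file.path(out_dir, "risk_model.json"))
  train_groups <- stratify(model$scan, model$risk_scores)
  emit(data.frame(sample_id = train$clin$sample_id,
                  risk_score = sprintf("%.10g", model$risk_scores),
                  risk_group = train_groups, stringsAsFactors = FALSE),
       "training_stratification.tsv")

  validation_cmp <- NULL
  if (!is.null(validation)) {
    message("stage: validation")
    groups <- classify_new(model, validation$expr)
    emit(data.frame(sample_id = validation$clin$sample_id,
                    risk_score = sprintf("%.10g",
                                         risk_scores(model, validation$expr)),
                    risk_group = groups, stringsAsFactors = FALSE),
         "validation_stratification.tsv")
    sigs <- c(list(pooled),
              lapply(names(config$compare %||% list()), function(nm) {
                gene_signature(nm, unlist(config$compare[[nm]]))
              }))
    validation_cmp <- compare_signatures(validation$expr, validation$clin,
                                         sigs, outer_folds = outer_folds,
                                         inner_folds = inner_folds,
                                         seed = derive_seed(seed, "compare"),
                                         min_group_fraction = mgf)
    emit(validation_cmp, "signature_comparison.tsv")
  }

  manifest <- list(format = "survmarkers/manifest", version = 1L,
                   package_version = as.character(utils::packageVersion("survmarkers")),
                   seed = seed,
                   markers = markers,
                   parameters = list(nb = nb, alpha = alpha,
                                     stability_threshold = stab_thr,
                                     unicox_nb = unicox_nb,
                                     survival_p_cut = p_cut,
                                     survival_statistic = p_stat,
                                     outer_folds = outer_folds,
                                     inner_folds = inner_folds,
                                     min_group_fraction = mgf,
                                     sam = sam_cfg),
                   outputs = as.list(tools::md5sum(sort(written))))
  names(manifest$outputs) <- basename(sort(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(train = train, validation = validation,
                 per_marker = per_marker, pooled_signature = pooled,
                 model = model, training_groups = train_groups,
                 validation_comparison = validation_cmp,
                 manifest = manifest, out_dir = out_dir))
}
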