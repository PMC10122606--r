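# Core domain types: expression matrix, clinical table, gene signature, and
# the tab-delimited readers/writers shared by every analysis stage.
#
# Conventions: UTF-8, tab-delimited, '.' decimal separator, no quoting,
# mandatory header row.  Missing marker status is an empty cell, never 0,
# so unlabeled samples stay distinguishable from marker-negative ones.

#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix of log-scale expression
#' values with genes as rows and samples as columns, both uniquely named.
#'
#' @param values Numeric matrix (genes x samples).
#' @param gene_ids,sample_ids Optional character vectors; if omitted the
#'   dimnames of `values` are used.
#' @return The validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("expression values must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop_input("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop_input("identifier lengths do not match matrix dimensions")
  if (anyNA(gene_ids) || any(!nzchar(gene_ids)))
    stop_input("missing or empty gene identifiers")
  if (anyNA(sample_ids) || any(!nzchar(sample_ids)))
    stop_input("missing or empty sample identifiers")
  if (anyDuplicated(gene_ids))
    stop_input("duplicate gene identifiers: ",
               paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_input("duplicate sample identifiers: ",
               paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop_input("expression values must be finite")
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Construct a validated clinical table
#'
#' A clinical table is a data.frame with columns `sample_id`, `time`
#' (positive follow-up time in consistent but arbitrary units), `event`
#' (1 = event observed, 0 = censored) and zero or more binary marker-status
#' columns (e.g. `er`, `pr`, `her2`) in which `NA` means the sample is
#' unlabeled for that marker.
#'
#' @param df data.frame with at least `sample_id`, `time`, `event`.
#' @param markers Character vector naming the marker columns; defaults to
#'   every column beyond the three required ones.
#' @return The validated data.frame with a `markers` attribute.
#' @export
clinical_table <- function(df, markers = NULL) {
  req <- c("sample_id", "time", "event")
  if (!all(req %in% names(df)))
    stop_input("clinical table needs columns: ", paste(req, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_input("duplicate sample identifiers in clinical table")
  if (anyNA(df$time) || any(!is.finite(df$time)) || any(df$time <= 0))
    stop_input("survival time must be finite and > 0")
  if (anyNA(df$event) || !all(df$event %in% c(0, 1)))
    stop_input("event indicator must be 0 (censored) or 1 (event)")
  if (is.null(markers)) markers <- setdiff(names(df), req)
  for (m in markers) {
    v <- df[[m]]
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop_input("marker column '", m, "' must be 0, 1 or missing")
    df[[m]] <- as.integer(v)
  }
  rownames(df) <- NULL
  attr(df, "markers") <- markers
  df
}

#' Marker columns of a clinical table
#'
#' Falls back to every column beyond `sample_id`/`time`/`event` when the
#' `markers` attribute has been dropped by data.frame subsetting.
#'
#' @param clin A clinical table.
#' @return Character vector of marker column names.
#' @export
clinical_markers <- function(clin) {
  attr(clin, "markers") %||% setdiff(names(clin), c("sample_id", "time", "event"))
}

#' Read an expression matrix from a tab-delimited file
#'
#' Expects the first row to hold sample identifiers, the first column gene
#' identifiers, and a numeric body.
#'
#' @param path File path.
#' @return A validated expression matrix.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL)
  if (ncol(raw) < 2L) stop_input("expression file has no sample columns")
  gene_ids <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(values) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_input(sprintf(
      "non-numeric expression value '%s' at gene '%s', sample '%s'",
      body[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
      colnames(body)[bad[1L, 2L]]))
  }
  expression_matrix(values, gene_ids, colnames(body))
}

#' Write an expression matrix to a tab-delimited file
#'
#' Values are written with 17 significant digits so that a read/write
#' round-trip reproduces the matrix exactly.
#'
#' @param expr Expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- expression_matrix(expr)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], sprintf("%.17g", expr[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a clinical table from a tab-delimited file
#'
#' Expects header columns `sample_id`, `time`, `event` and optionally
#' marker columns (any further columns are treated as binary markers);
#' empty marker cells mean missing status.
#'
#' @param path File path.
#' @return A validated clinical table (sample order preserved).
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, na.strings = c("", "NA"))
  clinical_table(df)
}

#' Write a clinical table to a tab-delimited file
#' @param clin Clinical table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  out <- as.data.frame(clin)
  out$time <- sprintf("%.17g", out$time)
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Align an expression matrix and a clinical table on shared samples
#'
#' Restricts both inputs to the intersection of their sample identifiers, in
#' a common order, and reports how many samples were dropped from each side.
#'
#' @param expr Expression matrix.
#' @param clin Clinical table.
#' @return `list(expr = , clin = )` restricted to shared samples.
#' @export
align_cohort <- function(expr, clin) {
  shared <- intersect(colnames(expr), clin$sample_id)
  if (length(shared) == 0L)
    stop_input("no shared samples between expression matrix and clinical table")
  drop_e <- ncol(expr) - length(shared)
  drop_c <- nrow(clin) - length(shared)
  if (drop_e > 0L || drop_c > 0L)
    message(sprintf("align_cohort: dropped %d expression-only and %d clinical-only samples",
                    drop_e, drop_c))
  markers <- clinical_markers(clin)
  clin2 <- clin[match(shared, clin$sample_id), , drop = FALSE]
  list(expr = expr[, shared, drop = FALSE],
       clin = clinical_table(clin2, markers = markers))
}

#' Construct a gene signature
#'
#' @param name Signature name.
#' @param genes Ordered character vector of unique gene symbols.
#' @param alias Optional character vector of synonyms (NA where none).
#' @param allow_empty Permit a zero-gene signature (used by selection steps
#'   that may legitimately select nothing, with a warning upstream).
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, genes, alias = NULL, allow_empty = FALSE) {
  genes <- as.character(genes)
  if (length(genes) == 0L && !allow_empty)
    stop_input("gene signature must be non-empty")
  if (anyDuplicated(genes)) stop_input("duplicate genes in signature '", name, "'")
  if (!is.null(alias)) stopifnot(length(alias) == length(genes))
  structure(list(name = name, genes = genes,
                 alias = alias %||% rep(NA_character_, length(genes))),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes\n", x$name, length(x$genes)))
  cat(" ", paste(utils::head(x$genes, 10L), collapse = ", "),
      if (length(x$genes) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Read a gene-list file
#'
#' One gene symbol per line, with an optional second tab-separated column of
#' synonyms (aliases used on older array platforms).
#'
#' @param path File path.
#' @param name Signature name (defaults to the file stem).
#' @return A [gene_signature()].
#' @export
read_gene_list <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop_input("gene-list file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[[`, character(1), 1L)
  alias <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                  character(1))
  gene_signature(name, trimws(genes), trimws(alias))
}

#' Load the reference gene signatures shipped with the package
#'
#' Returns the per-marker survival-gene lists (ER, PR, HER2), the two
#' proliferation indicator genes (AURKA, MKI67), the pooled 34-gene
#' signature, and the gene lists of the two commercial prognostic platforms
#' (Oncotype, 16 genes; PAM50 with the kinetochore gene KNTC2 excluded,
#' 49 genes).  Symbols printed under older aliases (C6orf97, CRKRS,
#' C17orf37) are stored under their current names CCDC170, CDK12 and MIEN1
#' with the alias retained.
#'
#' @param dir Directory of gene-list files; defaults to the package fixtures.
#' @return Named list of [gene_signature()] objects: `er`, `pr`, `her2`,
#'   `proliferation`, `signature34`, `oncotype`, `pam50`.
#' @export
load_reference_signatures <- function(dir = system.file("extdata", "signatures",
                                                        package = "survmarkers")) {
  files <- c(er = "er.txt", pr = "pr.txt", her2 = "her2.txt",
             proliferation = "proliferation.txt",
             signature34 = "signature34.txt",
             oncotype = "oncotype.txt", pam50 = "pam50.txt")
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing) > 0L)
    stop_input("missing signature fixture(s): ", paste(missing, collapse = ", "))
  out <- lapply(names(files), function(nm) {
    read_gene_list(file.path(dir, files[[nm]]), name = nm)
  })
  names(out) <- names(files)
  out
}
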