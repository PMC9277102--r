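#' Canonical mtDNA protein-coding genes
#'
#' The 13 protein-coding genes of the human mitochondrial genome, in genomic
#' order, named without the `MT-` prefix.
#'
#' @return Character vector of 13 gene symbols.
#' @export
mtdna_genes <- function() {
  c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3",
    "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB")
}

#' Analysis gene set: drop ND5 and ND6
#'
#' Non-strand-specific, poly(A)-selected RNA-seq cannot reliably separate
#' `ND5` from `ND6` (the genes overlap on opposite strands and `ND6`
#' transcripts are not polyadenylated), so both are removed from the analysis
#' set. The size of the returned set is the Bonferroni family size used by
#' the association analyses (11 genes for the canonical input).
#'
#' @param genes Character vector of mtDNA gene ids; `MT-` prefixes are
#'   tolerated. Defaults to the 13 canonical protein-coding genes.
#' @return `genes` minus ND5/ND6, order preserved. Warns if canonical genes
#'   are absent from the input.
#' @examples
#' length(mtdna_gene_set()) # 11
#' @export
mtdna_gene_set <- function(genes = mtdna_genes()) {
  genes <- as.character(genes)
  core <- sub("^MT-", "", genes)
  missing <- setdiff(mtdna_genes(), core)
  if (length(missing) > 0L) {
    warning("input lacks canonical mtDNA gene(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  genes[!core %in% c("ND5", "ND6")]
}

#' An expression table container
#'
#' A light container for a genes x samples TPM matrix tagged with a tissue
#' label. Entries must be nonnegative and ids unique.
#'
#' @param tpm Numeric matrix (genes in rows, samples in columns) with row and
#'   column names.
#' @param tissue Tissue label.
#' @return Object of class `expression_table` (a list with elements `tissue`
#'   and `tpm`).
#' @export
expression_table <- function(tpm, tissue) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    stop("tpm must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop("tpm must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(tpm)) || anyDuplicated(colnames(tpm))) {
    stop("gene and sample ids must be unique", call. = FALSE)
  }
  if (any(tpm < 0, na.rm = TRUE)) {
    bad <- which(tpm < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative TPM at gene '%s', sample '%s'",
                 rownames(tpm)[bad[1L]], colnames(tpm)[bad[2L]]),
         call. = FALSE)
  }
  structure(list(tissue = as.character(tissue), tpm = tpm),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> tissue '%s': %d genes x %d samples (TPM)\n",
              x$tissue, nrow(x$tpm), ncol(x$tpm)))
  invisible(x)
}

#' Covariate-adjusted gene expression
#'
#' Fits, independently for each gene, an ordinary least-squares regression of
#' TPM on donor age (years) and tissue ischemic time (minutes), with an
#' intercept, and returns the residuals ("adjusted gene expression"). Samples
#' with a missing covariate are dropped and listed; a covariate constant
#' across the retained samples is dropped from the design with a warning;
#' all-zero genes are skipped with a warning.
#'
#' @param table An [expression_table()].
#' @param covariates data.frame with columns `sample_id` and the covariate
#'   columns (default `age` and `ischemic_time_min`).
#' @param covariate_cols Character vector naming the covariate columns to
#'   adjust for.
#' @return Object of class `adjusted_expression`: list with `tissue`,
#'   `residuals` (genes x retained-samples matrix, columns in input sample
#'   order), `n_used`, `dropped_samples`, `skipped_genes`,
#'   `covariates_used`.
#' @export
adjust_expression <- function(table, covariates,
                              covariate_cols = c("age", "ischemic_time_min")) {
  stopifnot(inherits(table, "expression_table"), is.data.frame(covariates))
  if (!"sample_id" %in% names(covariates)) {
    stop("covariates need a sample_id column", call. = FALSE)
  }
  miss_cols <- setdiff(covariate_cols, names(covariates))
  if (length(miss_cols) > 0L) {
    stop("missing covariate column(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  samples <- colnames(table$tpm)
  idx <- match(samples, covariates$sample_id)
  if (anyNA(idx)) {
    stop("no covariates for sample(s): ",
         paste(utils::head(samples[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  X_all <- as.matrix(covariates[idx, covariate_cols, drop = FALSE])
  storage.mode(X_all) <- "double"
  complete <- stats::complete.cases(X_all)
  dropped <- samples[!complete]
  keep <- samples[complete]
  if (length(keep) < 3L) {
    stop("need >= 3 samples with complete covariates, have ", length(keep),
         call. = FALSE)
  }
  X <- X_all[complete, , drop = FALSE]
  constant <- apply(X, 2L, function(v) diff(range(v)) == 0)
  if (any(constant)) {
    warning("covariate(s) constant across samples dropped from the design: ",
            paste(covariate_cols[constant], collapse = ", "), call. = FALSE)
    X <- X[, !constant, drop = FALSE]
  }
  used <- colnames(X)
  Y <- table$tpm[, keep, drop = FALSE]
  all_zero <- rowSums(Y != 0) == 0L
  if (any(all_zero)) {
    warning("all-zero gene(s) skipped: ",
            paste(rownames(Y)[all_zero], collapse = ", "), call. = FALSE)
    Y <- Y[!all_zero, , drop = FALSE]
  }
  design <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(design, t(Y))
  res <- t(as.matrix(fit$residuals))
  dimnames(res) <- dimnames(Y)
  structure(list(
    tissue          = table$tissue,
    residuals       = res,
    n_used          = length(keep),
    dropped_samples = dropped,
    skipped_genes   = rownames(table$tpm)[all_zero],
    covariates_used = used
  ), class = "adjusted_expression")
}

#' @export
print.adjusted_expression <- function(x, ...) {
  cat(sprintf(
    "<adjusted_expression> tissue '%s': %d genes x %d samples; adjusted for %s\n",
    x$tissue, nrow(x$residuals), x$n_used,
    paste(x$covariates_used, collapse = " + ")))
  if (length(x$dropped_samples) > 0L) {
    cat("  dropped (missing covariates):",
        length(x$dropped_samples), "sample(s)\n")
  }
  invisible(x)
}

#' Pearson screen of a candidate covariate
#'
#' Pearson correlation between a per-sample covariate and per-sample
#' expression, with the usual t-distributed two-sided p-value. Used to decide
#' whether a candidate covariate (age, ischemic time, mtDNA copy number, ...)
#' enters the adjustment design.
#'
#' @param values Numeric covariate vector.
#' @param expression Numeric expression vector, same length.
#' @return List with `r`, `p` and `n` (complete pairs). If either vector has
#'   zero variance, `r` and `p` are `NA`.
#' @export
screen_covariate <- function(values, expression) {
  ok <- stats::complete.cases(values, expression)
  x <- as.numeric(values[ok])
  y <- as.numeric(expression[ok])
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    message("zero variance in covariate screen; correlation undefined.")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Mood's median test
#'
#' Dichotomizes the pooled values at the pooled median (strictly above vs not
#' above; values equal to the median count as "not above"), forms the 2x2
#' group-by-side contingency table and computes the Pearson chi-square
#' statistic with 1 degree of freedom, without continuity correction. Used to
#' check for expression differences between sexes. If the table is degenerate
#' (e.g. all pooled values identical) the statistic is 0 and p = 1.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List with `statistic`, `p`, and the 2x2 `table`.
#' @export
mood_median_test <- function(group_a, group_b) {
  a <- as.numeric(group_a[!is.na(group_a)])
  b <- as.numeric(group_b[!is.na(group_b)])
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (length(a) + length(b) < 4L) {
    stop("need pooled n >= 4", call. = FALSE)
  }
  if (min(length(a), length(b)) < 2L) {
    message("a group has fewer than 2 observations; ",
            "Mood's test has very low power here.")
  }
  m <- stats::median(c(a, b))
  tab <- rbind(
    group_a = c(above = sum(a > m), not_above = sum(a <= m)),
    group_b = c(above = sum(b > m), not_above = sum(b <= m))
  )
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  denom <- prod(rs) * prod(cs)
  if (denom == 0) {
    return(list(statistic = 0, p = 1, table = tab))
  }
  stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 / denom
  list(statistic = unname(stat),
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       table = tab)
}

#' Merge bicistronic mtDNA transcript pairs
#'
#' The mitochondrial genome encodes ATP8/ATP6 and ND4L/ND4 on shared
#' bicistronic transcripts. As an approximation of re-quantifying the
#' bicistronic units from raw reads, this optionally replaces each pair of
#' rows by a single row holding the TPM sum. Pairs with a missing member are
#' skipped with a warning. Off by default in the pipeline.
#'
#' @param table An [expression_table()].
#' @param pairs List of length-2 character vectors naming the pairs to merge.
#' @return A new [expression_table()] with each complete pair collapsed into
#'   one row named `"A/B"`.
#' @export
merge_bicistronic <- function(table,
                              pairs = list(c("ATP8", "ATP6"),
                                           c("ND4L", "ND4"))) {
  stopifnot(inherits(table, "expression_table"))
  tpm <- table$tpm
  core <- sub("^MT-", "", rownames(tpm))
  for (pair in pairs) {
    hit <- match(pair, core)
    if (anyNA(hit)) {
      warning("bicistronic pair ", paste(pair, collapse = "/"),
              " not fully present; skipped", call. = FALSE)
      next
    }
    merged <- tpm[hit[1L], , drop = FALSE] + tpm[hit[2L], , drop = FALSE]
    rownames(merged) <- paste(pair, collapse = "/")
    tpm <- rbind(tpm[-hit, , drop = FALSE], merged)
    core <- sub("^MT-", "", rownames(tpm))
  }
  expression_table(tpm, table$tissue)
}
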