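#' Validate a local-ancestry segment table
#'
#' Internal checks shared by the enrichment operations: required columns, 0-based
#' half-open coordinates with start < end, and per sample/haplotype/chromosome
#' non-overlapping sorted segments.
#' @noRd
validate_segments <- function(segments) {
  need <- c("sample_id", "haplotype", "chrom", "start", "end", "ancestry")
  segments <- as.data.table(segments)
  if (!all(need %in% names(segments))) {
    stop("segments need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(segments$start >= segments$end)) {
    stop("segments must have start < end (0-based half-open)", call. = FALSE)
  }
  if (!all(segments$ancestry %in% c("african", "european"))) {
    stop("segment ancestry must be 'african' or 'european'", call. = FALSE)
  }
  setorder(segments, sample_id, haplotype, chrom, start)
  overlap <- segments[, any(utils::head(end, -1L) > utils::tail(start, -1L)),
                      by = .(sample_id, haplotype, chrom)]$V1
  if (any(overlap)) {
    stop("overlapping segments within a sample/haplotype/chromosome",
         call. = FALSE)
  }
  segments
}

#' Chromosome spans implied by a segment table
#' @noRd
segment_chrom_spans <- function(segments) {
  segments[, .(chrom_start = min(start), chrom_end = max(end)), by = chrom]
}

#' Mean local African ancestry in 5-Mb windows around genes
#'
#' For each gene, takes a window of `window_mb` megabases centered on the gene
#' midpoint (clamped to the chromosome bounds implied by the segments) and
#' computes, per sample, the length-weighted African dosage over both
#' haplotypes of all segments overlapping the window; the gene's value is the
#' mean over samples. Genes whose chromosome has no overlapping segments get
#' `NA` and are flagged.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `category` (0-based half-open coordinates).
#' @param segments Local-ancestry segment table (see [read_msp()] or
#'   [simulate_local_tracts()]).
#' @param window_mb Window size in megabases (default 5).
#' @return data.frame with columns `gene_id`, `category`, `african`
#'   (mean African fraction in \eqn{[0,1]}, `NA` if no overlap), one row per
#'   gene in input order. Flagged genes are listed in the `no_overlap`
#'   attribute.
#' @export
gene_window_ancestry <- function(genes, segments, window_mb = 5) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "category") %in%
                  names(genes)))
  if (window_mb <= 0) stop("window_mb must be positive", call. = FALSE)
  seg <- validate_segments(segments)
  spans <- segment_chrom_spans(seg)
  half <- window_mb * 1e6 / 2
  g <- as.data.table(genes)[, .(gene_id, chrom, start, end, category)]
  g <- merge(g, spans, by = "chrom", all.x = TRUE, sort = FALSE)
  mid <- (g$start + g$end) / 2
  g[, w_start := pmax(chrom_start, mid - half)]
  g[, w_end := pmin(chrom_end, mid + half)]
  known <- !is.na(g$chrom_start)
  vals <- rep(NA_real_, nrow(g))
  if (any(known)) {
    gw <- g[known, .(gene_id, chrom, w_start, w_end)]
    setkey(seg, chrom, start, end)
    hits <- foverlaps(gw, seg,
                      by.x = c("chrom", "w_start", "w_end"),
                      by.y = c("chrom", "start", "end"), nomatch = NULL)
    hits[, overlap := pmin(end, w_end) - pmax(start, w_start)]
    hits <- hits[overlap > 0]
    agg <- hits[, .(african = sum(overlap * (ancestry == "african")) /
                      sum(overlap)), by = gene_id]
    vals[match(agg$gene_id, g$gene_id)] <- agg$african
  }
  out <- data.frame(gene_id = g$gene_id, category = g$category,
                    african = vals, stringsAsFactors = FALSE)
  out <- out[match(genes$gene_id, out$gene_id), ]
  rownames(out) <- NULL
  no_overlap <- out$gene_id[is.na(out$african)]
  if (length(no_overlap) > 0L) {
    message(length(no_overlap),
            " gene(s) with no overlapping local-ancestry segments flagged.")
  }
  attr(out, "no_overlap") <- no_overlap
  out
}

#' Global African ancestry recomputed from local-ancestry segments
#'
#' Length-weighted African dosage across all chromosomes and both haplotypes
#' of each sample. Serves as the QC counterpart to ADMIXTURE-style global
#' estimates: the two should be highly correlated. Errors if the segments of
#' any sample/haplotype leave gaps in the chromosome tiling.
#'
#' @param segments Local-ancestry segment table.
#' @return data.frame with columns `sample_id`, `african`.
#' @export
global_from_local <- function(segments) {
  seg <- validate_segments(segments)
  spans <- segment_chrom_spans(seg)
  gaps <- seg[spans, on = "chrom"][,
    {
      edges <- c(chrom_start[1L], utils::head(end, -1L), chrom_end[1L])
      .(n_gaps = sum(c(start, end[.N]) != edges))
    },
    by = .(sample_id, haplotype, chrom)]
  if (any(gaps$n_gaps > 0L)) {
    bad <- gaps[n_gaps > 0L]
    stop("local-ancestry segments do not tile the chromosome for ",
         nrow(bad), " sample/haplotype/chromosome combination(s), e.g. ",
         bad$sample_id[1L], " haplotype ", bad$haplotype[1L], " ",
         bad$chrom[1L], call. = FALSE)
  }
  out <- seg[, .(african = sum((end - start) * (ancestry == "african")) /
                   sum(end - start)), by = sample_id]
  as.data.frame(out)
}

#' Unweighted block bootstrap of category-mean local ancestry
#'
#' For each gene category, draws `n_resample` genes with replacement
#' (167 by default, matching the smallest category) and records the deviation
#' of their mean window ancestry from the global ancestry mean, repeated
#' `n_replicates` times. The gene (its 5-Mb window averaged over samples) is
#' the resampling block; genes are resampled unweighted, regardless of
#' length. The empirical 95% CI is the 2.5/97.5 percentile of the replicate
#' deviations.
#'
#' @param gene_values Numeric vector of per-gene mean African fractions
#'   (`NA`s dropped per category), e.g. the `african` column of
#'   [gene_window_ancestry()].
#' @param categories Character vector of category labels (`high_mt`,
#'   `low_mt`, `non_mt`), parallel to `gene_values`. Every category must have
#'   at least one non-`NA` gene.
#' @param global_mean Global African ancestry baseline (cohort mean).
#' @param n_resample Genes drawn per replicate (default 167).
#' @param n_replicates Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @return Named list with one `bootstrap_dist` object per category: list
#'   with `category`, `deviations`, `mean_deviation`, `ci95`, `n_resample`,
#'   `n_replicates`, `n_genes`, `seed`.
#' @export
block_bootstrap <- function(gene_values, categories, global_mean,
                            n_resample = 167L, n_replicates = 10000L,
                            seed = 1L) {
  stopifnot(length(gene_values) == length(categories))
  n_resample <- as.integer(n_resample)
  n_replicates <- as.integer(n_replicates)
  if (n_resample < 1L || n_replicates < 1L) {
    stop("n_resample and n_replicates must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  cats <- unique(as.character(categories))
  out <- list()
  for (cat_i in cats) {
    vals <- gene_values[categories == cat_i]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      stop("category '", cat_i, "' has no genes with ancestry values",
           call. = FALSE)
    }
    draws <- matrix(sample(vals, n_resample * n_replicates, replace = TRUE),
                    nrow = n_resample)
    dev <- colMeans(draws) - global_mean
    ci <- unname(stats::quantile(dev, c(0.025, 0.975)))
    out[[cat_i]] <- structure(list(
      category = cat_i, deviations = dev, mean_deviation = mean(dev),
      ci95 = ci, n_resample = n_resample, n_replicates = n_replicates,
      n_genes = length(vals), seed = as.integer(seed)),
      class = "bootstrap_dist")
  }
  out
}

#' @export
print.bootstrap_dist <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_dist> %s: mean deviation %+.5f (95%% CI %+.5f, %+.5f); %d genes, %d x %d resamples\n",
    x$category, x$mean_deviation, x$ci95[1L], x$ci95[2L], x$n_genes,
    x$n_replicates, x$n_resample))
  invisible(x)
}

#' Two-sample t-test between bootstrap deviation distributions
#'
#' Classical pooled-variance t-test of independent means on the replicate
#' deviation arrays of two categories (e.g. high-mt vs non-mt). Because the
#' "observations" are bootstrap replicates, the p-value scales with the
#' replicate count; the replicate counts are returned alongside so this
#' caveat stays visible.
#'
#' @param dist_a,dist_b `bootstrap_dist` objects with at least 2 replicates
#'   each.
#' @return List with `t`, `p` (two-sided), `n_a`, `n_b`. If both arrays have
#'   zero variance the test is degenerate and `t`/`p` are `NA`.
#' @export
category_ttest <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "bootstrap_dist"),
            inherits(dist_b, "bootstrap_dist"))
  a <- dist_a$deviations
  b <- dist_b$deviations
  if (length(a) < 2L || length(b) < 2L) {
    stop("need >= 2 replicates per distribution", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    message("zero variance in both bootstrap distributions; t undefined.")
    return(list(t = NA_real_, p = NA_real_,
                n_a = length(a), n_b = length(b)))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Local-ancestry enrichment analysis over gene categories
#'
#' Orchestrates the enrichment test: per-gene window ancestry, a global
#' baseline, the block bootstrap per category, and t-tests of high-mt and
#' low-mt against non-mt.
#'
#' The default baseline is the cohort mean of global ancestry recomputed from
#' the same local-ancestry segments ([global_from_local()]), so that category
#' deviations are measured against the estimates they are part of; set
#' `baseline = "q_table"` (with `q_table`) to use the mean of ADMIXTURE-style
#' global fractions instead.
#'
#' @param genes Gene annotation data.frame (see [gene_window_ancestry()]).
#' @param segments Local-ancestry segment table.
#' @param window_mb Window size in megabases.
#' @param n_resample,n_replicates,seed Passed to [block_bootstrap()].
#' @param baseline `"local"` (default) or `"q_table"`.
#' @param q_table Q table (columns `sample_id`, `african`), required when
#'   `baseline = "q_table"`.
#' @return List with `gene_values`, `global_mean`, `baseline`, `bootstrap`
#'   (per-category `bootstrap_dist`), and `tests` (data.frame of pairwise
#'   t-tests against `non_mt`).
#' @export
run_enrichment <- function(genes, segments, window_mb = 5,
                           n_resample = 167L, n_replicates = 10000L,
                           seed = 1L, baseline = c("local", "q_table"),
                           q_table = NULL) {
  baseline <- match.arg(baseline)
  gv <- gene_window_ancestry(genes, segments, window_mb = window_mb)
  global_mean <- if (baseline == "local") {
    mean(global_from_local(segments)$african)
  } else {
    if (is.null(q_table)) {
      stop("baseline = 'q_table' requires a q_table", call. = FALSE)
    }
    mean(q_table$african)
  }
  boot <- block_bootstrap(gv$african, gv$category, global_mean,
                          n_resample = n_resample,
                          n_replicates = n_replicates, seed = seed)
  tests <- NULL
  if ("non_mt" %in% names(boot)) {
    others <- setdiff(names(boot), "non_mt")
    tests <- do.call(rbind, lapply(others, function(cat_i) {
      tt <- category_ttest(boot[[cat_i]], boot[["non_mt"]])
      data.frame(category = cat_i, reference = "non_mt", t = tt$t, p = tt$p,
                 n_replicates = tt$n_a, stringsAsFactors = FALSE)
    }))
  }
  list(gene_values = gv, global_mean = global_mean, baseline = baseline,
       bootstrap = boot, tests = tests)
}
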