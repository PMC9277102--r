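#' One-sided Mann-Whitney U test with common-language effect size
#'
#' Tests whether adjusted expression in the low-discordance group is
#' stochastically greater than in the high-discordance group (the alternative
#' hypothesis: expression is lower where mitonuclear discordance is higher).
#' `U` counts pairs where a low-group value exceeds a high-group value, ties
#' counted half; the common-language effect size is
#' `CLES = U / (n_low * n_high)`, the probability that a random draw from the
#' low-discordance (e.g. European American) distribution exceeds a random
#' draw from the high-discordance (e.g. African American) distribution.
#'
#' With both groups of size at most `exact_max` the one-sided p-value is
#' computed by exhaustive enumeration of all group-label assignments (exact
#' under ties); otherwise by the tie-corrected normal approximation with a
#' 0.5 continuity correction.
#'
#' @param low_disc_group,high_disc_group Numeric vectors of adjusted TPM for
#'   the low- and high-discordance groups. Both must be nonempty.
#' @param exact_max Largest per-group size for which the exact enumeration is
#'   used (default 8).
#' @return List with `u_statistic`, `cles`, `p_raw`, `n_low`, `n_high`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_one_sided <- function(low_disc_group, high_disc_group,
                                   exact_max = 8L) {
  low <- as.numeric(low_disc_group)
  high <- as.numeric(high_disc_group)
  if (length(low) == 0L || length(high) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (anyNA(low) || anyNA(high)) {
    stop("NA values in group comparison", call. = FALSE)
  }
  n1 <- length(low)
  n2 <- length(high)
  pooled <- c(low, high)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cles <- u / (n1 * n2)
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    rank_sums <- colSums(matrix(r[combos], nrow = n1))
    u_perm <- rank_sums - n1 * (n1 + 1) / 2
    p <- mean(u_perm >= u)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      # all pooled values identical: no evidence either way
      return(list(u_statistic = u, cles = cles, p_raw = 1,
                  n_low = n1, n_high = n2, method = "degenerate"))
    }
    z <- (u - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  list(u_statistic = u, cles = cles, p_raw = p,
       n_low = n1, n_high = n2, method = method)
}

#' Bonferroni correction within a tissue
#'
#' Multiplies each p-value by the family size (the number of genes in the
#' analysis set, 11 by default in the pipeline) and caps at 1. Correction is
#' applied within tissue, never across tissues.
#'
#' @param p_values Numeric vector of raw p-values in \eqn{[0,1]}.
#' @param family_size Positive integer family size.
#' @return Adjusted p-values, same length as `p_values`.
#' @export
bonferroni <- function(p_values, family_size) {
  p <- as.numeric(p_values)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  family_size <- as.integer(family_size)
  if (length(family_size) != 1L || is.na(family_size) || family_size < 1L) {
    stop("family_size must be a single integer >= 1", call. = FALSE)
  }
  pmin(1, p * family_size)
}

#' Permutation test of mean expression difference across discordance groups
#'
#' Splits samples at the mean discordance of the tissue (high group: strictly
#' above the mean; samples exactly at the cutoff go to the low group) and
#' computes the observed difference `mean(low) - mean(high)` in adjusted
#' expression, so the hypothesized effect (lower expression at higher
#' discordance) is positive. Each permutation reassigns the group labels at
#' random, preserving group sizes. The p-value is the number of permuted
#' differences strictly above the observed difference divided by the number
#' of permutations; this literal formula can return 0, so
#' `midp = TRUE` gives the safer `(1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param adjusted Numeric vector of adjusted TPM, one per sample.
#' @param discordance Numeric vector of discordance values, same order.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed for reproducible permutations.
#' @param midp Use the add-one variant instead of the literal formula.
#' @return Object of class `permutation_result`: list with `cutoff`,
#'   `observed_diff`, `permuted_diffs`, `p`, `n_low`, `n_high`, `seed`,
#'   `note` (non-`NA` for degenerate constant input).
#' @export
permutation_test <- function(adjusted, discordance, n_perm = 1000L,
                             seed = NULL, midp = FALSE) {
  x <- as.numeric(adjusted)
  d <- as.numeric(discordance)
  if (length(x) != length(d)) {
    stop("adjusted and discordance must have equal length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(d)) stop("NA values in permutation test", call. = FALSE)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  cutoff <- mean(d)
  high <- d > cutoff
  n_high <- sum(high)
  n_low <- sum(!high)
  if (n_high == 0L || n_low == 0L) {
    stop(sprintf("a group is empty at the mean-discordance cutoff %.6g",
                 cutoff), call. = FALSE)
  }
  obs <- mean(x[!high]) - mean(x[high])
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  total <- sum(x)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n_low)
    s <- sum(x[idx])
    s / n_low - (total - s) / n_high
  }, numeric(1))
  p <- if (midp) (1 + sum(perm >= obs)) / (1 + n_perm) else
    sum(perm > obs) / n_perm
  note <- NA_character_
  if (diff(range(x)) == 0) {
    note <- "constant expression: observed and permuted differences all zero"
    message(note, " (p = ", p, " under the strict '>' rule).")
  }
  structure(list(cutoff = cutoff, observed_diff = obs, permuted_diffs = perm,
                 p = p, n_low = n_low, n_high = n_high,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 note = note),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> cutoff %.4g; low/high n = %d/%d; obs diff %.4g; p = %.4g (%d perms)\n",
    x$cutoff, x$n_low, x$n_high, x$observed_diff, x$p,
    length(x$permuted_diffs)))
  invisible(x)
}

#' One-sided Spearman rank correlation
#'
#' Spearman's rho between discordance and adjusted expression, computed as
#' the Pearson correlation of average (mid) ranks, with a one-sided p-value
#' for the alternative rho < 0 (lower expression with higher discordance)
#' from the t approximation on the rank correlation.
#'
#' @param discordance,adjusted Numeric vectors; pairs with an NA in either
#'   are dropped; at least 3 complete pairs are required.
#' @return List with `rho`, `p_raw` and `n`. If either variable has zero rank
#'   variance, `rho` and `p_raw` are `NA`.
#' @export
spearman_one_sided <- function(discordance, adjusted) {
  ok <- stats::complete.cases(discordance, adjusted)
  x <- as.numeric(discordance[ok])
  y <- as.numeric(adjusted[ok])
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    message("zero rank variance; Spearman rho undefined.")
    return(list(rho = NA_real_, p_raw = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L
  p <- if (abs(rho) >= 1) {
    if (rho < 0) 0 else 1
  } else {
    stats::pt(rho * sqrt(df / (1 - rho^2)), df)
  }
  list(rho = rho, p_raw = p, n = n)
}

#' Run the three association analyses over genes and tissues
#'
#' For each tissue and gene: (1) a one-sided Mann-Whitney U comparison of the
#' low-discordance population versus the high-discordance population with
#' CLES and within-tissue Bonferroni correction; (2) a permutation test on
#' discordance groups split at the tissue mean, ignoring population labels;
#' (3) a one-sided Spearman correlation of discordance with adjusted
#' expression. Also returns a per-tissue summary of how many genes trend in
#' the hypothesized direction (CLES > 0.5, observed difference > 0, rho < 0)
#' and how many are Bonferroni-significant.
#'
#' @param adjusted An `adjusted_expression` object or a list of them (one per
#'   tissue).
#' @param discordance data.frame from [discordance_table()] covering every
#'   expression sample.
#' @param low_population,high_population Population labels of the
#'   low-discordance (reference) and high-discordance (admixed) groups.
#' @param n_perm Permutations per gene.
#' @param seed Integer seed; gene g in a tissue uses `seed + g` for its
#'   permutations.
#' @param family_size Bonferroni family size; defaults to the number of genes
#'   in each tissue's table.
#' @param alpha Significance level used in the trend summary.
#' @return List with data.frames `comparison`, `permutation`, `correlation`
#'   and `summary`.
#' @export
run_association_suite <- function(adjusted, discordance,
                                  low_population = "EA",
                                  high_population = "AA",
                                  n_perm = 1000L, seed = 1L,
                                  family_size = NULL, alpha = 0.05) {
  if (inherits(adjusted, "adjusted_expression")) adjusted <- list(adjusted)
  stopifnot(is.data.frame(discordance),
            all(c("sample_id", "population", "discordance") %in%
                  names(discordance)))
  comp_rows <- list()
  perm_rows <- list()
  corr_rows <- list()
  summ_rows <- list()
  for (adj in adjusted) {
    stopifnot(inherits(adj, "adjusted_expression"))
    tissue <- adj$tissue
    samples <- colnames(adj$residuals)
    idx <- match(samples, discordance$sample_id)
    if (anyNA(idx)) {
      stop("tissue '", tissue, "': samples without a discordance record: ",
           paste(utils::head(samples[is.na(idx)], 5L), collapse = ", "),
           call. = FALSE)
    }
    d <- discordance$discordance[idx]
    pop <- discordance$population[idx]
    genes <- rownames(adj$residuals)
    fam <- if (is.null(family_size)) length(genes) else as.integer(family_size)
    is_low <- pop == low_population
    is_high <- pop == high_population
    for (g in seq_along(genes)) {
      y <- adj$residuals[g, ]
      mw <- mann_whitney_one_sided(y[is_low], y[is_high])
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        tissue = tissue, gene = genes[g], u_statistic = mw$u_statistic,
        cles = mw$cles, p_raw = mw$p_raw,
        p_bonferroni = bonferroni(mw$p_raw, fam),
        n_low = mw$n_low, n_high = mw$n_high, stringsAsFactors = FALSE)
      pt <- permutation_test(y, d, n_perm = n_perm, seed = seed + g)
      perm_rows[[length(perm_rows) + 1L]] <- data.frame(
        tissue = tissue, gene = genes[g], cutoff = pt$cutoff,
        observed_diff = pt$observed_diff, p = pt$p,
        p_bonferroni = bonferroni(pt$p, fam),
        n_low = pt$n_low, n_high = pt$n_high, seed = seed + g,
        stringsAsFactors = FALSE)
      sp <- spearman_one_sided(d, y)
      corr_rows[[length(corr_rows) + 1L]] <- data.frame(
        tissue = tissue, gene = genes[g], rho = sp$rho, p_raw = sp$p_raw,
        p_bonferroni = bonferroni(sp$p_raw, fam), n = sp$n,
        stringsAsFactors = FALSE)
    }
    ct <- do.call(rbind, comp_rows)
    ct <- ct[ct$tissue == tissue, ]
    pt_t <- do.call(rbind, perm_rows)
    pt_t <- pt_t[pt_t$tissue == tissue, ]
    rt <- do.call(rbind, corr_rows)
    rt <- rt[rt$tissue == tissue, ]
    summ_rows[[length(summ_rows) + 1L]] <- data.frame(
      tissue = tissue, n_genes = length(genes), family_size = fam,
      n_cles_above_half = sum(ct$cles > 0.5),
      n_obs_diff_positive = sum(pt_t$observed_diff > 0),
      n_rho_negative = sum(rt$rho < 0, na.rm = TRUE),
      n_sig_comparison = sum(ct$p_bonferroni < alpha),
      n_sig_permutation = sum(pt_t$p_bonferroni < alpha),
      n_sig_correlation = sum(rt$p_bonferroni < alpha, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  list(comparison = do.call(rbind, comp_rows),
       permutation = do.call(rbind, perm_rows),
       correlation = do.call(rbind, corr_rows),
       summary = do.call(rbind, summ_rows))
}
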