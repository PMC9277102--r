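#' Approximate human autosome map
#'
#' Physical lengths (base pairs, approximate GRCh38) and sex-averaged genetic
#' lengths (Morgans, approximate) of the 22 human autosomes. Used as the
#' default chromosome map of the cohort generator.
#'
#' @return data.frame with columns `chrom`, `length_bp`, `morgans`.
#' @export
default_chromosomes <- function() {
  mb <- c(248.96, 242.19, 198.30, 190.21, 181.54, 170.81, 159.35, 145.14,
          138.39, 133.80, 135.09, 133.28, 114.36, 107.04, 101.99, 90.34,
          83.26, 80.37, 58.62, 64.44, 46.71, 50.82)
  cm <- c(286, 269, 223, 214, 204, 192, 187, 168, 166, 181, 158, 175,
          126, 119, 141, 134, 128, 117, 107, 108, 62, 74)
  data.frame(chrom = paste0("chr", seq_along(mb)),
             length_bp = round(mb * 1e6), morgans = cm / 100,
             stringsAsFactors = FALSE)
}

#' Uniform toy chromosome map
#'
#' A reduced map of equal-sized chromosomes for fast simulation experiments.
#'
#' @param n_chrom Number of chromosomes.
#' @param length_bp Physical length of each chromosome.
#' @param morgans Genetic length of each chromosome in Morgans.
#' @return data.frame with columns `chrom`, `length_bp`, `morgans`.
#' @export
toy_chromosomes <- function(n_chrom = 22L, length_bp = 1e8, morgans = 1.1) {
  data.frame(chrom = paste0("chr", seq_len(n_chrom)),
             length_bp = rep(length_bp, n_chrom),
             morgans = rep(morgans, n_chrom), stringsAsFactors = FALSE)
}

#' Default per-population haplogroup frequencies
#'
#' Major-haplogroup frequencies for the admixed (AA) and reference (EA)
#' populations: AA 88/101 L, 9/101 H, 3/101 U, 1/101 T; EA 347/688 H,
#' 98/688 U, 65/688 T, 61/688 K, 50/688 J, 22/688 V, 13/688 each of I, X, W,
#' and 6/688 L.
#'
#' @return Named list with numeric frequency vectors `AA` and `EA`, each
#'   summing to 1.
#' @export
default_haplogroup_freqs <- function() {
  list(
    AA = c(L = 88, H = 9, U = 3, T = 1) / 101,
    EA = c(H = 347, U = 98, T = 65, K = 61, J = 50, V = 22,
           I = 13, X = 13, W = 13, L = 6) / 688
  )
}

#' Configuration of the synthetic admixed-cohort generator
#'
#' Collects and validates every tunable of the generator. The defaults encode
#' the study conditions the generator emulates: 101 admixed-population (AA)
#' and 688 reference-population (EA) samples; AA global African ancestry
#' Beta-distributed with mean 0.77 and concentration 3.2 (so that the
#' within-haplogroup discordance variance is about 0.042); EA African
#' ancestry near zero (mean 0.01); major-haplogroup frequencies as observed
#' in the two populations; admixture about six generations ago over the 22
#' human autosomes; expression linear in age, ischemic time and discordance
#' with Gaussian noise.
#'
#' @param n_aa,n_ea Sample counts for the admixed and reference populations.
#' @param aa_african_mean,ea_african_mean Mean African ancestry fraction per
#'   population, in (0, 1).
#' @param aa_african_concentration Beta concentration (shape1 + shape2) used
#'   for both populations' ancestry draws; positive.
#' @param haplogroup_freqs Named list (`AA`, `EA`) of named frequency vectors
#'   over major haplogroup letters; each must sum to 1 within 1e-9.
#' @param n_genes Number of expression genes; the first 13 take the canonical
#'   mtDNA protein-coding names.
#' @param beta_age,beta_ischemic,beta_discordance Linear effects on TPM per
#'   year of age, per minute of ischemic time, and per unit of discordance.
#' @param noise_sd Gaussian noise SD in TPM; positive.
#' @param intercept_range TPM intercept range genes are drawn from.
#' @param admixture_generations Generations since admixture (Poisson
#'   breakpoint rate multiplier); nonnegative integer.
#' @param chromosome_lengths Chromosome map data.frame (`chrom`, `length_bp`,
#'   `morgans`).
#' @param gene_counts Named integer vector: genes per annotation category
#'   (`high_mt`, `low_mt`, `non_mt`).
#' @param enrichment_shift Extra African tract probability inside high-mt
#'   gene windows, in \eqn{[-1, 1]}.
#' @param window_mb Window size (megabases) defining high-mt windows for the
#'   enrichment shift; matches the analysis window.
#' @param ischemic_range Ischemic-time range in minutes.
#' @param age_range Donor age range in years.
#' @param tissue Tissue label of the simulated expression table.
#' @param seed Integer master seed; each generator stage derives its own
#'   stream from it.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_aa = 101L, n_ea = 688L,
                          aa_african_mean = 0.77,
                          aa_african_concentration = 3.2,
                          ea_african_mean = 0.01,
                          haplogroup_freqs = default_haplogroup_freqs(),
                          n_genes = 13L,
                          beta_age = 2, beta_ischemic = -0.3,
                          beta_discordance = -10, noise_sd = 20,
                          intercept_range = c(2000, 10000),
                          admixture_generations = 6L,
                          chromosome_lengths = default_chromosomes(),
                          gene_counts = c(high_mt = 167L, low_mt = 793L,
                                          non_mt = 17456L),
                          enrichment_shift = 0,
                          window_mb = 5,
                          ischemic_range = c(60, 1440),
                          age_range = c(20, 70),
                          tissue = "skeletal_muscle",
                          seed = 1L) {
  cfg <- list(n_aa = as.integer(n_aa), n_ea = as.integer(n_ea),
              aa_african_mean = aa_african_mean,
              aa_african_concentration = aa_african_concentration,
              ea_african_mean = ea_african_mean,
              haplogroup_freqs = haplogroup_freqs,
              n_genes = as.integer(n_genes),
              beta_age = beta_age, beta_ischemic = beta_ischemic,
              beta_discordance = beta_discordance, noise_sd = noise_sd,
              intercept_range = intercept_range,
              admixture_generations = as.integer(admixture_generations),
              chromosome_lengths = chromosome_lengths,
              gene_counts = gene_counts,
              enrichment_shift = enrichment_shift,
              window_mb = window_mb,
              ischemic_range = ischemic_range,
              age_range = age_range,
              tissue = as.character(tissue),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(...) stop("invalid cohort config: ", ..., call. = FALSE)
  if (cfg$n_aa < 0L || cfg$n_ea < 0L) stop_cfg("sample counts must be >= 0")
  for (f in c("aa_african_mean", "ea_african_mean")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v <= 0 || v >= 1) {
      stop_cfg(f, " must lie strictly in (0, 1)")
    }
  }
  if (!is.finite(cfg$aa_african_concentration) ||
      cfg$aa_african_concentration <= 0) {
    stop_cfg("aa_african_concentration must be positive")
  }
  if (!all(c("AA", "EA") %in% names(cfg$haplogroup_freqs))) {
    stop_cfg("haplogroup_freqs must name populations AA and EA")
  }
  for (pop in names(cfg$haplogroup_freqs)) {
    fr <- cfg$haplogroup_freqs[[pop]]
    if (is.null(names(fr)) || any(fr < 0)) {
      stop_cfg("haplogroup frequencies must be named and nonnegative")
    }
    if (abs(sum(fr) - 1) > 1e-9) {
      stop_cfg("haplogroup frequencies for ", pop,
               " sum to ", format(sum(fr), digits = 12), ", not 1")
    }
  }
  if (cfg$n_genes < 0L) stop_cfg("n_genes must be >= 0")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop_cfg("noise_sd must be positive")
  }
  if (cfg$admixture_generations < 0L) {
    stop_cfg("admixture_generations must be >= 0")
  }
  cl <- cfg$chromosome_lengths
  if (!is.data.frame(cl) ||
      !all(c("chrom", "length_bp", "morgans") %in% names(cl)) ||
      nrow(cl) == 0L) {
    stop_cfg("chromosome_lengths must be a nonempty data.frame with ",
             "columns chrom, length_bp, morgans")
  }
  if (any(cl$length_bp <= 0) || any(cl$morgans < 0)) {
    stop_cfg("chromosome lengths must be positive and morgans nonnegative")
  }
  if (abs(cfg$enrichment_shift) > 1) {
    stop_cfg("enrichment_shift must lie in [-1, 1]")
  }
  if (any(cfg$gene_counts < 0L) ||
      !all(c("high_mt", "low_mt", "non_mt") %in% names(cfg$gene_counts))) {
    stop_cfg("gene_counts must name high_mt, low_mt, non_mt")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d AA + %d EA samples; AA African ancestry Beta(mean %.2f, conc %.2f);\n",
    x$n_aa, x$n_ea, x$aa_african_mean, x$aa_african_concentration))
  cat(sprintf(
    "  %d genes; beta_discordance %.3g TPM, noise_sd %.3g TPM; %d generations over %d chromosomes; seed %d\n",
    x$n_genes, x$beta_discordance, x$noise_sd, x$admixture_generations,
    nrow(x$chromosome_lengths), x$seed))
  invisible(x)
}

beta_shapes <- function(mean, concentration) {
  c(shape1 = mean * concentration, shape2 = (1 - mean) * concentration)
}

#' Simulate global-ancestry (Q) fractions
#'
#' Draws each sample's African ancestry fraction from a Beta distribution
#' parameterized by the population mean and the shared concentration, with
#' the European fraction as the complement (a supervised K = 2 Q table).
#'
#' @param config A [cohort_config()].
#' @return data.frame with columns `sample_id`, `population`, `african`,
#'   `european`; AA samples first.
#' @export
simulate_global_ancestry <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  sh_aa <- beta_shapes(config$aa_african_mean,
                       config$aa_african_concentration)
  sh_ea <- beta_shapes(config$ea_african_mean,
                       config$aa_african_concentration)
  african <- c(stats::rbeta(config$n_aa, sh_aa[1L], sh_aa[2L]),
               stats::rbeta(config$n_ea, sh_ea[1L], sh_ea[2L]))
  data.frame(
    sample_id = c(sprintf("AA-%04d", seq_len(config$n_aa)),
                  sprintf("EA-%04d", seq_len(config$n_ea))),
    population = rep(c("AA", "EA"), c(config$n_aa, config$n_ea)),
    african = african, european = 1 - african,
    stringsAsFactors = FALSE)
}

#' Simulate sample metadata with mtDNA haplogroups
#'
#' Assigns each sample a major mtDNA haplogroup letter by a categorical draw
#' from its population's frequency vector, plus covariates: age uniform over
#' the configured range (20-70 years by default), ischemic time uniform over
#' the configured range in minutes, and sex Bernoulli(0.5).
#'
#' @param config A [cohort_config()].
#' @param ancestry Output of [simulate_global_ancestry()].
#' @return data.frame with columns `sample_id`, `population`, `age`,
#'   `ischemic_time_min`, `sex`, `tissue`, `haplogroup`.
#' @export
simulate_haplogroups <- function(config, ancestry) {
  stopifnot(inherits(config, "cohort_config"), is.data.frame(ancestry))
  set.seed(config$seed + 2L)
  n <- nrow(ancestry)
  hg <- character(n)
  for (pop in unique(ancestry$population)) {
    fr <- config$haplogroup_freqs[[pop]]
    if (is.null(fr)) {
      stop("no haplogroup frequencies configured for population '", pop, "'",
           call. = FALSE)
    }
    sel <- ancestry$population == pop
    hg[sel] <- sample(names(fr), sum(sel), replace = TRUE, prob = fr)
  }
  data.frame(
    sample_id = ancestry$sample_id,
    population = ancestry$population,
    age = stats::runif(n, config$age_range[1L], config$age_range[2L]),
    ischemic_time_min = stats::runif(n, config$ischemic_range[1L],
                                     config$ischemic_range[2L]),
    sex = c("female", "male")[stats::rbinom(n, 1L, 0.5) + 1L],
    tissue = config$tissue,
    haplogroup = hg,
    stringsAsFactors = FALSE)
}

#' Simulate a gene annotation table
#'
#' Places `high_mt`, `low_mt` and `non_mt` genes uniformly on the configured
#' chromosomes (probability proportional to physical length), with gene
#' lengths uniform between 10 and 200 kb.
#'
#' @param config A [cohort_config()].
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `category` (0-based half-open coordinates).
#' @export
simulate_gene_annotation <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 5L)
  counts <- config$gene_counts
  cl <- config$chromosome_lengths
  n <- sum(counts)
  category <- rep(names(counts), counts)
  prefix <- c(high_mt = "HMT", low_mt = "LMT", non_mt = "G")
  gene_id <- paste0(prefix[category],
                    unlist(lapply(counts, function(k) {
                      formatC(seq_len(k), width = 5, flag = "0")
                    })))
  ci <- sample.int(nrow(cl), n, replace = TRUE, prob = cl$length_bp)
  len <- stats::runif(n, 1e4, 2e5)
  len <- pmin(len, cl$length_bp[ci] / 2)
  start <- floor(stats::runif(n, 0, cl$length_bp[ci] - len))
  data.frame(gene_id = gene_id, chrom = cl$chrom[ci], start = start,
             end = floor(start + len), category = category,
             stringsAsFactors = FALSE)
}

## Merged union of high-mt gene windows, per chromosome (list of 2-col mats)
high_mt_windows <- function(genes, chromosomes, window_mb) {
  half <- window_mb * 1e6 / 2
  hm <- genes[genes$category == "high_mt", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(chromosomes))) {
    chrom <- chromosomes$chrom[i]
    L <- chromosomes$length_bp[i]
    g <- hm[hm$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0L) next
    mid <- (g$start + g$end) / 2
    s <- pmax(0, mid - half)
    e <- pmin(L, mid + half)
    o <- order(s)
    s <- s[o]; e <- e[o]
    ms <- s[1L]; me <- e[1L]
    merged_s <- numeric(0); merged_e <- numeric(0)
    for (j in seq_along(s)[-1L]) {
      if (s[j] <= me) {
        me <- max(me, e[j])
      } else {
        merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
        ms <- s[j]; me <- e[j]
      }
    }
    merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
    out[[chrom]] <- cbind(start = merged_s, end = merged_e)
  }
  out
}

#' Simulate local-ancestry tracts
#'
#' For each haplotype and chromosome, recombination breakpoints are drawn
#' from a Poisson process with expected count `admixture_generations x
#' Morgans` (positions uniform along the physical chromosome, i.e. a flat
#' recombination map), and each resulting tract is independently African with
#' probability equal to the sample's global African fraction. Segments
#' partition each chromosome exactly (0-based half-open, no gaps, no
#' overlaps). With `enrichment_shift != 0` and a gene annotation supplied,
#' tracts are additionally split at the boundaries of the merged high-mt gene
#' windows and the African probability of tracts inside those windows is
#' raised by the shift (clamped to \eqn{[0, 1]}), injecting a known
#' local-ancestry enrichment.
#'
#' @param config A [cohort_config()].
#' @param ancestry Output of [simulate_global_ancestry()].
#' @param genes Gene annotation (required only when
#'   `config$enrichment_shift != 0`).
#' @return data.table with columns `sample_id`, `haplotype` (0/1), `chrom`,
#'   `start`, `end`, `ancestry` (`african`/`european`).
#' @export
simulate_local_tracts <- function(config, ancestry, genes = NULL) {
  stopifnot(inherits(config, "cohort_config"), is.data.frame(ancestry))
  set.seed(config$seed + 3L)
  eshift <- config$enrichment_shift
  windows <- NULL
  if (eshift != 0) {
    if (is.null(genes)) {
      stop("enrichment_shift != 0 requires a gene annotation", call. = FALSE)
    }
    windows <- high_mt_windows(genes, config$chromosome_lengths,
                               config$window_mb)
  }
  g <- config$admixture_generations
  cl <- config$chromosome_lengths
  n_samples <- nrow(ancestry)
  base_p <- ancestry$african
  grp_sample <- rep(seq_len(n_samples), each = 2L)
  grp_hap <- rep(c(0L, 1L), n_samples)
  n_grp <- 2L * n_samples
  pieces <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    L <- cl$length_bp[i]
    lambda <- g * cl$morgans[i]
    counts <- stats::rpois(n_grp, lambda)
    bp <- round(stats::runif(sum(counts), 0, L))
    grp_bp <- rep(seq_len(n_grp), counts)
    fixed <- L
    if (!is.null(windows) && !is.null(windows[[cl$chrom[i]]])) {
      w <- windows[[cl$chrom[i]]]
      fixed <- sort(unique(round(c(fixed, w[, "start"], w[, "end"]))))
      fixed <- fixed[fixed > 0 & fixed <= L]
    }
    dt <- data.table(
      grp = c(grp_bp, rep(seq_len(n_grp), each = length(fixed))),
      pos = c(bp, rep(fixed, times = n_grp)))
    dt <- dt[pos > 0 & pos <= L]
    dt <- unique(dt)
    setorder(dt, grp, pos)
    dt[, start := shift(pos, fill = 0), by = grp]
    dt <- dt[pos > start]
    p <- base_p[grp_sample[dt$grp]]
    if (!is.null(windows) && !is.null(windows[[cl$chrom[i]]])) {
      w <- windows[[cl$chrom[i]]]
      edges <- as.vector(t(w))
      mid <- (dt$start + dt$pos) / 2
      inside <- findInterval(mid, edges) %% 2L == 1L
      p <- pmin(1, pmax(0, p + eshift * inside))
    }
    pieces[[i]] <- data.table(
      sample_id = ancestry$sample_id[grp_sample[dt$grp]],
      haplotype = grp_hap[dt$grp],
      chrom = cl$chrom[i],
      start = dt$start,
      end = dt$pos,
      ancestry = c("european", "african")[stats::rbinom(nrow(dt), 1L, p) + 1L])
  }
  out <- rbindlist(pieces)
  setorder(out, sample_id, haplotype, chrom, start)
  out[]
}

#' Simulate a TPM expression table
#'
#' `TPM[g, s] = intercept_g + beta_age * age_s + beta_ischemic * ischemic_s +
#' beta_discordance * D_s + noise`, with Gaussian noise of SD `noise_sd`, and
#' values floored at 0 (TPM is nonnegative); the number of floored cells is
#' reported via a message and the `n_floored` attribute. Gene intercepts are
#' drawn uniformly over `config$intercept_range`. The first
#' `min(n_genes, 13)` genes take the canonical mtDNA protein-coding names;
#' any further genes are named `SYNxx`.
#'
#' @param config A [cohort_config()].
#' @param samples Metadata from [simulate_haplogroups()]; every sample must
#'   have complete covariates.
#' @param truth_discordance Numeric vector of true discordance values, one
#'   per row of `samples`.
#' @return An [expression_table()] with the gene intercepts in the
#'   `intercepts` attribute and the floored-cell count in `n_floored`.
#' @export
simulate_expression <- function(config, samples, truth_discordance) {
  stopifnot(inherits(config, "cohort_config"), is.data.frame(samples))
  if (length(truth_discordance) != nrow(samples)) {
    stop("need one discordance value per sample", call. = FALSE)
  }
  bad <- !stats::complete.cases(samples$age, samples$ischemic_time_min,
                                truth_discordance)
  if (any(bad)) {
    stop("missing covariate or discordance for sample(s): ",
         paste(utils::head(samples$sample_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  set.seed(config$seed + 4L)
  n_genes <- config$n_genes
  canon <- mtdna_genes()
  gene_ids <- c(utils::head(canon, min(n_genes, length(canon))),
                if (n_genes > length(canon)) {
                  sprintf("SYN%02d", seq_len(n_genes - length(canon)))
                })
  intercepts <- stats::runif(n_genes, config$intercept_range[1L],
                             config$intercept_range[2L])
  n <- nrow(samples)
  signal <- config$beta_age * samples$age +
    config$beta_ischemic * samples$ischemic_time_min +
    config$beta_discordance * truth_discordance
  tpm <- matrix(rep(intercepts, n), nrow = n_genes) +
    matrix(rep(signal, each = n_genes), nrow = n_genes) +
    matrix(stats::rnorm(n_genes * n, 0, config$noise_sd), nrow = n_genes)
  n_floored <- sum(tpm < 0)
  if (n_floored > 0L) {
    message(n_floored, " TPM value(s) floored at 0.")
    tpm[tpm < 0] <- 0
  }
  dimnames(tpm) <- list(gene_ids, samples$sample_id)
  out <- expression_table(tpm, config$tissue)
  attr(out, "intercepts") <- stats::setNames(intercepts, gene_ids)
  attr(out, "n_floored") <- n_floored
  out
}

#' Simulate a complete synthetic admixed cohort
#'
#' Runs every generator stage in order: global ancestry, haplogroups and
#' covariates, gene annotation, local-ancestry tracts, true discordance
#' (computed with the same operations the analysis uses, so the round trip is
#' exact), and expression. Samples whose simulated haplogroup falls outside
#' the African/European model are dropped from every component (none arise
#' under the default frequencies).
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `samples`,
#'   `global_ancestry`, `expression` (named list of [expression_table()]s),
#'   `local_ancestry`, `genes`, and `truth` (the config plus each sample's
#'   true discordance).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ancestry <- simulate_global_ancestry(config)
  samples <- simulate_haplogroups(config, ancestry)
  designation <- classify_haplogroup(samples$haplogroup)
  keep <- designation != "excluded"
  if (any(!keep)) {
    message(sum(!keep), " simulated sample(s) dropped: haplogroup outside ",
            "the African/European model.")
    ancestry <- ancestry[keep, , drop = FALSE]
    samples <- samples[keep, , drop = FALSE]
    designation <- designation[keep]
  }
  genes <- simulate_gene_annotation(config)
  tracts <- simulate_local_tracts(config, ancestry, genes)
  discordance <- compute_discordance(ancestry$african, designation,
                                     ancestry$european)
  expr <- simulate_expression(config, samples, discordance)
  truth <- list(
    config = config,
    discordance = data.frame(sample_id = samples$sample_id,
                             population = samples$population,
                             designation = as.character(designation),
                             discordance = discordance,
                             stringsAsFactors = FALSE),
    n_floored = attr(expr, "n_floored"),
    intercepts = attr(expr, "intercepts"))
  structure(list(samples = samples, global_ancestry = ancestry,
                 expression = stats::setNames(list(expr), config$tissue),
                 local_ancestry = tracts, genes = genes, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d samples (%s); %d annotation genes; %d local-ancestry segments\n",
    nrow(x$samples),
    paste(sprintf("%d %s", table(x$samples$population),
                  names(table(x$samples$population))), collapse = ", "),
    nrow(x$genes), nrow(x$local_ancestry)))
  cat(sprintf("  expression: %s\n",
              paste(vapply(x$expression, function(e) {
                sprintf("%s (%d genes)", e$tissue, nrow(e$tpm))
              }, ""), collapse = "; ")))
  invisible(x)
}
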