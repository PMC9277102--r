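#' Pipeline run configuration
#'
#' Validates the inputs and parameters of a full analysis run. Every input
#' path must exist at validation time.
#'
#' @param metadata,q_table,msp,bed Paths to the sample-metadata TSV, Q-table
#'   TSV, MSP local-ancestry TSV and BED gene annotation.
#' @param expression Named character vector (or list) of GCT paths, one per
#'   tissue; names are the tissue labels.
#' @param out_dir Output directory for result tables.
#' @param low_population,high_population Population labels of the reference
#'   (low-discordance) and admixed (high-discordance) groups.
#' @param family_size Bonferroni family size; `NULL` uses the per-tissue gene
#'   count after the analysis-set filter.
#' @param merge_bicistronic Collapse ATP8/ATP6 and ND4L/ND4 into summed rows
#'   before adjustment (default `FALSE`).
#' @param n_perm Permutations per gene.
#' @param window_mb Enrichment window size in megabases.
#' @param n_resample,n_replicates Block-bootstrap parameters.
#' @param enrichment_population Population whose samples enter the enrichment
#'   analysis (default the admixed population).
#' @param seed Integer seed recorded in all outputs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(metadata, q_table, msp, bed, expression,
                            out_dir,
                            low_population = "EA", high_population = "AA",
                            family_size = NULL, merge_bicistronic = FALSE,
                            n_perm = 1000L, window_mb = 5,
                            n_resample = 167L, n_replicates = 10000L,
                            enrichment_population = high_population,
                            seed = 1L) {
  expression <- unlist(expression)
  if (is.null(names(expression)) || any(names(expression) == "")) {
    stop("expression paths must be named by tissue", call. = FALSE)
  }
  paths <- c(metadata = metadata, q_table = q_table, msp = msp, bed = bed,
             expression)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input path(s) do not exist: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(
    metadata = metadata, q_table = q_table, msp = msp, bed = bed,
    expression = expression, out_dir = out_dir,
    low_population = low_population, high_population = high_population,
    family_size = family_size,
    merge_bicistronic = isTRUE(merge_bicistronic),
    n_perm = as.integer(n_perm), window_mb = window_mb,
    n_resample = as.integer(n_resample),
    n_replicates = as.integer(n_replicates),
    enrichment_population = enrichment_population,
    seed = as.integer(seed)), class = "pipeline_config")
}

write_result_tsv <- function(df, path, config, stage) {
  header <- c(
    "# mitonuclear result table",
    sprintf("# stage: %s", stage),
    sprintf("# seed: %d", config$seed),
    sprintf("# package_version: %s",
            as.character(utils::packageVersion("mitonuclear"))))
  writeLines(header, path)
  suppressWarnings(fwrite(df, path, sep = "\t", append = TRUE,
                          col.names = TRUE))
  path
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full mitonuclear discordance pipeline
#'
#' Executes discordance computation, expression adjustment, the three
#' association analyses and the local-ancestry enrichment test, then writes
#' one results directory containing the per-stage TSVs, a machine-readable
#' JSON manifest (inputs, parameters, seed, versions) and a human-readable
#' summary of per-tissue trend and significance counts.
#'
#' @param config A [pipeline_config()].
#' @return List with all stage results (`discordance`, `adjusted`,
#'   `association`, `enrichment`) plus `files` (written paths), invisibly
#'   printable.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  meta <- run_stage("read", read_sample_meta(config$metadata))
  q <- run_stage("read", read_q_table(config$q_table))
  disc <- run_stage("discordance", discordance_table(q, meta))

  adjusted <- list()
  for (tissue in names(config$expression)) {
    adjusted[[tissue]] <- run_stage("adjust", {
      tab <- read_gct(config$expression[[tissue]], tissue = tissue)
      keep <- intersect(mtdna_gene_set(rownames(tab$tpm)), rownames(tab$tpm))
      tab <- expression_table(tab$tpm[keep, , drop = FALSE], tissue)
      if (config$merge_bicistronic) tab <- merge_bicistronic(tab)
      # restrict to samples with a discordance record
      usable <- intersect(colnames(tab$tpm), disc$sample_id)
      tab <- expression_table(tab$tpm[, usable, drop = FALSE], tissue)
      adjust_expression(tab, meta)
    })
  }

  assoc <- run_stage("associate", run_association_suite(
    adjusted, disc,
    low_population = config$low_population,
    high_population = config$high_population,
    n_perm = config$n_perm, seed = config$seed,
    family_size = config$family_size))

  enrich <- run_stage("enrich", {
    genes <- read_gene_bed(config$bed)
    segments <- read_msp(config$msp)
    keep <- disc$sample_id[disc$population == config$enrichment_population]
    segments <- segments[segments$sample_id %in% keep, ]
    run_enrichment(genes, segments, window_mb = config$window_mb,
                   n_resample = config$n_resample,
                   n_replicates = config$n_replicates, seed = config$seed)
  })

  files <- c(
    discordance = write_result_tsv(disc, file.path(config$out_dir,
                                                   "discordance.tsv"),
                                   config, "discordance"),
    comparison = write_result_tsv(assoc$comparison,
                                  file.path(config$out_dir,
                                            "group_comparison.tsv"),
                                  config, "compare"),
    permutation = write_result_tsv(assoc$permutation,
                                   file.path(config$out_dir,
                                             "permutation.tsv"),
                                   config, "permute"),
    correlation = write_result_tsv(assoc$correlation,
                                   file.path(config$out_dir,
                                             "correlation.tsv"),
                                   config, "correlate"),
    summary = write_result_tsv(assoc$summary,
                               file.path(config$out_dir,
                                         "association_summary.tsv"),
                               config, "summarize"))
  boot_summary <- do.call(rbind, lapply(enrich$bootstrap, function(b) {
    data.frame(category = b$category, n_genes = b$n_genes,
               mean_deviation = b$mean_deviation,
               ci95_low = b$ci95[1L], ci95_high = b$ci95[2L],
               n_resample = b$n_resample, n_replicates = b$n_replicates,
               global_mean = enrich$global_mean,
               baseline = enrich$baseline, stringsAsFactors = FALSE)
  }))
  files["enrichment"] <- write_result_tsv(
    boot_summary, file.path(config$out_dir, "enrichment_summary.tsv"),
    config, "enrich")
  reps <- do.call(rbind, lapply(enrich$bootstrap, function(b) {
    data.frame(category = b$category,
               replicate = seq_along(b$deviations),
               deviation = b$deviations, stringsAsFactors = FALSE)
  }))
  files["enrichment_replicates"] <- write_result_tsv(
    reps, file.path(config$out_dir, "enrichment_replicates.tsv"),
    config, "enrich")
  if (!is.null(enrich$tests)) {
    files["enrichment_tests"] <- write_result_tsv(
      enrich$tests, file.path(config$out_dir, "enrichment_tests.tsv"),
      config, "enrich")
  }

  manifest <- list(
    inputs = as.list(c(metadata = config$metadata, q_table = config$q_table,
                       msp = config$msp, bed = config$bed,
                       config$expression)),
    parameters = list(
      low_population = config$low_population,
      high_population = config$high_population,
      family_size = config$family_size,
      merge_bicistronic = config$merge_bicistronic,
      n_perm = config$n_perm, window_mb = config$window_mb,
      n_resample = config$n_resample, n_replicates = config$n_replicates,
      enrichment_population = config$enrichment_population,
      seed = config$seed),
    versions = list(
      mitonuclear = as.character(utils::packageVersion("mitonuclear")),
      r = paste(R.version$major, R.version$minor, sep = ".")),
    outputs = as.list(files))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  files["manifest"] <- manifest_path

  summary_lines <- c(
    "mitonuclear pipeline summary",
    sprintf("seed: %d", config$seed), "",
    "Per-tissue association trends (genes in the hypothesized direction):")
  for (i in seq_len(nrow(assoc$summary))) {
    s <- assoc$summary[i, ]
    summary_lines <- c(summary_lines, sprintf(
      paste0("  %s: %d genes; CLES > 0.5: %d; mean-diff > 0: %d; ",
             "rho < 0: %d; Bonferroni-significant (U/perm/Spearman): ",
             "%d/%d/%d"),
      s$tissue, s$n_genes, s$n_cles_above_half, s$n_obs_diff_positive,
      s$n_rho_negative, s$n_sig_comparison, s$n_sig_permutation,
      s$n_sig_correlation))
  }
  summary_lines <- c(summary_lines, "", "Local-ancestry enrichment:")
  for (i in seq_len(nrow(boot_summary))) {
    b <- boot_summary[i, ]
    summary_lines <- c(summary_lines, sprintf(
      "  %s: mean deviation %+.5f (95%% CI %+.5f, %+.5f), %d genes",
      b$category, b$mean_deviation, b$ci95_low, b$ci95_high, b$n_genes))
  }
  summary_path <- file.path(config$out_dir, "summary.txt")
  writeLines(summary_lines, summary_path)
  files["summary_txt"] <- summary_path

  invisible(list(discordance = disc, adjusted = adjusted,
                 association = assoc, enrichment = enrich, files = files))
}
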