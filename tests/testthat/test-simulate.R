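test_that("config validation rejects malformed parameters", {
  expect_error(cohort_config(aa_african_mean = 1.2), "strictly in \\(0, 1\\)")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(haplogroup_freqs = list(
    AA = c(L = 0.9, H = 0.2), EA = c(H = 1))), "sum to")
  expect_error(cohort_config(chromosome_lengths = data.frame(
    chrom = "chr1", length_bp = -5, morgans = 1)), "positive")
  expect_error(cohort_config(enrichment_shift = 1.5), "\\[-1, 1\\]")
})

test_that("global ancestry draws hit the configured Beta mean", {
  cfg <- cohort_config(n_aa = 10000L, n_ea = 100L, seed = 3L)
  anc <- simulate_global_ancestry(cfg)
  expect_equal(anc$african + anc$european, rep(1, nrow(anc)))
  aa <- anc$african[anc$population == "AA"]
  expect_length(aa, 10000L)
  expect_lt(abs(mean(aa) - 0.77), 0.01)
  # empty admixed group leaves only reference samples
  cfg0 <- cohort_config(n_aa = 0L, n_ea = 10L, seed = 3L)
  anc0 <- simulate_global_ancestry(cfg0)
  expect_equal(unique(anc0$population), "EA")
  expect_equal(nrow(anc0), 10L)
})

test_that("the generator is bit-reproducible under a fixed seed", {
  co1 <- simulate_cohort(small_config(seed = 99L))
  co2 <- simulate_cohort(small_config(seed = 99L))
  expect_identical(co1$global_ancestry, co2$global_ancestry)
  expect_identical(co1$samples, co2$samples)
  expect_identical(co1$local_ancestry, co2$local_ancestry)
  expect_identical(co1$expression[[1]]$tpm, co2$expression[[1]]$tpm)
  co3 <- simulate_cohort(small_config(seed = 100L))
  expect_false(identical(co1$global_ancestry, co3$global_ancestry))
})

test_that("haplogroup draws match the configured frequencies", {
  freqs <- list(AA = c(L = 0.871, H = 0.129), EA = c(H = 1))
  cfg <- cohort_config(n_aa = 10000L, n_ea = 50L,
                       haplogroup_freqs = freqs, seed = 8L)
  anc <- simulate_global_ancestry(cfg)
  meta <- simulate_haplogroups(cfg, anc)
  share_l <- mean(meta$haplogroup[meta$population == "AA"] == "L")
  expect_lt(abs(share_l - 0.871), 0.01)
  expect_true(all(meta$haplogroup[meta$population == "EA"] == "H"))
  expect_true(all(meta$age >= 20 & meta$age <= 70))
  expect_true(all(meta$ischemic_time_min >= 60 &
                    meta$ischemic_time_min <= 1440))
  # degenerate categorical
  cfg1 <- cohort_config(n_aa = 20L, n_ea = 0L,
                        haplogroup_freqs = list(AA = c(L = 1), EA = c(H = 1)),
                        seed = 8L)
  meta1 <- simulate_haplogroups(cfg1, simulate_global_ancestry(cfg1))
  expect_true(all(meta1$haplogroup == "L"))
})

test_that("tracts partition every chromosome exactly", {
  cfg <- small_config(seed = 21L)
  co <- simulate_cohort(cfg)
  seg <- data.table::as.data.table(co$local_ancestry)
  per_chrom <- seg[, .(total = sum(end - start), first = min(start),
                       last = max(end)),
                   by = .(sample_id, haplotype, chrom)]
  lens <- cfg$chromosome_lengths$length_bp[
    match(per_chrom$chrom, cfg$chromosome_lengths$chrom)]
  expect_true(all(per_chrom$total == lens))
  expect_true(all(per_chrom$first == 0))
  expect_true(all(per_chrom$last == lens))
  # no gaps/overlaps: global_from_local runs without error
  expect_silent(global_from_local(co$local_ancestry))
})

test_that("zero admixture generations yield whole-chromosome tracts", {
  cfg <- small_config(admixture_generations = 0L, seed = 4L)
  anc <- simulate_global_ancestry(cfg)
  seg <- simulate_local_tracts(cfg, anc)
  counts <- data.table::as.data.table(seg)[, .N,
                                           by = .(sample_id, haplotype, chrom)]
  expect_true(all(counts$N == 1L))
})

test_that("breakpoint counts follow the Poisson expectation g x Morgans", {
  cfg <- cohort_config(
    n_aa = 5000L, n_ea = 0L, admixture_generations = 6L,
    chromosome_lengths = data.frame(chrom = "chr1", length_bp = 1e8,
                                    morgans = 1),
    seed = 17L)
  anc <- simulate_global_ancestry(cfg)
  seg <- simulate_local_tracts(cfg, anc)
  n_seg <- data.table::as.data.table(seg)[, .N, by = .(sample_id, haplotype)]
  mean_breaks <- mean(n_seg$N - 1L)  # 10000 haplotypes
  expect_lt(abs(mean_breaks - 6) / 6, 0.02)
})

test_that("tract African dosage is centered on the global fraction", {
  # replicate tract realizations for few samples, many seeds
  cfg0 <- cohort_config(n_aa = 4L, n_ea = 0L,
                        chromosome_lengths = toy_chromosomes(2L, 1e8, 1),
                        seed = 1L)
  anc <- simulate_global_ancestry(cfg0)
  doses <- sapply(1:150, function(s) {
    cfg <- cohort_config(n_aa = 4L, n_ea = 0L,
                         chromosome_lengths = toy_chromosomes(2L, 1e8, 1),
                         seed = s)
    gl <- global_from_local(simulate_local_tracts(cfg, anc))
    gl$african[match(anc$sample_id, gl$sample_id)]
  })
  # per sample: mean realized dosage ~ Beta parameter, within 3 MC SE
  for (i in seq_len(nrow(anc))) {
    se <- sd(doses[i, ]) / sqrt(ncol(doses))
    expect_lt(abs(mean(doses[i, ]) - anc$african[i]), 3 * se)
  }
})

test_that("expression is the configured linear model plus noise", {
  cfg <- small_config(seed = 31L, beta_age = 2, beta_ischemic = 0,
                      beta_discordance = 0, noise_sd = 1e-9)
  anc <- simulate_global_ancestry(cfg)
  meta <- simulate_haplogroups(cfg, anc)
  d <- rep(0.5, nrow(meta))
  expr <- simulate_expression(cfg, meta, d)
  # exact linear signal in age: residuals after adjustment ~ 0
  adj <- adjust_expression(expr, meta)
  expect_lt(max(abs(adj$residuals)), 1e-6)
  # missing covariate errors with the sample named
  meta_bad <- meta
  meta_bad$age[3] <- NA
  expect_error(simulate_expression(cfg, meta_bad, d),
               meta$sample_id[3], fixed = TRUE)
})

test_that("expression is independent of discordance under a null effect", {
  cfg <- small_config(seed = 55L, beta_discordance = 0)
  co <- simulate_cohort(cfg)
  adj <- adjust_expression(co$expression[[1]], co$samples)
  d <- co$truth$discordance$discordance[
    match(colnames(adj$residuals), co$truth$discordance$sample_id)]
  rhos <- apply(adj$residuals, 1L, function(y) cor(rank(d), rank(y)))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("TPM flooring is applied and logged", {
  cfg <- small_config(seed = 2L, intercept_range = c(1, 2), noise_sd = 50,
                      beta_age = 0, beta_ischemic = 0, beta_discordance = 0)
  anc <- simulate_global_ancestry(cfg)
  meta <- simulate_haplogroups(cfg, anc)
  expect_message(expr <- simulate_expression(cfg, meta, rep(0.2, nrow(meta))),
                 "floored")
  expect_true(attr(expr, "n_floored") > 0)
  expect_true(all(expr$tpm >= 0))
})

test_that("every sample id appears exactly once in each cohort component", {
  co <- simulate_cohort(small_config(seed = 77L))
  ids <- co$samples$sample_id
  expect_false(anyDuplicated(ids) > 0)
  expect_setequal(co$global_ancestry$sample_id, ids)
  expect_setequal(colnames(co$expression[[1]]$tpm), ids)
  expect_setequal(unique(co$local_ancestry$sample_id), ids)
  expect_setequal(co$truth$discordance$sample_id, ids)
  expect_true(all(co$truth$discordance$discordance >= 0 &
                    co$truth$discordance$discordance <= 1))
})
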