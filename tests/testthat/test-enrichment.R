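# per-base brute-force oracle on a toy chromosome
base_wise_african <- function(genes, segments, window_mb, chrom_len) {
  mid <- (genes$start + genes$end) / 2
  half <- window_mb * 1e6 / 2
  w_start <- max(0, mid - half)
  w_end <- min(chrom_len, mid + half)
  bases <- seq(floor(w_start), ceiling(w_end) - 1)  # 0-based positions
  num <- 0
  den <- 0
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    inside <- bases >= s$start & bases < s$end
    num <- num + sum(inside) * (s$ancestry == "african")
    den <- den + sum(inside)
  }
  num / den
}

test_that("gene window ancestry matches a per-base counting oracle", {
  # 1-kb toy chromosome, window wider than the chromosome (clamped)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 400, end = 600,
                      category = "high_mt")
  segs <- seg_table(
    list("s1", 0, "chr1", 0, 250, "african"),
    list("s1", 1, "chr1", 0, 1000, "european"),
    list("s1", 0, "chr1", 250, 1000, "european"),
    list("s2", 0, "chr1", 0, 1000, "african"),
    list("s2", 1, "chr1", 0, 700, "african"),
    list("s2", 1, "chr1", 700, 1000, "european"))
  got <- gene_window_ancestry(genes, segs, window_mb = 2 / 1000)
  oracle <- base_wise_african(genes, segs, 2 / 1000, 1000)
  expect_equal(got$african, oracle, tolerance = 1e-9)
  # saturation and half-half symmetry
  all_afr <- seg_table(list("s1", 0, "chr1", 0, 1000, "african"),
                       list("s1", 1, "chr1", 0, 1000, "african"))
  expect_equal(gene_window_ancestry(genes, all_afr, 2 / 1000)$african, 1.0)
  half <- seg_table(list("s1", 0, "chr1", 0, 1000, "african"),
                    list("s1", 1, "chr1", 0, 1000, "european"),
                    list("s2", 0, "chr1", 0, 1000, "african"),
                    list("s2", 1, "chr1", 0, 1000, "european"))
  expect_equal(gene_window_ancestry(genes, half, 2 / 1000)$african, 0.5)
})

test_that("genes without overlapping segments are flagged as NA", {
  genes <- data.frame(gene_id = c("g1", "g2"),
                      chrom = c("chr1", "chrX"),
                      start = c(100, 100), end = c(200, 200),
                      category = c("non_mt", "non_mt"))
  segs <- seg_table(list("s1", 0, "chr1", 0, 1000, "african"),
                    list("s1", 1, "chr1", 0, 1000, "african"))
  expect_message(got <- gene_window_ancestry(genes, segs, 1 / 1000),
                 "flagged")
  expect_equal(got$african[1], 1.0)
  expect_true(is.na(got$african[2]))
  expect_equal(attr(got, "no_overlap"), "g2")
})

test_that("global ancestry from segments is the length-weighted dosage", {
  segs <- seg_table(list("s1", 0, "chr1", 0, 1000, "african"),
                    list("s1", 1, "chr1", 0, 1000, "african"))
  expect_equal(global_from_local(segs)$african, 1.0)
  half <- seg_table(list("s1", 0, "chr1", 0, 500, "african"),
                    list("s1", 0, "chr1", 500, 1000, "european"),
                    list("s1", 1, "chr1", 0, 1000, "european"))
  expect_equal(global_from_local(half)$african, 0.25)
  gap <- seg_table(list("s1", 0, "chr1", 0, 400, "african"),
                   list("s1", 0, "chr1", 500, 1000, "european"),
                   list("s1", 1, "chr1", 0, 1000, "european"))
  expect_error(global_from_local(gap), "tile")
})

test_that("window covering a whole single-chromosome genome equals global", {
  set.seed(20)
  rows <- list()
  for (s in c("a", "b", "c")) {
    for (h in 0:1) {
      cuts <- sort(sample(1:999, 3))
      edges <- c(0, cuts, 1000)
      for (i in 1:4) {
        rows[[length(rows) + 1]] <- list(
          s, h, "chr1", edges[i], edges[i + 1],
          sample(c("african", "european"), 1))
      }
    }
  }
  segs <- do.call(seg_table, rows)
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 450, end = 550,
                      category = "non_mt")
  gw <- gene_window_ancestry(genes, segs, window_mb = 10)  # >> chromosome
  expect_equal(gw$african, mean(global_from_local(segs)$african),
               tolerance = 1e-12)
})

test_that("block bootstrap recovers exact and shifted nulls", {
  # every gene value equal to the global mean: all deviations exactly 0
  vals <- rep(0.8, 30)
  cats <- rep(c("high_mt", "non_mt"), 15)
  bb <- block_bootstrap(vals, cats, global_mean = 0.8, n_resample = 10,
                        n_replicates = 200, seed = 1)
  expect_true(all(bb$high_mt$deviations == 0))
  expect_equal(bb$high_mt$ci95, c(0, 0))
  expect_equal(bb$high_mt$mean_deviation, 0)
  # CLT: replicate SD ~ gene-value SD / sqrt(n_resample) for iid values
  set.seed(2)
  vals2 <- rnorm(4000, 0.7, 0.05)
  bb2 <- block_bootstrap(vals2, rep("non_mt", 4000), global_mean = 0.7,
                         n_resample = 167, n_replicates = 4000, seed = 3)
  ratio <- sd(bb2$non_mt$deviations) / (sd(vals2) / sqrt(167))
  expect_lt(abs(ratio - 1), 0.05)
  # deviations are translation-consistent
  bb3 <- block_bootstrap(vals2 + 0.1, rep("non_mt", 4000),
                         global_mean = 0.8, n_resample = 167,
                         n_replicates = 500, seed = 4)
  bb4 <- block_bootstrap(vals2, rep("non_mt", 4000),
                         global_mean = 0.7, n_resample = 167,
                         n_replicates = 500, seed = 4)
  expect_equal(bb3$non_mt$deviations, bb4$non_mt$deviations,
               tolerance = 1e-12)
  expect_error(block_bootstrap(c(NA, 1), c("a", "b"), 0.5, 5, 10, 1),
               "no genes")
})

test_that("category t-test matches the pooled-variance closed form", {
  mk <- function(dev, cat) structure(
    list(category = cat, deviations = dev, mean_deviation = mean(dev),
         ci95 = quantile(dev, c(0.025, 0.975)), n_resample = 1L,
         n_replicates = length(dev), n_genes = 1L, seed = 1L),
    class = "bootstrap_dist")
  a <- c(0.1, 0.2, 0.15, 0.12, 0.18)
  b <- c(0.05, 0.08, 0.02, 0.06, 0.09)
  got <- category_ttest(mk(a, "high_mt"), mk(b, "non_mt"))
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 8), tolerance = 1e-12)
  same <- category_ttest(mk(a, "x"), mk(a, "y"))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # |t| grows with the replicate count for the same underlying data
  more <- category_ttest(mk(rep(a, 2), "x"), mk(rep(b, 2), "y"))
  expect_gt(abs(more$t), abs(got$t))
  expect_message(deg <- category_ttest(mk(rep(1, 3), "x"), mk(rep(1, 3), "y")),
                 "zero variance")
  expect_true(is.na(deg$t))
})

test_that("with no injected shift every category CI tends to contain 0", {
  hits <- 0L
  n_rep <- 6L
  for (i in seq_len(n_rep)) {
    cfg <- cohort_config(
      n_aa = 40L, n_ea = 0L, seed = 300L + i,
      chromosome_lengths = toy_chromosomes(6L, 1e8, 1.1),
      gene_counts = c(high_mt = 10L, low_mt = 15L, non_mt = 60L))
    anc <- simulate_global_ancestry(cfg)
    genes <- simulate_gene_annotation(cfg)
    segs <- simulate_local_tracts(cfg, anc, genes)
    # resample count matches the smallest category, as in the full analysis
    en <- run_enrichment(genes, segs, n_resample = 10L,
                         n_replicates = 1000L, seed = i)
    ok <- vapply(en$bootstrap, function(b) {
      b$ci95[1] <= 0 && 0 <= b$ci95[2]
    }, logical(1))
    hits <- hits + all(ok)
  }
  expect_gte(hits, n_rep - 1L)
})
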