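# Small configurations shared across tests. Kept deliberately tiny so the
# default suite stays fast; statistically demanding checks build their own.

small_config <- function(seed = 11L, n_aa = 25L, n_ea = 35L, ...) {
  cohort_config(
    n_aa = n_aa, n_ea = n_ea,
    chromosome_lengths = toy_chromosomes(n_chrom = 4L, length_bp = 5e7,
                                         morgans = 0.6),
    gene_counts = c(high_mt = 6L, low_mt = 10L, non_mt = 40L),
    seed = seed, ...)
}

# one-chromosome segment table builder for hand-constructed cases
seg_table <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], haplotype = as.integer(r[[2]]),
               chrom = r[[3]], start = as.numeric(r[[4]]),
               end = as.numeric(r[[5]]), ancestry = r[[6]],
               stringsAsFactors = FALSE)
  }))
}
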