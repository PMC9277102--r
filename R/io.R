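## All on-disk formats are plain TSV dialects. Coordinates are 0-based
## half-open internally; the MSP dialect (1-based inclusive) is converted at
## the read/write boundary.

#' Write / read an ADMIXTURE-style Q table
#'
#' Tab-separated table with columns `sample_id`, `african`, `european` (plus
#' optional further ancestry columns when K > 2). On read, samples whose
#' non-African/non-European remainder exceeds `tolerance` are rejected with a
#' warning (the two-way discordance model assumes a negligible contribution
#' from other ancestral populations); for retained samples the European
#' fraction is recomputed as `1 - african`.
#'
#' @param ancestry data.frame with columns `sample_id`, `african`,
#'   `european`.
#' @param path File path.
#' @param tolerance Largest tolerated remainder `1 - african - european`
#'   per sample (default 0.05).
#' @return `read_q_table()` returns a data.frame with columns `sample_id`,
#'   `african`, `european` (and `population` if present in the file);
#'   `write_q_table()` returns `path` invisibly.
#' @export
write_q_table <- function(ancestry, path) {
  stopifnot(is.data.frame(ancestry),
            all(c("sample_id", "african", "european") %in% names(ancestry)))
  fwrite(ancestry, path, sep = "\t")
  invisible(path)
}

#' @rdname write_q_table
#' @export
read_q_table <- function(path, tolerance = 0.05) {
  q <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("sample_id", "african", "european") %in% names(q))) {
    stop("Q table must have columns sample_id, african, european: ", path,
         call. = FALSE)
  }
  if (any(q$african < 0 | q$african > 1 | q$european < 0 | q$european > 1)) {
    stop("ancestry fractions outside [0, 1] in ", path, call. = FALSE)
  }
  remainder <- 1 - q$african - q$european
  bad <- abs(remainder) > tolerance
  if (any(bad)) {
    warning(sum(bad), " sample(s) rejected: other-ancestry remainder above ",
            tolerance, " (e.g. ", q$sample_id[bad][1L], ")", call. = FALSE)
    q <- q[!bad, , drop = FALSE]
  }
  q$european <- 1 - q$african
  keep <- intersect(c("sample_id", "population", "african", "european"),
                    names(q))
  q[, keep, drop = FALSE]
}

#' Write / read sample metadata
#'
#' Tab-separated table with columns `sample_id`, `population`, `age`,
#' `ischemic_time_min`, `sex`, `tissue`, `haplogroup`.
#'
#' @param meta Metadata data.frame.
#' @param path File path.
#' @return `read_sample_meta()` returns the data.frame;
#'   `write_sample_meta()` returns `path` invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  fwrite(meta, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  meta <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("sample metadata must have a sample_id column: ", path,
         call. = FALSE)
  }
  meta
}

#' Write / read a GCT v1.2 expression matrix
#'
#' The GCT v1.2 dialect: a `#1.2` version line, a `nrow<TAB>ncol` dimension
#' line, then a header `Name<TAB>Description<TAB>sample...` and one row per
#' gene. The reader validates the version line, that the dimension line
#' matches the parsed matrix, and that no TPM entry is negative.
#'
#' @param table An [expression_table()].
#' @param path File path.
#' @param tissue Tissue label to attach on read.
#' @return `read_gct()` returns an [expression_table()]; `write_gct()`
#'   returns `path` invisibly.
#' @export
write_gct <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(table$tpm), ncol(table$tpm), sep = "\t")),
             con)
  df <- data.frame(Name = rownames(table$tpm),
                   Description = table$tissue,
                   table$tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gct
#' @export
read_gct <- function(path, tissue = NA_character_) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || lines[1L] != "#1.2") {
    stop("not a GCT v1.2 file (missing '#1.2' header line): ", path,
         call. = FALSE)
  }
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(dims) != 2L || anyNA(dims)) {
    stop("malformed GCT dimension line (line 2): ", path, call. = FALSE)
  }
  body <- fread(path, sep = "\t", header = TRUE, skip = 2L,
                data.table = FALSE)
  if (!all(c("Name", "Description") %in% names(body)[1:2])) {
    stop("GCT header must start with Name, Description: ", path,
         call. = FALSE)
  }
  mat <- as.matrix(body[, -(1:2), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- body$Name
  if (nrow(mat) != dims[1L] || ncol(mat) != dims[2L]) {
    stop(sprintf(
      "GCT dimension line (line 2) says %d x %d but parsed %d x %d: %s",
      dims[1L], dims[2L], nrow(mat), ncol(mat), path), call. = FALSE)
  }
  if (any(mat < 0, na.rm = TRUE)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative TPM at gene '%s', sample '%s' in %s",
                 rownames(mat)[bad[1L]], colnames(mat)[bad[2L]], path),
         call. = FALSE)
  }
  if (is.na(tissue) && length(unique(body$Description)) == 1L) {
    tissue <- body$Description[1L]
  }
  expression_table(mat, tissue)
}

#' Write / read MSP-style local-ancestry tables
#'
#' The RFMix MSP dialect: a first comment line mapping subpopulation codes
#' (`#Subpopulation order/codes: african=0 european=1`), then a header
#' `#chm spos epos sgpos egpos n_snps <sample>.0 <sample>.1 ...` and one row
#' per genomic interval shared across samples, holding one ancestry code per
#' haplotype. Positions in the file are 1-based inclusive; they are converted
#' to the package's 0-based half-open convention on read (and back on write).
#' The writer disaggregates per-sample segments onto the union of all
#' breakpoints per chromosome; the reader merges consecutive equal-code rows
#' back into segments, so a write/read round trip is lossless.
#'
#' @param segments Segment table (`sample_id`, `haplotype`, `chrom`, `start`,
#'   `end`, `ancestry`).
#' @param path File path.
#' @return `read_msp()` returns a segment data.table; `write_msp()` returns
#'   `path` invisibly.
#' @export
write_msp <- function(segments, path) {
  seg <- validate_segments(segments)
  samples <- unique(seg$sample_id)
  haps <- paste0(rep(samples, each = 2L), ".", c(0L, 1L))
  rows <- list()
  for (ch in unique(seg$chrom)) {
    s <- seg[chrom == ch]
    edges <- sort(unique(c(s$start, s$end)))
    ivs <- data.table(start = utils::head(edges, -1L),
                      end = utils::tail(edges, -1L))
    mids <- (ivs$start + ivs$end) / 2
    codes <- matrix(NA_integer_, nrow = nrow(ivs), ncol = length(haps),
                    dimnames = list(NULL, haps))
    for (smp in samples) {
      for (h in c(0L, 1L)) {
        g <- s[sample_id == smp & haplotype == h]
        if (nrow(g) == 0L) {
          stop("sample ", smp, " haplotype ", h,
               " has no segments on ", ch, call. = FALSE)
        }
        idx <- findInterval(mids, g$start)
        if (any(idx < 1L) || any(mids >= g$end[idx])) {
          stop("segments of sample ", smp, " haplotype ", h,
               " do not cover chromosome ", ch, call. = FALSE)
        }
        codes[, paste0(smp, ".", h)] <-
          as.integer(g$ancestry[idx] == "european")
      }
    }
    rows[[ch]] <- data.table(
      `#chm` = ch,
      spos = ivs$start + 1L,           # 1-based inclusive on disk
      epos = ivs$end,
      sgpos = round((ivs$start + 1L) / 1e6, 4L),
      egpos = round(ivs$end / 1e6, 4L),
      `n snps` = pmax(1L, as.integer((ivs$end - ivs$start) / 1e4)),
      codes)
  }
  out <- rbindlist(rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#Subpopulation order/codes: african=0\teuropean=1", con)
  writeLines(paste(names(out), collapse = "\t"), con)
  close(con)
  on.exit()
  fwrite(out, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_msp
#' @export
read_msp <- function(path) {
  first <- readLines(path, n = 2L)
  if (length(first) < 2L ||
      !grepl("^#Subpopulation order/codes:", first[1L])) {
    stop("not an MSP file (missing subpopulation code line): ", path,
         call. = FALSE)
  }
  code_spec <- sub("^#Subpopulation order/codes:\\s*", "", first[1L])
  parts <- strsplit(code_spec, "[\t ]+")[[1L]]
  code_map <- list()
  for (p in parts) {
    kv <- strsplit(p, "=")[[1L]]
    code_map[[kv[2L]]] <- tolower(kv[1L])
  }
  pops <- unlist(code_map)
  if (!all(c("african", "european") %in%
           vapply(pops, function(x) {
             if (grepl("^afr", x)) "african" else
               if (grepl("^eur", x)) "european" else x
           }, ""))) {
    stop("MSP code line must map codes to African and European populations: ",
         first[1L], call. = FALSE)
  }
  norm_pop <- vapply(pops, function(x) {
    if (grepl("^afr", x)) "african" else if (grepl("^eur", x)) "european"
    else x
  }, "")
  header <- strsplit(sub("^#", "", first[2L]), "\t")[[1L]]
  body <- fread(path, sep = "\t", header = FALSE, skip = 2L)
  setnames(body, header)
  hap_cols <- setdiff(header, c("chm", "spos", "epos", "sgpos", "egpos",
                                "n snps"))
  pieces <- vector("list", length(hap_cols))
  for (k in seq_along(hap_cols)) {
    col <- hap_cols[k]
    dot <- regexpr("\\.[01]$", col)
    if (dot < 0L) stop("malformed haplotype column '", col, "'",
                       call. = FALSE)
    smp <- substr(col, 1L, dot - 1L)
    hap <- as.integer(substr(col, dot + 1L, nchar(col)))
    pieces[[k]] <- body[, .(
      sample_id = smp, haplotype = hap, chrom = chm,
      start = spos - 1L,               # to 0-based half-open
      end = epos,
      code = get(col))]
  }
  seg <- rbindlist(pieces)
  seg[, ancestry := norm_pop[as.character(code)]]
  seg[, code := NULL]
  setorder(seg, sample_id, haplotype, chrom, start)
  # merge consecutive intervals with identical ancestry
  seg[, grp := cumsum(c(1L, (ancestry[-1L] != ancestry[-.N]) |
                          (start[-1L] != end[-.N]))),
      by = .(sample_id, haplotype, chrom)]
  out <- seg[, .(start = min(start), end = max(end),
                 ancestry = ancestry[1L]),
             by = .(sample_id, haplotype, chrom, grp)]
  out[, grp := NULL]
  validate_segments(out)
}

#' Write / read a BED6 gene annotation
#'
#' BED with 0-based half-open coordinates and the functional category encoded
#' in the name field as `GENE|category` (`high_mt`, `low_mt` or `non_mt`).
#'
#' @param genes Annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `category`).
#' @param path File path.
#' @return `read_gene_bed()` returns the annotation data.frame;
#'   `write_gene_bed()` returns `path` invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "category") %in%
                  names(genes)))
  bed <- data.frame(chrom = genes$chrom, start = genes$start,
                    end = genes$end,
                    name = paste(genes$gene_id, genes$category, sep = "|"),
                    score = 0L, strand = "+", stringsAsFactors = FALSE)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  bed <- fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(bed) < 4L) stop("BED file needs >= 4 columns: ", path,
                           call. = FALSE)
  names(bed)[1:4] <- c("chrom", "start", "end", "name")
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("BED name field must be 'GENE|category': ", path, call. = FALSE)
  }
  category <- vapply(parts, `[`, "", 2L)
  ok <- category %in% c("high_mt", "low_mt", "non_mt")
  if (!all(ok)) {
    stop("unknown gene category '", category[!ok][1L], "' in ", path,
         call. = FALSE)
  }
  data.frame(gene_id = vapply(parts, `[`, "", 1L), chrom = bed$chrom,
             start = bed$start, end = bed$end, category = category,
             stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Emits the five on-disk artifacts the analysis pipeline consumes:
#' `metadata.tsv`, `q_table.tsv`, one `expression_<tissue>.gct` per tissue,
#' `local_ancestry.msp.tsv` and `genes.bed`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    metadata = file.path(dir, "metadata.tsv"),
    q_table = file.path(dir, "q_table.tsv"),
    msp = file.path(dir, "local_ancestry.msp.tsv"),
    bed = file.path(dir, "genes.bed"))
  write_sample_meta(cohort$samples, paths$metadata)
  write_q_table(cohort$global_ancestry, paths$q_table)
  write_msp(cohort$local_ancestry, paths$msp)
  write_gene_bed(cohort$genes, paths$bed)
  for (tissue in names(cohort$expression)) {
    p <- file.path(dir, sprintf("expression_%s.gct", tissue))
    write_gct(cohort$expression[[tissue]], p)
    paths[[paste0("expression_", tissue)]] <- p
  }
  invisible(paths)
}
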