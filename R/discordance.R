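#' Per-individual mitonuclear discordance
#'
#' Mitonuclear discordance is the fraction of an individual's global nuclear
#' genetic ancestry that does not match the continental origin of their mtDNA
#' haplogroup. Under a two-way (K = 2) African/European ancestry model:
#' a carrier of an African mtDNA lineage has discordance equal to the European
#' nuclear fraction (i.e. 1 - African fraction), and a carrier of a
#' European/Eurasian lineage has discordance equal to the African fraction.
#' The self-reported population plays no role in the formula.
#'
#' @param african Numeric vector of global African ancestry fractions in
#'   \eqn{[0,1]}.
#' @param designation Ancestry designation of the mtDNA haplogroup, as
#'   returned by [classify_haplogroup()]: `"african"` or
#'   `"european_eurasian"`. Recycled against `african` if length 1.
#'   `"excluded"` designations are an error: such samples must be removed.
#' @param european Numeric vector of European fractions; defaults to
#'   `1 - african` and must sum with `african` to 1 within `1e-6`.
#' @return Numeric vector of discordance values in \eqn{[0,1]}.
#' @examples
#' compute_discordance(0.75, "african") # 0.25
#' compute_discordance(0.30, "european_eurasian") # 0.30
#' @export
compute_discordance <- function(african, designation, european = 1 - african) {
  african <- as.numeric(african)
  european <- as.numeric(european)
  designation <- as.character(designation)
  if (length(designation) == 1L) {
    designation <- rep(designation, length(african))
  }
  if (length(african) != length(designation) ||
      length(african) != length(european)) {
    stop("african, european and designation must have matching lengths",
         call. = FALSE)
  }
  if (any(!is.finite(african)) || any(african < 0) || any(african > 1) ||
      any(!is.finite(european)) || any(european < 0) || any(european > 1)) {
    stop("ancestry fractions must be finite values in [0, 1]", call. = FALSE)
  }
  if (any(abs(african + european - 1) > 1e-6)) {
    stop("african + european fractions must sum to 1 within 1e-6",
         call. = FALSE)
  }
  if (any(designation == "excluded")) {
    stop("mtDNA designation 'excluded' at position(s) ",
         paste(utils::head(which(designation == "excluded"), 5L),
               collapse = ", "),
         ": remove these samples before computing discordance",
         call. = FALSE)
  }
  ok <- designation %in% c("african", "european_eurasian")
  if (!all(ok)) {
    stop("unknown mtDNA designation(s): ",
         paste(unique(designation[!ok]), collapse = ", "), call. = FALSE)
  }
  ifelse(designation == "african", european, african)
}

#' Build a per-sample discordance table
#'
#' Joins a global-ancestry (Q) table with sample metadata carrying haplogroup
#' labels, classifies each haplogroup, drops samples whose haplogroup falls
#' outside the two-way African/European model, and computes mitonuclear
#' discordance for the remainder.
#'
#' @param ancestry data.frame with columns `sample_id`, `african`, `european`
#'   (see [read_q_table()]).
#' @param meta data.frame with columns `sample_id`, `haplogroup` and
#'   optionally `population`.
#' @return data.frame with columns `sample_id`, `population`, `haplogroup`,
#'   `designation`, `discordance`, one row per retained sample, in the order
#'   of `ancestry`. The number of excluded samples is reported via a message
#'   and stored in the `n_excluded` attribute.
#' @export
discordance_table <- function(ancestry, meta) {
  stopifnot(is.data.frame(ancestry), is.data.frame(meta))
  need_a <- c("sample_id", "african", "european")
  if (!all(need_a %in% names(ancestry))) {
    stop("ancestry table must have columns ",
         paste(need_a, collapse = ", "), call. = FALSE)
  }
  if (!all(c("sample_id", "haplogroup") %in% names(meta))) {
    stop("meta table must have columns sample_id, haplogroup", call. = FALSE)
  }
  idx <- match(ancestry$sample_id, meta$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(utils::head(ancestry$sample_id[is.na(idx)], 5L),
               collapse = ", "), call. = FALSE)
  }
  designation <- classify_haplogroup(meta$haplogroup[idx])
  keep <- designation != "excluded"
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message(n_excluded, " sample(s) with a non-African, non-Eurasian ",
            "haplogroup excluded from the discordance analysis.")
  }
  population <- if ("population" %in% names(meta)) {
    as.character(meta$population[idx])
  } else {
    rep(NA_character_, nrow(ancestry))
  }
  out <- data.frame(
    sample_id   = ancestry$sample_id[keep],
    population  = population[keep],
    haplogroup  = as.character(meta$haplogroup[idx])[keep],
    designation = as.character(designation[keep]),
    discordance = compute_discordance(ancestry$african[keep],
                                      designation[keep],
                                      ancestry$european[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Summarize discordance by group
#'
#' Plain per-group moments and order statistics of the discordance values:
#' n, mean, median, unbiased (n-1) variance, min and max. With a single
#' record in a group the variance is reported as `NA`.
#'
#' @param records data.frame with a `discordance` column, e.g. from
#'   [discordance_table()].
#' @param by Name of the grouping column (default `"population"`).
#' @return data.frame with one row per group.
#' @export
summarize_discordance <- function(records, by = "population") {
  stopifnot(is.data.frame(records), "discordance" %in% names(records))
  if (!by %in% names(records)) {
    stop("grouping column '", by, "' not found", call. = FALSE)
  }
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  groups <- split(records$discordance, records[[by]], drop = TRUE)
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("empty group in discordance summary", call. = FALSE)
  }
  out <- data.frame(
    group    = names(groups),
    n        = vapply(groups, length, 1L),
    mean     = vapply(groups, mean, 1),
    median   = vapply(groups, stats::median, 1),
    variance = vapply(groups, function(x) {
      if (length(x) < 2L) NA_real_ else stats::var(x)
    }, 1),
    min      = vapply(groups, min, 1),
    max      = vapply(groups, max, 1),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  names(out)[1L] <- by
  out
}
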