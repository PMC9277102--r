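#' mtDNA haplogroup to continental ancestry designation
#'
#' Maps an mtDNA haplogroup label (e.g. `"L3e2b"`, `"H1c"`) to a continental
#' ancestry designation. The major haplogroup is taken to be the first
#' alphabetic character of the label: `L` lineages are of African origin;
#' `H, I, J, K, T, U, V, W, X` are of European/Eurasian origin; `A, B, C`
#' (Native American) and `M, N, R, F, Z` (Asian) fall outside the two-way
#' African/European ancestry model and are classified as `excluded` —
#' carriers of these haplogroups must be removed before computing
#' mitonuclear discordance. Any other leading letter is an error.
#'
#' Sub-haplogroup suffixes carry no ancestry information under this rule;
#' labels whose second character is also a letter (e.g. `"HV"`) resolve by
#' their first letter and are flagged with a message.
#'
#' @param haplogroup Character vector of haplogroup labels. Each must be a
#'   nonempty string beginning with a letter.
#' @return A factor with levels `african`, `european_eurasian`, `excluded`,
#'   one element per input label.
#' @examples
#' classify_haplogroup(c("L3e2b", "H1c", "B2"))
#' @export
classify_haplogroup <- function(haplogroup) {
  lv <- c("african", "european_eurasian", "excluded")
  if (length(haplogroup) == 0L) {
    return(factor(character(), levels = lv))
  }
  hg <- as.character(haplogroup)
  bad <- is.na(hg) | !grepl("^[A-Za-z]", hg)
  if (any(bad)) {
    stop("haplogroup labels must be nonempty strings starting with a letter; ",
         "offending input(s): ",
         paste(utils::head(sprintf("'%s'", hg[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  two_letter <- grepl("^[A-Za-z][A-Za-z]", hg)
  if (any(two_letter)) {
    message(sum(two_letter), " label(s) with a two-letter clade prefix ",
            "(e.g. '", hg[two_letter][1L],
            "') resolved by their first letter.")
  }
  letter <- toupper(substr(hg, 1L, 1L))
  des <- rep(NA_character_, length(letter))
  des[letter == "L"] <- "african"
  des[letter %in% c("H", "I", "J", "K", "T", "U", "V", "W", "X")] <-
    "european_eurasian"
  des[letter %in% c("A", "B", "C", "M", "N", "R", "F", "Z")] <- "excluded"
  if (anyNA(des)) {
    unk <- unique(hg[is.na(des)])
    stop("unrecognized major haplogroup letter in: ",
         paste(sprintf("'%s'", utils::head(unk, 5L)), collapse = ", "),
         call. = FALSE)
  }
  factor(des, levels = lv)
}
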