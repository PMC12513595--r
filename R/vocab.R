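# Vocabulary: drug-name lexicon and PT -> SOC dictionary.
#
# Both are plain two-column delimited files so that a licensed MedDRA
# export or a site-specific synonym table can be dropped in without code
# changes. The shipped dictionary is a synthetic stand-in with the same
# structure as a real export (primary-SOC convention: one SOC per PT).

#' Read a drug synonym lexicon
#'
#' A lexicon maps folded synonym text (trade names, research codes,
#' spelling variants) to one canonical drug name. Canonical names map to
#' themselves so that normalization is idempotent.
#'
#' @param path path to a two-column delimited file with columns
#'   `synonym` and `canonical`; `NULL` loads the lexicon shipped with the
#'   package.
#' @return tibble with columns `synonym` (folded) and `canonical`.
#' @export
#' @examples
#' lex <- read_drug_lexicon()
#' normalize_drug_name("GAZYVA", lex)
read_drug_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "drug_lexicon.tsv",
    package = "pvsignals", mustWork = TRUE
  )
  lex <- readr::read_tsv(path,
    comment = "#", col_types = readr::cols(.default = readr::col_character())
  )
  check_columns(lex, c("synonym", "canonical"), "drug lexicon")
  lex <- dplyr::mutate(lex, synonym = fold_text(.data$synonym))
  # every canonical name must be reachable from itself
  self <- tibble::tibble(
    synonym = fold_text(unique(lex$canonical)),
    canonical = unique(lex$canonical)
  )
  dplyr::distinct(dplyr::bind_rows(lex, self), .data$synonym, .keep_all = TRUE)
}

#' Normalize raw drug names against a lexicon
#'
#' Case-, whitespace- and punctuation-insensitive lookup. Unmatched names
#' are returned folded (never dropped) and flagged, so every report keeps
#' its drug rows.
#'
#' @param raw character vector of verbatim drug-name strings.
#' @param lexicon a lexicon tibble from [read_drug_lexicon()].
#' @return tibble with columns `raw`, `canonical`, `matched`.
#' @export
normalize_drug_name <- function(raw, lexicon = read_drug_lexicon()) {
  folded <- fold_text(raw)
  idx <- match(folded, lexicon$synonym)
  tibble::tibble(
    raw = as.character(raw),
    canonical = ifelse(is.na(idx), folded, lexicon$canonical[idx]),
    matched = !is.na(idx)
  )
}

#' Read a PT -> SOC dictionary
#'
#' @param path path to a two-column delimited file with columns `pt` and
#'   `soc`; `NULL` loads the synthetic stand-in shipped with the package.
#' @return tibble with columns `pt`, `soc` and a `version` attribute.
#' @export
read_pt_soc_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "meddra_standin_pt_soc.tsv",
    package = "pvsignals", mustWork = TRUE
  )
  header <- readLines(path, n = 5)
  version <- sub("^#\\s*version:\\s*", "", grep("^#\\s*version:", header, value = TRUE))
  dict <- readr::read_tsv(path,
    comment = "#", col_types = readr::cols(.default = readr::col_character())
  )
  check_columns(dict, c("pt", "soc"), "PT/SOC dictionary")
  if (anyDuplicated(fold_text(dict$pt)) > 0) {
    rlang::abort("PT/SOC dictionary maps some PT to more than one SOC")
  }
  attr(dict, "version") <- if (length(version) > 0) version[[1]] else "unversioned"
  dict
}

#' Map preferred terms to system organ classes
#'
#' Exact lookup after text folding. PTs absent from the dictionary map to
#' the sentinel SOC `"Unmapped"`; one warning summarises how many.
#'
#' @param pt character vector of PT names.
#' @param dict dictionary tibble from [read_pt_soc_dictionary()].
#' @return character vector of SOC names, same length as `pt`.
#' @export
map_pt_to_soc <- function(pt, dict = read_pt_soc_dictionary()) {
  idx <- match(fold_text(pt), fold_text(dict$pt))
  n_unmapped <- sum(is.na(idx) & !is.na(pt))
  if (n_unmapped > 0) {
    rlang::warn(sprintf("%d PT value(s) not in the dictionary; mapped to 'Unmapped'", n_unmapped))
  }
  ifelse(is.na(idx), "Unmapped", dict$soc[idx])
}

#' Tumor / non-tumor indication lexicon
#'
#' Keyword lists used to classify free-text indications into tumor and
#' non-tumor strata. Matching is by case-folded substring containment;
#' the two lists must be disjoint.
#'
#' @param tumor,non_tumor character vectors of keywords.
#' @return object of class `indication_lexicon`.
#' @export
indication_lexicon <- function(
    tumor = c(
      "lymphoma", "leukaemia", "leukemia", "macroglobulinaemia",
      "macroglobulinemia", "neoplasm"
    ),
    non_tumor = c(
      "nephritis", "nephrotic", "lupus", "glomerulonephritis"
    )) {
  tumor <- fold_text(tumor)
  non_tumor <- fold_text(non_tumor)
  overlap <- intersect(tumor, non_tumor)
  if (length(overlap) > 0) {
    rlang::abort(paste0(
      "tumor and non-tumor keyword lists overlap: ",
      paste(overlap, collapse = ", ")
    ))
  }
  structure(list(tumor = tumor, non_tumor = non_tumor),
    class = "indication_lexicon"
  )
}
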