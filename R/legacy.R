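# Concordance of five legacy fossa terminologies with the landmark-based
# names, shipped as a versioned TSV (one row per authority/term/modern-name
# triple; cells joined with "+" or ";" in the source table yield one row per
# term). Excluded source terms (see concordance_notes) are deliberately not
# entries.

.authorities <- c("hatcher1901", "osborn_mook1921", "welles1984",
                  "bonaparte1999", "harris2006")

#' The packaged legacy-terminology concordance
#'
#' @return A data frame with columns `authority`, `legacy_term`,
#'   `modern_abbrev`, `note`.
#' @examples
#' head(concordance())
#' @export
concordance <- function() {
  path <- system.file("extdata", "concordance_table1.tsv", package = "fossanom")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "concordance_table1.tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$note[is.na(df$note)] <- ""
  df
}

#' Notes on terms excluded from the concordance
#'
#' Three source terms are attested but excluded from the concordance because
#' they do not name landmark-bounded fossae in the modern sense: Hatcher's
#' "spinal cavities" (small irregular pockets in the spinal laminae),
#' Welles's "lateral chonos" (not distinguishable from the medial chonos),
#' and Bonaparte's "angular cavity" (apparently a fossa within a divided
#' cpol, i.e. cpol-f).
#'
#' @return A data frame with columns `authority`, `term`, `reason`.
#' @export
concordance_notes <- function() {
  data.frame(
    authority = c("hatcher1901", "welles1984", "bonaparte1999"),
    term = c("spinal cavities", "lateral chonos", "angular cavity"),
    reason = c(
      "small, irregular pockets in the laminae of the neural spine; not landmark-bounded",
      "not distinguishable from the medial chonos",
      "appears to name a fossa within a divided cpol (cpol-f)"),
    stringsAsFactors = FALSE
  )
}

.check_authority <- function(authority) {
  if (!authority %in% .authorities)
    stop("unknown authority: ", authority, " (known: ",
         paste(.authorities, collapse = ", "), ")", call. = FALSE)
  invisible(authority)
}

.norm_term <- function(x) gsub("\\s+", " ", trimws(tolower(x)))

#' Translate a legacy fossa term to modern abbreviations
#'
#' Matching is case-insensitive and whitespace-normalized. Because legacy
#' usage is ambiguous, the result is a set: the union of modern names over
#' all concordance rows matching the (authority, term) pair.
#'
#' @param term Legacy term, e.g. "infradiapophyseal cavity".
#' @param authority One of hatcher1901, osborn_mook1921, welles1984,
#'   bonaparte1999, harris2006.
#' @return Character vector of abbreviations; empty, with attribute
#'   `not_in_concordance = TRUE`, if the term is unattested for that
#'   authority.
#' @examples
#' translate_term("infradiapophyseal fossa", "harris2006")  # cdf, pacdf
#' @export
translate_term <- function(term, authority) {
  .check_authority(authority)
  df <- concordance()
  hit <- df$authority == authority & .norm_term(df$legacy_term) == .norm_term(term)
  out <- sort(unique(df$modern_abbrev[hit]))
  if (!length(out)) attr(out, "not_in_concordance") <- TRUE
  out
}

#' Legacy terms of an authority for a modern fossa name
#'
#' @param abbreviation A table1-catalogue abbreviation.
#' @param authority Authority id.
#' @return Character vector of legacy terms (empty where the source cell
#'   is em-dash).
#' @examples
#' reverse_translate("cdf", "welles1984")  # "medial chonos"
#' @export
reverse_translate <- function(abbreviation, authority) {
  .check_authority(authority)
  table1 <- vapply(enumerate_catalogue("table1")$names, `[[`, "", "abbreviation")
  if (!abbreviation %in% table1)
    stop("unknown abbreviation: ", abbreviation,
         " is not in the table1 catalogue", call. = FALSE)
  df <- concordance()
  hit <- df$authority == authority & df$modern_abbrev == abbreviation
  sort(unique(df$legacy_term[hit]))
}

#' Number of distinct legacy terms per authority
#'
#' Duplicated terms (the same term applied to several modern fossae) count
#' once; terms that were "+"-joined in one source cell count separately.
#' Note that the source total for welles1984 ("9 chonoses") exceeds the
#' tabulated terms: only 7 appear in the table and an eighth ("lateral
#' chonos") is excluded by footnote; `count_terms` reports table content.
#'
#' @param authority Authority id.
#' @return Integer count.
#' @examples
#' count_terms("hatcher1901")  # 8
#' @export
count_terms <- function(authority) {
  .check_authority(authority)
  df <- concordance()
  length(unique(df$legacy_term[df$authority == authority]))
}
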