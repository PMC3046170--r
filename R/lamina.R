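#' Catalogue of vertebral laminae
#'
#' The fixed catalogue of neural arch laminae (following the conventions of
#' the standard lamina nomenclature) that may bound fossae. Each lamina
#' connects two landmarks, except the midline prespinal and postspinal
#' laminae, which emanate from the neural spine alone. The
#' epipophyseal-prezygapophyseal lamina (eprl) runs from the prezygapophysis
#' to the epipophysis, a process on the postzygapophysis; the epipophysis is
#' modeled as part of the postzygapophysis node, not a seventh landmark.
#'
#' @return A data frame with columns `abbreviation`, `full_name`, `end1`,
#'   `end2` (landmark codes; `end2` is `NA` for midline laminae), `modifier`
#'   (`none`/`anterior`/`posterior`), `midline`, `divisible` (attested as
#'   occurring divided), and `epipophyseal` (TRUE for the eprl, whose po
#'   endpoint is the epipophysis).
#' @examples
#' lamina_catalogue()
#' @export
lamina_catalogue <- function() {
  df <- rbind(
    data.frame(abbreviation = "acdl", full_name = "anterior centrodiapophyseal lamina",
               end1 = "c", end2 = "d", modifier = "anterior", midline = FALSE,
               divisible = FALSE),
    data.frame(abbreviation = "pcdl", full_name = "posterior centrodiapophyseal lamina",
               end1 = "c", end2 = "d", modifier = "posterior", midline = FALSE,
               divisible = TRUE),
    data.frame(abbreviation = "cprl", full_name = "centroprezygapophyseal lamina",
               end1 = "c", end2 = "pr", modifier = "none", midline = FALSE,
               divisible = TRUE),
    data.frame(abbreviation = "cpol", full_name = "centropostzygapophyseal lamina",
               end1 = "c", end2 = "po", modifier = "none", midline = FALSE,
               divisible = TRUE),
    data.frame(abbreviation = "prdl", full_name = "prezygodiapophyseal lamina",
               end1 = "pr", end2 = "d", modifier = "none", midline = FALSE,
               divisible = TRUE),
    data.frame(abbreviation = "podl", full_name = "postzygodiapophyseal lamina",
               end1 = "po", end2 = "d", modifier = "none", midline = FALSE,
               divisible = FALSE),
    data.frame(abbreviation = "sprl", full_name = "spinoprezygapophyseal lamina",
               end1 = "s", end2 = "pr", modifier = "none", midline = FALSE,
               divisible = FALSE),
    data.frame(abbreviation = "spol", full_name = "spinopostzygapophyseal lamina",
               end1 = "s", end2 = "po", modifier = "none", midline = FALSE,
               divisible = TRUE),
    data.frame(abbreviation = "spdl", full_name = "spinodiapophyseal lamina",
               end1 = "s", end2 = "d", modifier = "none", midline = FALSE,
               divisible = TRUE),
    data.frame(abbreviation = "ppdl", full_name = "paradiapophyseal lamina",
               end1 = "pa", end2 = "d", modifier = "none", midline = FALSE,
               divisible = TRUE),
    data.frame(abbreviation = "acpl", full_name = "anterior centroparapophyseal lamina",
               end1 = "c", end2 = "pa", modifier = "anterior", midline = FALSE,
               divisible = FALSE),
    data.frame(abbreviation = "pcpl", full_name = "posterior centroparapophyseal lamina",
               end1 = "c", end2 = "pa", modifier = "posterior", midline = FALSE,
               divisible = FALSE),
    data.frame(abbreviation = "prpl", full_name = "prezygoparapophyseal lamina",
               end1 = "pr", end2 = "pa", modifier = "none", midline = FALSE,
               divisible = FALSE),
    data.frame(abbreviation = "eprl", full_name = "epipophyseal-prezygapophyseal lamina",
               end1 = "po", end2 = "pr", modifier = "none", midline = FALSE,
               divisible = FALSE),
    data.frame(abbreviation = "prsl", full_name = "prespinal lamina",
               end1 = "s", end2 = NA_character_, modifier = "anterior", midline = TRUE,
               divisible = FALSE),
    data.frame(abbreviation = "posl", full_name = "postspinal lamina",
               end1 = "s", end2 = NA_character_, modifier = "posterior", midline = TRUE,
               divisible = FALSE)
  )
  df$epipophyseal <- df$abbreviation == "eprl"
  df
}

# accepted spelling variants on input (never emitted)
.lamina_name_variants <- c(
  "parapodiapophyseal lamina" = "ppdl"
)

.lamina_lookup <- function(label) {
  cat <- lamina_catalogue()
  i <- match(label, cat$abbreviation)
  if (is.na(i)) stop("unknown lamina label: ", label, call. = FALSE)
  cat[i, ]
}

#' Landmark endpoints of a lamina
#'
#' @param label Lamina abbreviation, e.g. `"acpl"`.
#' @return Character vector of landmark codes; midline laminae (prsl, posl)
#'   return `"s"` alone.
#' @examples
#' lamina_endpoints("acpl")  # c, pa
#' lamina_endpoints("prsl")  # s
#' @export
lamina_endpoints <- function(label) {
  row <- .lamina_lookup(label)
  ends <- c(row$end1, row$end2)
  unique(ends[!is.na(ends)])
}

lamina_full_name <- function(label) .lamina_lookup(label)$full_name

#' Zone of a lamina relative to the zygodiapophyseal table
#'
#' Spinal laminae (any endpoint on the neural spine) lie above the table;
#' laminae reaching the centrum or parapophysis and not the spine lie below
#' it. The laminae that run in the table plane itself (prdl, podl, eprl)
#' have no intrinsic zone; by convention they are assigned below the table,
#' which places the intralaminar fossae of e.g. a divided prdl with the
#' diapophyseal fossae. Set `table_plane = "above"` to override.
#'
#' @param label Lamina abbreviation.
#' @param table_plane Zone assigned to table-plane laminae, `"below"`
#'   (default) or `"above"`.
#' @return `"above_table"` or `"below_table"`.
#' @examples
#' zone_of_lamina("spol")  # above_table
#' zone_of_lamina("cprl")  # below_table
#' @export
zone_of_lamina <- function(label, table_plane = c("below", "above")) {
  table_plane <- match.arg(table_plane)
  ends <- lamina_endpoints(label)
  if ("s" %in% ends) return("above_table")
  if (any(c("c", "pa") %in% ends)) return("below_table")
  paste0(table_plane, "_table")   # prdl, podl, eprl
}

#' Export the lamina catalogue as TSV
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_lamina_catalogue <- function(path) {
  utils::write.table(lamina_catalogue(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
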