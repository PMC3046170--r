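# Complexity scoring: count unique fossae above and below the
# zygodiapophyseal table. A unique fossa is a midline fossa or one member of
# a left/right pair; a midline fossa divided (by the prespinal/postspinal
# lamina) counts as two.

#' Construct a fossa inventory
#'
#' @param items Data frame with columns `abbreviation`, `laterality`
#'   (`"midline"`/`"paired"`), `divided` (logical).
#' @param taxon,position Metadata.
#' @return A `fossa_inventory`.
#' @export
new_fossa_inventory <- function(items, taxon = "", position = "") {
  stopifnot(is.data.frame(items),
            all(c("abbreviation", "laterality", "divided") %in% names(items)))
  if (nrow(items)) {
    stopifnot(all(items$laterality %in% c("midline", "paired")),
              is.logical(items$divided))
    for (ab in items$abbreviation) parse_name(ab)   # must be parseable
    has_sdf <- "sdf" %in% items$abbreviation
    has_sub <- any(c("sdf1", "sdf2") %in% items$abbreviation)
    if (has_sdf && has_sub)
      stop("inconsistent inventory: a vertebra has either the undivided sdf ",
           "or its subdivisions sdf1/sdf2, not both", call. = FALSE)
  }
  structure(items, class = c("fossa_inventory", "data.frame"),
            taxon = taxon, position = position)
}

#' Zone of a fossa relative to the zygodiapophyseal table
#'
#' Names containing the neural spine (and the sdf subdivisions sdf1/sdf2)
#' lie above the table; names containing the centrum or parapophysis and no
#' spine lie below it; intralaminar fossae take the zone of their parent
#' lamina (see [zone_of_lamina()] for the table-plane convention).
#'
#' @param abbreviation Fossa abbreviation.
#' @param table_plane Passed to [zone_of_lamina()] for intralaminar names.
#' @return `"above_table"` or `"below_table"`.
#' @examples
#' zone_of("sprf")   # above_table
#' zone_of("pocdf")  # below_table
#' @export
zone_of <- function(abbreviation, table_plane = c("below", "above")) {
  table_plane <- match.arg(table_plane)
  nm <- parse_name(abbreviation)
  if (nm$special %in% c("sdf1", "sdf2")) return("above_table")
  if (nm$special == "intralaminar")
    return(zone_of_lamina(nm$parent_lamina, table_plane))
  codes <- c(nm$primary, nm$secondary, nm$tertiary)
  if ("s" %in% codes) return("above_table")
  if (any(c("c", "pa") %in% codes)) return("below_table")
  "below_table"
}

#' Score the fossa complexity of a vertebra
#'
#' Each inventory item weighs 1, except a divided midline item, which weighs
#' 2 (its two halves are distinct unique fossae); weights are summed above
#' and below the zygodiapophyseal table. Bilaterally divided paired items
#' are not double-counted: a pair still contributes one unique fossa.
#'
#' @param inventory A `fossa_inventory` (or data frame with the same
#'   columns).
#' @param table_plane Zone convention for table-plane intralaminar fossae.
#' @return A `complexity_score`: list with integer elements `above` and
#'   `below`.
#' @examples
#' inv <- new_fossa_inventory(data.frame(
#'   abbreviation = c("sprf", "spof", "prsdf", "posdf"),
#'   laterality = c("midline", "midline", "paired", "paired"),
#'   divided = FALSE))
#' complexity_score(inv)  # above = 4, below = 0
#' @export
complexity_score <- function(inventory, table_plane = c("below", "above")) {
  table_plane <- match.arg(table_plane)
  if (!inherits(inventory, "fossa_inventory"))
    inventory <- new_fossa_inventory(inventory)
  above <- 0L; below <- 0L
  for (i in seq_len(nrow(inventory))) {
    w <- if (inventory$divided[i] && inventory$laterality[i] == "midline") 2L else 1L
    if (zone_of(inventory$abbreviation[i], table_plane) == "above_table")
      above <- above + w else below <- below + w
  }
  structure(list(above = above, below = below,
                 taxon = attr(inventory, "taxon"),
                 position = attr(inventory, "position")),
            class = "complexity_score")
}

#' @export
print.complexity_score <- function(x, ...) {
  cat("Fossa complexity", if (nzchar(x$taxon %||% "")) paste0(" (", x$taxon,
      if (nzchar(x$position %||% "")) paste0(" ", x$position), ")"),
      ": ", x$above, " unique fossae above the table, ",
      x$below, " below\n", sep = "")
  invisible(x)
}

#' Read and write fossa-inventory tables
#'
#' The TSV format has columns `taxon`, `position`, `abbreviation`,
#' `laterality`, `divided`; one row per inventory item, multiple vertebrae
#' distinguished by taxon/position.
#'
#' @param path File path.
#' @return `read_inventories()` returns a list of `fossa_inventory` objects,
#'   one per distinct (taxon, position).
#' @export
read_inventories <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon", "position", "abbreviation", "laterality", "divided")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("inventory file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$divided <- as.logical(df$divided)
  key <- paste(df$taxon, df$position, sep = "\r")
  lapply(split(df, key), function(sub)
    new_fossa_inventory(sub[, c("abbreviation", "laterality", "divided")],
                        taxon = sub$taxon[1], position = sub$position[1]))
}

#' @rdname read_inventories
#' @param inventories List of `fossa_inventory` objects.
#' @param table_plane Zone convention for table-plane intralaminar fossae.
#' @return `write_complexity_scores()` writes a TSV (taxon, position, above,
#'   below) and returns the data frame invisibly.
#' @export
write_complexity_scores <- function(inventories, path,
                                    table_plane = c("below", "above")) {
  table_plane <- match.arg(table_plane)
  rows <- lapply(inventories, function(inv) {
    sc <- complexity_score(inv, table_plane)
    data.frame(taxon = attr(inv, "taxon"), position = attr(inv, "position"),
               above = sc$above, below = sc$below, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
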