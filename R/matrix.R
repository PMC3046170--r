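# Presence/absence character-matrix export for phylogenetic analysis: one
# character per catalogue fossa name per vertebral position-class
# (cervical/dorsal/caudal); 1 = present in a scored vertebra, 0 = the class
# was scored for the taxon and the fossa absent, ? = class unscored.
# Coding is presence/absence only; no ordered-multistate scheme is invented.

.position_class <- function(position) {
  p <- tolower(trimws(position))
  if (grepl("^(cv|cervical)", p)) return("cervical")
  if (grepl("^(dv|dorsal)", p)) return("dorsal")
  if (grepl("^(ca|caudal)", p)) return("caudal")
  NA_character_
}

#' Build a presence/absence character matrix from fossa inventories
#'
#' @param inventories List of `fossa_inventory` objects (each with taxon and
#'   position attributes; positions are mapped to the classes
#'   cervical/dorsal/caudal).
#' @param mode Catalogue mode supplying the character list.
#' @return A `character_matrix`: list with `taxa`, `characters` (data frame
#'   abbreviation x position_class), and `cells` (character matrix of
#'   "0"/"1"/"?").
#' @export
character_matrix <- function(inventories, mode = "table1") {
  if (!length(inventories)) stop("empty input: no inventories", call. = FALSE)
  stopifnot(all(vapply(inventories, inherits, logical(1), "fossa_inventory")))
  taxa <- vapply(inventories, attr, "", "taxon")
  pos <- vapply(inventories, attr, "", "position")
  cls <- vapply(pos, .position_class, "")
  if (anyNA(cls))
    stop("position not mappable to cervical/dorsal/caudal: ",
         paste(pos[is.na(cls)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(paste(taxa, pos)))
    stop("duplicate taxon/position rows", call. = FALSE)

  abbr <- vapply(enumerate_catalogue(mode)$names, `[[`, "", "abbreviation")
  chars <- expand.grid(abbreviation = abbr,
                       position_class = c("cervical", "dorsal", "caudal"),
                       stringsAsFactors = FALSE)
  utaxa <- unique(taxa)
  cells <- matrix("?", nrow = length(utaxa), ncol = nrow(chars),
                  dimnames = list(utaxa, paste(chars$abbreviation,
                                               chars$position_class, sep = ".")))
  for (t in utaxa) {
    for (cl in c("cervical", "dorsal", "caudal")) {
      idx <- which(taxa == t & cls == cl)
      if (!length(idx)) next   # class unscored for this taxon -> "?"
      present <- unique(unlist(lapply(inventories[idx],
                                      function(inv) inv$abbreviation)))
      col <- chars$position_class == cl
      cells[t, col] <- ifelse(chars$abbreviation[col] %in% present, "1", "0")
    }
  }
  structure(list(taxa = utaxa, characters = chars, cells = cells),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix: ", length(x$taxa), " taxa x ", nrow(x$characters),
      " characters (presence/absence, ? = missing)\n", sep = "")
  invisible(x)
}

#' Export a character matrix
#'
#' TSV output is a rectangular table (taxon column plus one column per
#' character). NEXUS output is a DATA block with `symbols="01"` and
#' `missing=?`, readable by standard phylogenetics software.
#'
#' @param inventories List of `fossa_inventory` objects, or a
#'   `character_matrix`.
#' @param path Output path.
#' @param mode Catalogue mode (ignored when a matrix is given).
#' @param format `"nexus"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
export_character_matrix <- function(inventories, path, mode = "table1",
                                    format = c("nexus", "tsv")) {
  format <- match.arg(format)
  cm <- if (inherits(inventories, "character_matrix")) inventories
        else character_matrix(inventories, mode)
  if (format == "tsv") {
    df <- data.frame(taxon = cm$taxa, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(cm$cells, stringsAsFactors = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lab <- gsub("[^A-Za-z0-9_.]", "_", cm$taxa)
    pad <- formatC(lab, width = max(nchar(lab)), flag = "-")
    lines <- c(
      "#NEXUS",
      "BEGIN DATA;",
      paste0("  DIMENSIONS NTAX=", length(cm$taxa),
             " NCHAR=", nrow(cm$characters), ";"),
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
      "  MATRIX",
      paste0("    ", pad, "  ",
             apply(cm$cells, 1, paste, collapse = "")),
      "  ;",
      "END;"
    )
    writeLines(lines, path)
  }
  invisible(path)
}
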