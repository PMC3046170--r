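#' Enumerate the fossa-name catalogue
#'
#' Three catalogue modes:
#' \describe{
#'   \item{base}{the six bipartite names (primary d/pr/po crossed with
#'     secondary s/c) plus the six tripartite extensions that pass the
#'     compatibility predicate — no parapophyseal promotion.}
#'   \item{extended}{base plus the three parapophyseal-promotion names
#'     cpaf, padf and prpadf: eight bipartite and seven tripartite names.}
#'   \item{table1}{the sixteen names attested in the published concordance:
#'     extended minus padf, plus the sdf subdivisions sdf1 and sdf2
#'     (intralaminar names are excluded from every catalogue).}
#' }
#' Ordering is deterministic: bipartite (and special) names before
#' tripartite, then lexicographic by abbreviation.
#'
#' @param mode One of `"base"`, `"extended"`, `"table1"`.
#' @return A `name_catalogue`: list with elements `mode` and `names`
#'   (list of `fossa_name`).
#' @examples
#' length(enumerate_catalogue("table1")$names)  # 16
#' @export
enumerate_catalogue <- function(mode = c("base", "extended", "table1")) {
  mode <- match.arg(mode)

  names_list <- list()
  for (primary in c("d", "pr", "po")) {
    for (secondary in c("s", "c")) {
      names_list <- c(names_list,
                      list(new_fossa_name(primary = primary, secondary = secondary)))
      for (tertiary in c("pa", "pr", "po")) {
        if (tertiary %in% c(primary, secondary)) next
        if (!roles_compatible(primary, secondary, tertiary)) next
        names_list <- c(names_list,
                        list(new_fossa_name(primary = primary, secondary = secondary,
                                            tertiary = tertiary)))
      }
    }
  }

  if (mode %in% c("extended", "table1")) {
    names_list <- c(names_list, list(
      new_fossa_name(primary = "pa", secondary = "c"),              # cpaf
      new_fossa_name(primary = "d", secondary = "pa"),              # padf
      new_fossa_name(primary = "d", secondary = "pa", tertiary = "pr")  # prpadf
    ))
  }
  if (mode == "table1") {
    abbr <- vapply(names_list, `[[`, "", "abbreviation")
    names_list <- names_list[abbr != "padf"]
    names_list <- c(names_list, list(new_fossa_name(special = "sdf1"),
                                     new_fossa_name(special = "sdf2")))
  }

  abbr <- vapply(names_list, `[[`, "", "abbreviation")
  tripartite <- vapply(names_list, function(x) !is.null(x$tertiary), logical(1))
  ord <- order(tripartite, abbr, method = "radix")
  names_list <- names_list[ord]

  abbr <- vapply(names_list, `[[`, "", "abbreviation")
  stopifnot(!anyDuplicated(abbr))

  structure(list(mode = mode, names = names_list), class = "name_catalogue")
}

#' @export
print.name_catalogue <- function(x, ...) {
  cat("Fossa name catalogue (mode = ", x$mode, "): ",
      length(x$names), " names\n", sep = "")
  df <- as.data.frame(x)
  print(df[, c("abbreviation", "full_name")], right = FALSE)
  invisible(x)
}

#' @export
as.data.frame.name_catalogue <- function(x, ...) {
  catalogue_table(x)
}

#' Tabulate a name catalogue
#'
#' @param catalogue A `name_catalogue` from [enumerate_catalogue()], or a
#'   mode string.
#' @return A data frame with columns `abbreviation`, `full_name`, `primary`,
#'   `secondary`, `tertiary`, `special`, and logical membership columns
#'   `in_base`, `in_extended`, `in_table1`.
#' @export
catalogue_table <- function(catalogue = "table1") {
  if (is.character(catalogue)) catalogue <- enumerate_catalogue(catalogue)
  stopifnot(inherits(catalogue, "name_catalogue"))
  grab <- function(nm, field) nm[[field]] %||% NA_character_
  membership <- lapply(c("base", "extended", "table1"), function(m)
    vapply(enumerate_catalogue(m)$names, `[[`, "", "abbreviation"))
  names(membership) <- c("base", "extended", "table1")
  df <- do.call(rbind, lapply(catalogue$names, function(nm) {
    data.frame(abbreviation = nm$abbreviation,
               full_name    = nm$full_name,
               primary      = grab(nm, "primary"),
               secondary    = grab(nm, "secondary"),
               tertiary     = grab(nm, "tertiary"),
               special      = nm$special,
               stringsAsFactors = FALSE)
  }))
  df$in_base     <- df$abbreviation %in% membership$base
  df$in_extended <- df$abbreviation %in% membership$extended
  df$in_table1   <- df$abbreviation %in% membership$table1
  df
}

#' Export a name catalogue as TSV
#'
#' @param mode Catalogue mode.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_catalogue <- function(mode, path) {
  utils::write.table(catalogue_table(mode), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
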