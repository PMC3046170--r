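#' @keywords internal
new_fossa_name <- function(primary = NULL, secondary = NULL, tertiary = NULL,
                           special = "none", parent_lamina = NULL) {
  x <- structure(
    list(primary = primary, secondary = secondary, tertiary = tertiary,
         special = special, parent_lamina = parent_lamina),
    class = "fossa_name"
  )
  x$abbreviation <- fossa_abbreviation(x)
  x$full_name <- fossa_full_name(x)
  x
}

fossa_abbreviation <- function(x) {
  switch(x$special,
    sdf1 = "sdf1",
    sdf2 = "sdf2",
    intralaminar = paste0(x$parent_lamina, "-f"),
    paste0(x$tertiary %||% "", x$secondary %||% "", x$primary %||% "", "f")
  )
}

fossa_full_name <- function(x) {
  switch(x$special,
    sdf1 = "spinodiapophyseal fossa 1",
    sdf2 = "spinodiapophyseal fossa 2",
    intralaminar = paste(lamina_full_name(x$parent_lamina), "fossa"),
    {
      stem <- paste0(.secondary_form[x$secondary] %||% "",
                     .primary_form[x$primary])
      if (is.null(x$tertiary)) paste(stem, "fossa")
      else paste(.tertiary_form[x$tertiary], stem, "fossa")
    }
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' @export
print.fossa_name <- function(x, ...) {
  cat(x$abbreviation, "\t", x$full_name, "\n", sep = "")
  if (x$special == "none") {
    parts <- c(primary = x$primary %||% NA, secondary = x$secondary %||% NA,
               tertiary = x$tertiary %||% NA)
    parts <- parts[!is.na(parts)]
    cat("  ", paste(names(parts), parts, sep = " = ", collapse = ", "), "\n", sep = "")
  } else {
    cat("  special case: ", x$special,
        if (x$special == "intralaminar") paste0(" (within divided ", x$parent_lamina, ")"),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.fossa_name <- function(x, ...) x$abbreviation

#' @export
as.character.fossa_name <- function(x, ...) x$abbreviation

# ---------------------------------------------------------------------------
# compatibility predicate
#
# A (tertiary, secondary, primary) role assignment is geometrically possible
# only if the landmarks are not at opposite ends of the vertebra:
#   * tertiary pr is incompatible with primary po, and vice versa;
#   * pa (in tertiary or secondary role) is incompatible with secondary s
#     and with primary po;
#   * pa as a secondary landmark occurs only beneath the diapophysis
#     (primary d).
# These rules reproduce exactly the attested tripartite set
# {pacdf, prcdf, pocdf, prsdf, posdf, pacprf}.

roles_compatible <- function(primary, secondary = NULL, tertiary = NULL) {
  msg <- roles_incompatibility(primary, secondary, tertiary)
  is.null(msg)
}

roles_incompatibility <- function(primary, secondary = NULL, tertiary = NULL) {
  has <- function(x) !is.null(x) && length(x) == 1 && !is.na(x)
  if (has(tertiary) && tertiary == "pr" && primary == "po")
    return("tertiary pr cannot combine with primary po (opposite ends)")
  if (has(tertiary) && tertiary == "po" && primary == "pr")
    return("tertiary po cannot combine with primary pr (opposite ends)")
  pa_role <- primary == "pa" ||
    (has(tertiary) && tertiary == "pa") || (has(secondary) && secondary == "pa")
  if (pa_role && has(secondary) && secondary == "s")
    return("parapophysis cannot combine with secondary s (opposite sides of the table)")
  if (pa_role && primary == "po")
    return("parapophysis cannot combine with primary po (opposite ends)")
  if (has(secondary) && secondary == "pa" && primary != "d")
    return("secondary pa occurs only with primary d")
  NULL
}

# ---------------------------------------------------------------------------

#' Compose a fossa name from a set of landmarks
#'
#' Builds the canonical fossa name for a set of 2-4 bounding landmarks by the
#' role-assignment algorithm: the diapophysis is the "primary" primary
#' landmark; a lone zygapophysis comes next; the parapophysis is promoted to
#' primary only when no table landmark is present (cpaf). The neural spine
#' then centrum serve as secondary landmarks, with the parapophysis promoted
#' to secondary when a table primary is present but neither s nor c is
#' (padf, prpadf). Any remaining landmark becomes tertiary. The two
#' symmetric-flank sets `{s,d,pr,po}` and `{c,d,pr,po}` name the undivided
#' sdf and cdf. The sets `{s,pr,po}` and `{d,pr,po}` arise only when the
#' epipophyseal-prezygapophyseal lamina divides the sdf and are nameable only
#' as sdf1/sdf2 (pass `eprl = TRUE`).
#'
#' @param landmarks Character vector of landmark codes (subset of
#'   c, d, pa, po, pr, s).
#' @param eprl Logical; is the face bounded by the
#'   epipophyseal-prezygapophyseal lamina?
#' @param sacral Logical; sacral vertebrae take bipartite names only, so a
#'   tertiary landmark, if assigned, is dropped.
#' @param prefer One of `NA`, `"pr"`, `"po"`: view-specific preference used
#'   only to break a genuine prezygapophysis-vs-postzygapophysis tie for the
#'   primary role.
#' @return A `fossa_name` object.
#' @examples
#' compose_name(c("c", "d"))              # cdf
#' compose_name(c("c", "d", "pr"))        # prcdf
#' compose_name(c("c", "pa"))             # cpaf (parapophyseal promotion)
#' compose_name(c("s", "pr", "po"), eprl = TRUE)  # sdf1
#' @export
compose_name <- function(landmarks, eprl = FALSE, sacral = FALSE, prefer = NA) {
  landmarks <- unique(as.character(landmarks))
  check_landmark_codes(landmarks)
  if (length(landmarks) < 2)
    stop("underdetermined fossa: a named fossa needs at least two landmarks",
         call. = FALSE)
  if (length(landmarks) > 4)
    stop("impossible combination: more than four landmarks", call. = FALSE)

  set_eq <- function(a) setequal(landmarks, a)

  # special: the eprl divides the sdf into sdf1 (spine side) / sdf2 (table side)
  if (set_eq(c("s", "pr", "po")) || set_eq(c("d", "pr", "po"))) {
    if (!eprl)
      stop("eprl context required: {", paste(sort(landmarks), collapse = ","),
           "} is nameable only as sdf1/sdf2 beside the epipophyseal-",
           "prezygapophyseal lamina", call. = FALSE)
    return(new_fossa_name(special = if ("s" %in% landmarks) "sdf1" else "sdf2"))
  }

  # symmetric-flank rule: both zygapophyses flank the undivided sdf / cdf
  if (set_eq(c("s", "d", "pr", "po")))
    return(new_fossa_name(primary = "d", secondary = "s"))
  if (set_eq(c("c", "d", "pr", "po")))
    return(new_fossa_name(primary = "d", secondary = "c"))

  rest <- landmarks

  # (1) primary
  primary <- NULL
  if ("d" %in% rest) {
    primary <- "d"
  } else {
    zyg <- intersect(c("pr", "po"), rest)
    if (length(zyg) == 1) {
      primary <- zyg
    } else if (length(zyg) == 2) {
      if (!is.na(prefer) && prefer %in% zyg) {
        primary <- prefer
      } else {
        stop("impossible combination: both zygapophyses present with no ",
             "diapophysis; no primary landmark can be chosen", call. = FALSE)
      }
    } else if ("pa" %in% rest) {
      primary <- "pa"   # promotion: no table landmark at all
    }
  }
  if (is.null(primary))
    stop("no table landmark: none of d, pr, po, pa can serve as primary",
         call. = FALSE)
  rest <- setdiff(rest, primary)

  # (2) secondary
  secondary <- NULL
  if ("s" %in% rest) secondary <- "s"
  else if ("c" %in% rest) secondary <- "c"
  else if ("pa" %in% rest && primary != "pa") secondary <- "pa"  # promotion
  if (is.null(secondary))
    stop("impossible combination: no secondary landmark (neural spine, ",
         "centrum or promoted parapophysis) bounds the fossa", call. = FALSE)
  rest <- setdiff(rest, secondary)

  # (3) tertiary
  tertiary <- NULL
  if (length(rest) == 1) {
    tertiary <- rest
    if (!tertiary %in% c("pa", "pr", "po"))
      stop("impossible combination: ", tertiary,
           " cannot act as a tertiary landmark", call. = FALSE)
  } else if (length(rest) > 1) {
    stop("impossible combination: more landmarks than the tripartite grammar ",
         "admits (", paste(sort(rest), collapse = ","), " left over)",
         call. = FALSE)
  }

  msg <- roles_incompatibility(primary, secondary, tertiary)
  if (!is.null(msg)) stop("impossible combination: ", msg, call. = FALSE)

  if (sacral) tertiary <- NULL   # bipartite names only in the sacrum
  new_fossa_name(primary = primary, secondary = secondary, tertiary = tertiary)
}

#' Abbreviate a fossa name
#'
#' The abbreviation is the concatenation tertiary + secondary + primary code
#' plus a terminal "f"; intralaminar fossae take the parent lamina
#' abbreviation plus "-f"; the sdf subdivisions are "sdf1"/"sdf2".
#'
#' @param name A `fossa_name` object.
#' @return A single string.
#' @examples
#' abbreviate_name(compose_name(c("c", "d", "pr")))  # "prcdf"
#' @export
abbreviate_name <- function(name) {
  stopifnot(inherits(name, "fossa_name"))
  name$abbreviation
}

#' Expand a fossa name to its canonical full English name
#'
#' @param name A `fossa_name` object.
#' @return A single string, e.g. "prezygapophyseal centrodiapophyseal fossa".
#' @examples
#' expand_name(compose_name(c("pa", "c", "pr")))
#' @export
expand_name <- function(name) {
  stopifnot(inherits(name, "fossa_name"))
  name$full_name
}
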