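# Assign nomenclatural names to the bounded faces of a vertebra graph.

# view-specific preference used only to break a genuine pr-vs-po tie
.chart_prefer <- c(lateral = NA, anterior = "pr", posterior = "po")

.face_is_intralaminar <- function(face, edges) {
  eids <- unique(face$edge_ids)
  if (length(eids) != 2) return(NA_character_)
  i <- match(eids, edges$id)
  ram <- edges$ramus[i]
  if (any(is.na(ram)) || ram[1] == ram[2]) return(NA_character_)
  lab1 <- edges$laminae[[i[1]]]; lab2 <- edges$laminae[[i[2]]]
  common <- intersect(lab1, lab2)
  if (length(common) == 1) common else NA_character_
}

.face_laterality <- function(face, chart_id) {
  if (chart_id == "lateral") return("paired")
  sides <- setdiff(face$sides, "midline")
  if (length(sides) >= 2) "midline" else "paired"
}

#' Name the fossae of a vertebra graph
#'
#' Enumerates the bounded faces of every chart and assigns each its
#' nomenclatural name, in order of precedence: (1) a face whose two boundary
#' edges are the rami of one divided lamina takes the intralaminar name
#' (lamina + "-f"); (2) a face bounded by the epipophyseal-prezygapophyseal
#' lamina is sdf1 if it also touches the neural spine and sdf2 if it also
#' touches the diapophysis; (3) otherwise [compose_name()] is applied to the
#' effective boundary landmarks (a pass-through parapophysis of degree 2 is
#' invisible to naming), with the view's pr/po preference available to break
#' a genuine zygapophyseal tie; (4) in sacral mode tripartite names are
#' truncated to their bipartite base. Faces that cannot take a valid name
#' are returned unnamed with a reason, never as errors.
#'
#' @param graph A `vertebra_graph`.
#' @return A data frame with one row per bounded face: columns `chart`,
#'   `abbreviation`, `full_name`, `boundary_laminae`, `laterality`,
#'   `landmarks`, `unnamed_reason` (`NA` for named faces).
#' @examples
#' assign_fossa_names(make_archetype("cervical_eprl"))
#' @export
assign_fossa_names <- function(graph) {
  stopifnot(inherits(graph, "vertebra_graph"))
  sacral <- isTRUE(graph$metadata$sacral_mode)
  rows <- list()
  for (chart in graph$charts) {
    faces <- enumerate_faces(chart)
    for (face in faces) {
      abbrev <- NA_character_; full <- NA_character_; reason <- NA_character_

      intra <- .face_is_intralaminar(face, chart$edges)
      if (!is.na(intra)) {
        nm <- new_fossa_name(special = "intralaminar", parent_lamina = intra)
        abbrev <- nm$abbreviation; full <- nm$full_name
      } else if ("eprl" %in% face$laminae) {
        if ("s" %in% face$landmarks_effective) {
          nm <- new_fossa_name(special = "sdf1")
        } else if ("d" %in% face$landmarks_effective) {
          nm <- new_fossa_name(special = "sdf2")
        } else nm <- NULL
        if (is.null(nm)) {
          reason <- "irregular"
        } else {
          abbrev <- nm$abbreviation; full <- nm$full_name
        }
      } else {
        nm <- tryCatch(
          compose_name(face$landmarks_effective, sacral = sacral,
                       prefer = .chart_prefer[[chart$id]]),
          error = function(e) e)
        if (inherits(nm, "error")) {
          msg <- conditionMessage(nm)
          reason <- if (grepl("underdetermined|no table landmark", msg))
            "unnamed_lamina" else if (grepl("eprl context", msg))
            "irregular" else "irregular"
        } else {
          abbrev <- nm$abbreviation; full <- nm$full_name
        }
      }

      rows[[length(rows) + 1]] <- data.frame(
        chart = chart$id,
        abbreviation = abbrev,
        full_name = full,
        boundary_laminae = paste(face$laminae, collapse = ","),
        laterality = .face_laterality(face, chart$id),
        landmarks = paste(face$landmarks_effective, collapse = ","),
        unnamed_reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Extract a fossa inventory from a vertebra graph
#'
#' Names all faces with [assign_fossa_names()] and collapses them into a
#' per-vertebra inventory: one item per distinct named fossa, with
#' laterality (left/right instances of one fossa in the frontal charts
#' collapse to a single paired item) and a division flag (always `FALSE`
#' for graph-derived inventories; division by the prespinal/postspinal
#' laminae is recorded when such midline laminae split a spinal fossa into
#' two same-named faces).
#'
#' @param graph A `vertebra_graph`.
#' @return A `fossa_inventory`: data frame with attributes `taxon`,
#'   `position` and columns `abbreviation`, `laterality`, `divided`.
#' @export
fossa_inventory <- function(graph) {
  named <- assign_fossa_names(graph)
  named <- named[!is.na(named$abbreviation), , drop = FALSE]
  items <- list()
  for (ab in unique(named$abbreviation)) {
    sub <- named[named$abbreviation == ab, , drop = FALSE]
    lat <- if (any(sub$laterality == "midline")) "midline" else "paired"
    # a midline fossa appearing as two same-named faces in one chart has
    # been divided by a midline lamina
    divided <- lat == "midline" && any(table(sub$chart) > 1)
    items[[length(items) + 1]] <- data.frame(
      abbreviation = ab, laterality = lat, divided = divided,
      stringsAsFactors = FALSE)
  }
  inv <- do.call(rbind, items)
  if (is.null(inv))
    inv <- data.frame(abbreviation = character(0), laterality = character(0),
                      divided = logical(0))
  new_fossa_inventory(inv, taxon = graph$metadata$taxon,
                      position = graph$metadata$position)
}
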