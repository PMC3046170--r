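# Vertebra-description files: a documented JSON dialect mirroring the
# in-memory model.
#
#   {
#     "metadata": {"taxon": "...", "position": "cv6", "sacral_mode": false},
#     "charts": {
#       "<lateral|anterior|posterior>": {
#         "nodes": [{"id": "...", "landmark": "pr", "side": "left"}, ...],
#         "edges": [{"id": "...", "laminae": ["cprl"], "from": "...",
#                    "to": "...", "ramus": null, "structural": false}, ...],
#         "rotation": {"<node id>": ["<edge id>", ...], ...},
#         "outer": {"edge": "<edge id>", "from": "<node id>"}
#       }, ...
#     }
#   }
#
# No automatic planar embedding is attempted: the rotation system and the
# outer-face witness are part of the file.

.schema_fail <- function(...) stop("schema violation: ", ..., call. = FALSE)

.need <- function(obj, field, where) {
  if (is.null(obj[[field]])) .schema_fail("missing field '", field, "' in ", where)
  obj[[field]]
}

#' Read a vertebra-description file
#'
#' Parses and validates the JSON dialect described in the package vignette;
#' all lamina labels are resolved against the catalogue and the rotation
#' system is checked for completeness.
#'
#' @param path Path to a JSON vertebra file.
#' @return A `vertebra_graph`.
#' @export
read_vertebra_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    .schema_fail("not parseable as JSON (", conditionMessage(e), ")"))
  meta <- .need(doc, "metadata", "document root")
  charts_doc <- .need(doc, "charts", "document root")
  if (!length(charts_doc)) .schema_fail("'charts' is empty")
  charts <- list()
  for (cid in names(charts_doc)) {
    if (!cid %in% c("lateral", "anterior", "posterior"))
      .schema_fail("unknown chart id '", cid, "'")
    cdoc <- charts_doc[[cid]]
    nodes_doc <- .need(cdoc, "nodes", paste0("chart '", cid, "'"))
    edges_doc <- .need(cdoc, "edges", paste0("chart '", cid, "'"))
    rot_doc <- .need(cdoc, "rotation", paste0("chart '", cid, "'"))
    outer_doc <- .need(cdoc, "outer", paste0("chart '", cid, "'"))

    nodes <- do.call(rbind, lapply(nodes_doc, function(n) {
      data.frame(id = .need(n, "id", "node"),
                 landmark = .need(n, "landmark", "node"),
                 side = .need(n, "side", "node"), stringsAsFactors = FALSE)
    }))
    if (!all(nodes$side %in% c("midline", "left", "right")))
      .schema_fail("node side must be midline/left/right in chart '", cid, "'")

    edges <- do.call(rbind, lapply(edges_doc, function(e) {
      data.frame(id = .need(e, "id", "edge"),
                 from = .need(e, "from", "edge"),
                 to = .need(e, "to", "edge"), stringsAsFactors = FALSE)
    }))
    edges$laminae <- I(lapply(edges_doc, function(e)
      as.character(unlist(e$laminae))))
    edges$ramus <- vapply(edges_doc, function(e)
      if (is.null(e$ramus)) NA_character_ else as.character(e$ramus), "")
    edges$structural <- vapply(edges_doc, function(e)
      isTRUE(e$structural), logical(1))

    rotation <- lapply(rot_doc, function(r) as.character(unlist(r)))
    outer <- list(edge = .need(outer_doc, "edge", "outer witness"),
                  from = .need(outer_doc, "from", "outer witness"))
    charts[[cid]] <- vertebra_chart(cid, nodes, edges, rotation, outer)
  }
  vertebra_graph(charts,
                 taxon = meta$taxon %||% "",
                 position = meta$position %||% "",
                 sacral_mode = isTRUE(meta$sacral_mode))
}

#' Write a vertebra graph to a JSON file
#'
#' @param graph A `vertebra_graph`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_vertebra_file <- function(graph, path) {
  stopifnot(inherits(graph, "vertebra_graph"))
  charts <- lapply(graph$charts, function(ch) {
    nodes <- lapply(seq_len(nrow(ch$nodes)), function(i)
      list(id = ch$nodes$id[i], landmark = ch$nodes$landmark[i],
           side = ch$nodes$side[i]))
    edges <- lapply(seq_len(nrow(ch$edges)), function(i)
      list(id = ch$edges$id[i],
           laminae = as.list(ch$edges$laminae[[i]]),
           from = ch$edges$from[i], to = ch$edges$to[i],
           ramus = if (is.na(ch$edges$ramus[i])) NULL else ch$edges$ramus[i],
           structural = ch$edges$structural[i]))
    list(nodes = nodes, edges = edges, rotation = ch$rotation,
         outer = list(edge = ch$outer$edge, from = ch$outer$from))
  })
  doc <- list(metadata = graph$metadata, charts = charts)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a named-fossa inventory table as TSV
#'
#' @param named Output of [assign_fossa_names()].
#' @param path Output path; `""` prints to standard output.
#' @return The data frame, invisibly.
#' @export
write_fossa_table <- function(named, path = "") {
  utils::write.table(named, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(named)
}
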