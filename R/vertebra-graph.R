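# A vertebra is modeled as up to three planar "charts" (lateral, anterior,
# posterior views), each an embedded multigraph: nodes are landmark
# instances, edges are laminae (or, in the frontal views, the structural
# table margin between the zygapophyses), and a rotation system — the
# cyclic order of incident edges at every node plus an outer-face witness —
# fixes the embedding so that bounded faces can be enumerated. The bounded
# faces are the lamina-bounded fossae.

#' Construct a vertebra chart
#'
#' @param id Chart id: `"lateral"`, `"anterior"` or `"posterior"`.
#' @param nodes Data frame with columns `id`, `landmark` (code), `side`
#'   (`"midline"`, `"left"` or `"right"`).
#' @param edges Data frame with columns `id`, `from`, `to`, plus optional
#'   `laminae` (list column of lamina-label character vectors), `ramus`
#'   (`NA`, or the ramus tag of a divided lamina), `structural` (logical;
#'   TRUE for the non-lamina table-margin edge of the frontal views).
#' @param rotation Named list: for every node id, the incident edge ids in
#'   cyclic (counterclockwise) order.
#' @param outer Outer-face witness: `list(edge = <edge id>, from = <node id>)`,
#'   one directed edge lying on the unbounded face.
#' @return A `vertebra_chart` object (validated).
#' @export
vertebra_chart <- function(id, nodes, edges, rotation, outer) {
  if (is.null(edges$laminae)) edges$laminae <- I(replicate(nrow(edges), character(0), simplify = FALSE))
  if (is.null(edges$ramus)) edges$ramus <- NA_character_
  if (is.null(edges$structural)) edges$structural <- FALSE
  chart <- structure(
    list(id = id,
         nodes = nodes[, c("id", "landmark", "side")],
         edges = edges[, c("id", "from", "to", "laminae", "ramus", "structural")],
         rotation = rotation, outer = outer),
    class = "vertebra_chart"
  )
  validate_chart(chart)
  chart
}

validate_chart <- function(chart) {
  nodes <- chart$nodes; edges <- chart$edges
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (anyDuplicated(edges$id)) stop("duplicate edge ids", call. = FALSE)
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad)) stop("edge endpoint not a node: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  check_landmark_codes(nodes$landmark)
  lam <- unique(unlist(edges$laminae))
  unknown <- setdiff(lam, lamina_catalogue()$abbreviation)
  if (length(unknown))
    stop("unknown lamina label: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (any(!edges$structural & lengths(edges$laminae) == 0))
    stop("edge without lamina label must be marked structural", call. = FALSE)

  # rotation: exactly the incident edges at every node, each once
  for (v in nodes$id) {
    inc <- edges$id[edges$from == v | edges$to == v]
    rot <- chart$rotation[[v]]
    if (is.null(rot) || !setequal(rot, inc) || length(rot) != length(inc))
      stop("invalid embedding: rotation at node '", v,
           "' does not list its incident edges exactly once", call. = FALSE)
  }

  # connectivity (ignoring edge multiplicity)
  if (nrow(nodes) > 0) {
    seen <- nodes$id[1]; frontier <- seen
    while (length(frontier)) {
      nb <- unique(c(edges$to[edges$from %in% frontier],
                     edges$from[edges$to %in% frontier]))
      frontier <- setdiff(nb, seen)
      seen <- c(seen, frontier)
    }
    if (length(seen) < nrow(nodes))
      stop("disconnected chart: nodes ",
           paste(setdiff(nodes$id, seen), collapse = ", "),
           " unreachable", call. = FALSE)
  }

  o <- chart$outer
  if (is.null(o$edge) || is.null(o$from) || !o$edge %in% edges$id)
    stop("invalid embedding: outer-face witness missing or unknown edge",
         call. = FALSE)
  i <- match(o$edge, edges$id)
  if (!o$from %in% c(edges$from[i], edges$to[i]))
    stop("invalid embedding: outer-face witness direction does not match ",
         "its edge", call. = FALSE)
  invisible(chart)
}

#' Construct a vertebra graph
#'
#' @param charts Named list of `vertebra_chart` objects (names from
#'   lateral/anterior/posterior).
#' @param taxon,position Free-text metadata (`position` e.g. `"cv6"`).
#' @param sacral_mode Logical; sacral vertebrae take bipartite names only.
#' @return A `vertebra_graph` object.
#' @export
vertebra_graph <- function(charts, taxon = "", position = "", sacral_mode = FALSE) {
  stopifnot(is.list(charts), length(charts) >= 1,
            all(vapply(charts, inherits, logical(1), "vertebra_chart")))
  ok <- names(charts) %in% c("lateral", "anterior", "posterior")
  if (!all(ok)) stop("chart ids must be lateral/anterior/posterior", call. = FALSE)
  structure(list(metadata = list(taxon = taxon, position = position,
                                 sacral_mode = isTRUE(sacral_mode)),
                 charts = charts),
            class = "vertebra_graph")
}

#' @export
print.vertebra_graph <- function(x, ...) {
  cat("Vertebra graph: ", x$metadata$taxon,
      if (nzchar(x$metadata$position)) paste0(" (", x$metadata$position, ")"),
      if (x$metadata$sacral_mode) " [sacral mode]", "\n", sep = "")
  for (ch in x$charts) {
    nf <- nrow(ch$edges) - nrow(ch$nodes) + 1
    cat("  ", ch$id, ": ", nrow(ch$nodes), " nodes, ", nrow(ch$edges),
        " edges, ", nf, " bounded faces\n", sep = "")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# face traversal on the rotation system

directed_key <- function(edge, from) paste(edge, from, sep = "@")

# next directed edge of the face walk: arrive at v along e; leave along the
# clockwise successor of e in the (counterclockwise) rotation at v
.face_next <- function(chart, edge, to) {
  rot <- chart$rotation[[to]]
  i <- match(edge, rot)
  nxt <- rot[((i - 2) %% length(rot)) + 1]
  j <- match(nxt, chart$edges$id)
  from <- to
  # orient the next edge away from v; a parallel edge id appears once in the
  # rotation, and its direction is fixed by the departure node
  e_from <- chart$edges$from[j]; e_to <- chart$edges$to[j]
  to2 <- if (e_from == from) e_to else e_from
  list(edge = nxt, from = from, to = to2)
}

#' Enumerate the bounded faces (fossae) of a chart
#'
#' Standard face traversal on the combinatorial embedding: every directed
#' edge lies on exactly one face walk; the face containing the outer-face
#' witness is the unbounded region and is dropped. For a connected chart the
#' number of bounded faces is E - V + 1.
#'
#' @param chart A `vertebra_chart`.
#' @return A list of `fossa_region` records: each has `chart`, `edge_ids`,
#'   `walk` (data frame of directed edges), `node_ids`, `landmarks` (all
#'   boundary landmark codes), `landmarks_effective` (excluding pass-through
#'   parapophysis nodes of degree 2), `laminae` (labels on the boundary),
#'   `sides`.
#' @export
enumerate_faces <- function(chart) {
  stopifnot(inherits(chart, "vertebra_chart"))
  validate_chart(chart)
  edges <- chart$edges
  pending <- c(directed_key(edges$id, edges$from),
               directed_key(edges$id, edges$to))
  dir_tab <- rbind(
    data.frame(edge = edges$id, from = edges$from, to = edges$to),
    data.frame(edge = edges$id, from = edges$to, to = edges$from)
  )
  rownames(dir_tab) <- c(directed_key(edges$id, edges$from),
                         directed_key(edges$id, edges$to))
  visited <- character(0)
  faces <- list()
  for (k in rownames(dir_tab)) {
    if (k %in% visited) next
    walk <- list()
    cur <- as.list(dir_tab[k, ])
    repeat {
      key <- directed_key(cur$edge, cur$from)
      if (key %in% visited)
        stop("invalid embedding: directed edge ", key,
             " visited twice during face traversal", call. = FALSE)
      visited <- c(visited, key)
      walk[[length(walk) + 1]] <- cur
      cur <- .face_next(chart, cur$edge, cur$to)
      if (directed_key(cur$edge, cur$from) == k) break
    }
    faces[[length(faces) + 1]] <- walk
  }

  # identify outer face via the witness
  wkey <- directed_key(chart$outer$edge, chart$outer$from)
  is_outer <- vapply(faces, function(w)
    any(vapply(w, function(d) directed_key(d$edge, d$from) == wkey, logical(1))),
    logical(1))
  if (sum(is_outer) != 1)
    stop("invalid embedding: outer-face witness not found on any face",
         call. = FALSE)

  node_deg <- table(c(edges$from, edges$to))
  outer_len <- length(faces[is_outer][[1]])
  out <- list()
  for (w in faces[!is_outer]) {
    eids <- vapply(w, `[[`, "", "edge")
    nids <- unique(vapply(w, `[[`, "", "from"))
    lmk <- chart$nodes$landmark[match(nids, chart$nodes$id)]
    side <- chart$nodes$side[match(nids, chart$nodes$id)]
    # pass-through parapophysis: a pa node of degree 2 does not bound
    pass <- lmk == "pa" & as.integer(node_deg[nids]) == 2
    lam <- unique(unlist(edges$laminae[match(unique(eids), edges$id)]))
    out[[length(out) + 1]] <- structure(
      list(chart = chart$id,
           edge_ids = eids,
           walk = do.call(rbind, lapply(w, as.data.frame)),
           node_ids = nids,
           landmarks = sort(unique(lmk)),
           landmarks_effective = sort(unique(lmk[!pass])),
           laminae = sort(lam),
           sides = sort(unique(side))),
      class = "fossa_region")
  }
  attr(out, "outer_length") <- outer_len
  out
}
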