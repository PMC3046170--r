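# Archetype vertebrae. Each archetype is drawn once as a schematic planar
# figure (node coordinates plus optional bend points on curved laminae); the
# rotation system is derived from the drawing by sorting incident edge
# directions counterclockwise, and the outer face is found by signed area.
# Only the combinatorial data (rotation + outer witness) is retained, so
# serialized archetypes carry no coordinates.

# --- geometric helpers ------------------------------------------------------

.angle <- function(from, towards) atan2(towards[2] - from[2], towards[1] - from[1])

# direction of edge e seen from node v: towards the nearest bend if any
.edge_dir_at <- function(edge, v, coords) {
  if (edge$from == v) {
    tgt <- if (length(edge$bend)) edge$bend[[1]] else coords[[edge$to]]
  } else {
    tgt <- if (length(edge$bend)) edge$bend[[length(edge$bend)]] else coords[[edge$from]]
  }
  .angle(coords[[v]], tgt)
}

# polyline of a directed edge traversal (tail -> head), including bends
.edge_path <- function(edge, from, coords) {
  b <- edge$bend
  if (edge$from != from && length(b)) b <- rev(b)
  do.call(rbind, c(list(coords[[from]]), b,
                   list(coords[[if (edge$from == from) edge$to else edge$from]])))
}

.polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# Build a vertebra_chart from a drawing: nodes (id, landmark, side, x, y) and
# edge specs list(id, from, to, laminae, ramus, structural, bend = list(c(x,y)...))
.chart_from_drawing <- function(id, nodes, edge_specs) {
  coords <- stats::setNames(lapply(seq_len(nrow(nodes)),
                                   function(i) c(nodes$x[i], nodes$y[i])),
                            nodes$id)
  edges <- data.frame(
    id = vapply(edge_specs, `[[`, "", "id"),
    from = vapply(edge_specs, `[[`, "", "from"),
    to = vapply(edge_specs, `[[`, "", "to"),
    stringsAsFactors = FALSE
  )
  edges$laminae <- I(lapply(edge_specs, function(e) e$laminae %||% character(0)))
  edges$ramus <- vapply(edge_specs, function(e) e$ramus %||% NA_character_, "")
  edges$structural <- vapply(edge_specs, function(e) isTRUE(e$structural), logical(1))

  rotation <- lapply(stats::setNames(nodes$id, nodes$id), function(v) {
    inc <- which(edges$from == v | edges$to == v)
    ang <- vapply(inc, function(i) .edge_dir_at(edge_specs[[i]], v, coords), 0)
    edges$id[inc[order(ang)]]
  })

  chart <- vertebra_chart(id, nodes, edges, rotation,
                          outer = list(edge = edges$id[1], from = edges$from[1]))
  # locate the outer face by signed area of the face polygons
  chart$outer <- .find_outer(chart, edge_specs, coords)
  validate_chart(chart)
  # retain the schematic drawing (not serialized) for independent checks
  attr(chart, "drawing") <- list(
    coords = coords,
    bends = stats::setNames(lapply(edge_specs, function(e) e$bend), edges$id))
  chart
}

.find_outer <- function(chart, edge_specs, coords) {
  edges <- chart$edges
  spec_of <- stats::setNames(edge_specs, edges$id)
  pending <- unique(c(directed_key(edges$id, edges$from),
                      directed_key(edges$id, edges$to)))
  visited <- character(0)
  best <- NULL; best_area <- Inf
  dir_tab <- rbind(data.frame(edge = edges$id, from = edges$from, to = edges$to),
                   data.frame(edge = edges$id, from = edges$to, to = edges$from))
  rownames(dir_tab) <- c(directed_key(edges$id, edges$from),
                         directed_key(edges$id, edges$to))
  for (k in pending) {
    if (k %in% visited) next
    cur <- as.list(dir_tab[k, ])
    pts <- NULL
    repeat {
      visited <- c(visited, directed_key(cur$edge, cur$from))
      path <- .edge_path(spec_of[[cur$edge]], cur$from, coords)
      pts <- rbind(pts, path[-nrow(path), , drop = FALSE])
      cur <- .face_next(chart, cur$edge, cur$to)
      if (directed_key(cur$edge, cur$from) == k) break
    }
    area <- .polygon_area(pts)
    if (area < best_area) {
      best_area <- area
      best <- as.list(dir_tab[k, c("edge", "from")])
    }
  }
  if (best_area >= 0)
    stop("internal error: no negatively oriented (outer) face found")
  best
}

# --- drawings ---------------------------------------------------------------

.lateral_nodes <- function(with_pa = FALSE) {
  df <- data.frame(
    id       = c("pr", "s", "po", "d", "c"),
    landmark = c("pr", "s", "po", "d", "c"),
    side     = "left",
    x = c(0, 2, 4, 2, 2),
    y = c(2, 3, 2, 1, -1),
    stringsAsFactors = FALSE
  )
  if (with_pa)
    df <- rbind(df, data.frame(id = "pa", landmark = "pa", side = "left",
                               x = 1, y = 0))
  df
}

.e <- function(id, from, to, laminae = id, ramus = NULL, structural = FALSE,
               bend = list()) {
  list(id = id, from = from, to = to,
       laminae = if (isTRUE(structural)) character(0) else laminae,
       ramus = ramus, structural = structural, bend = bend)
}

.lateral_edges_cervical <- function() list(
  .e("sprl", "s", "pr"),
  .e("spol", "s", "po"),
  .e("prdl", "pr", "d"),
  .e("podl", "po", "d"),
  .e("acdl", "c", "d", bend = list(c(1.4, 0))),
  .e("pcdl", "c", "d", bend = list(c(2.6, 0))),
  .e("cprl", "c", "pr", bend = list(c(0.3, 0.5))),
  .e("cpol", "c", "po", bend = list(c(3.7, 0.5)))
)

.lateral_edges_dorsal <- function(complex = FALSE) {
  base <- list(
    .e("sprl", "s", "pr"),
    .e("spol", "s", "po"),
    .e("prdl", "pr", "d"),
    .e("podl", "po", "d"),
    .e("pcdl", "c", "d", bend = list(c(2.6, 0))),
    .e("cprl", "c", "pr", bend = list(c(0.3, 0.5))),
    .e("cpol", "c", "po", bend = list(c(3.7, 0.5))),
    .e("acpl", "c", "pa"),
    .e("ppdl", "pa", "d")
  )
  if (complex) base <- c(base, list(
    .e("pcpl", "c", "pa", bend = list(c(1.8, -0.2))),
    .e("prpl", "pr", "pa"),
    .e("spdl", "s", "d")
  ))
  base
}

.frontal_chart <- function(id, zyg, spinal, central) {
  # anterior or posterior view: midline spine and centrum, paired
  # zygapophyses, a structural table-margin edge between left and right
  zl <- paste0(zyg, "_l"); zr <- paste0(zyg, "_r")
  nodes <- data.frame(
    id       = c("s", zl, zr, "c"),
    landmark = c("s", zyg, zyg, "c"),
    side     = c("midline", "left", "right", "midline"),
    x = c(0, -1, 1, 0),
    y = c(3, 2, 2, 0),
    stringsAsFactors = FALSE
  )
  edges <- list(
    .e(paste0(spinal, "_l"), "s", zl, laminae = spinal),
    .e(paste0(spinal, "_r"), "s", zr, laminae = spinal),
    .e(paste0(central, "_l"), "c", zl, laminae = central),
    .e(paste0(central, "_r"), "c", zr, laminae = central),
    .e("table_margin", zl, zr, structural = TRUE)
  )
  list(id = id, nodes = nodes, edges = edges)
}

.frontal_chart_caudal <- function(id, zyg, spinal) {
  zl <- paste0(zyg, "_l"); zr <- paste0(zyg, "_r")
  nodes <- data.frame(
    id = c("s", zl, zr), landmark = c("s", zyg, zyg),
    side = c("midline", "left", "right"),
    x = c(0, -1, 1), y = c(3, 2, 2), stringsAsFactors = FALSE
  )
  edges <- list(
    .e(paste0(spinal, "_l"), "s", zl, laminae = spinal),
    .e(paste0(spinal, "_r"), "s", zr, laminae = spinal),
    .e("table_margin", zl, zr, structural = TRUE)
  )
  list(id = id, nodes = nodes, edges = edges)
}

# charts in which the division of each divisible lamina is expressed
.division_chart <- c(cprl = "anterior", cpol = "posterior", spol = "posterior",
                     spdl = "lateral", pcdl = "lateral", prdl = "lateral",
                     ppdl = "lateral")

# replace a lamina's edge(s) by two parallel rami with offset bends
.divide_in_drawing <- function(drawing, label) {
  specs <- drawing$edges
  ids <- vapply(specs, `[[`, "", "id")
  hit <- which(vapply(specs, function(e) label %in% (e$laminae %||% character(0)),
                      logical(1)))
  if (!length(hit))
    stop("lamina ", label, " not present in chart ", drawing$id, call. = FALSE)
  coords <- stats::setNames(lapply(seq_len(nrow(drawing$nodes)),
                                   function(i) c(drawing$nodes$x[i], drawing$nodes$y[i])),
                            drawing$nodes$id)
  ramus_names <- if (drawing$id == "lateral") c("anterior", "posterior")
                 else c("medial", "lateral")
  out <- list()
  for (i in seq_along(specs)) {
    e <- specs[[i]]
    if (!i %in% hit) { out[[length(out) + 1]] <- e; next }
    p1 <- coords[[e$from]]; p2 <- coords[[e$to]]
    mid <- if (length(e$bend)) e$bend[[1]] else (p1 + p2) / 2
    d <- p2 - p1; n <- c(-d[2], d[1]); n <- n / sqrt(sum(n^2)) * 0.15
    for (k in 1:2) {
      sgn <- if (k == 1) 1 else -1
      out[[length(out) + 1]] <- list(
        id = paste0(e$id, "_", substr(ramus_names[k], 1, 3)),
        from = e$from, to = e$to, laminae = e$laminae,
        ramus = ramus_names[k], structural = FALSE,
        bend = list(mid + sgn * n))
    }
  }
  drawing$edges <- out
  drawing
}

#' Build an archetype vertebra graph
#'
#' Deterministic schematic vertebrae capturing the canonical laminar
#' configurations:
#' \describe{
#'   \item{cervical_simple}{parapophysis on the centrum; lateral chart with
#'     sprl, spol, prdl, podl, acdl, pcdl, cprl, cpol; frontal charts with
#'     paired spino- and centro-zygapophyseal laminae.}
#'   \item{cervical_eprl}{as cervical_simple plus the
#'     epipophyseal-prezygapophyseal lamina dividing the sdf.}
#'   \item{dorsal_simple}{parapophysis risen onto the arch as a pass-through
#'     node: acdl replaced by acpl + ppdl.}
#'   \item{dorsal_complex}{parapophysis with four laminae (ppdl, acpl, pcpl,
#'     prpl) plus the spdl.}
#'   \item{caudal_simple}{reduced lamination: sprl, spol, prdl, podl, acdl,
#'     pcdl only.}
#' }
#'
#' @param kind Archetype name (see above).
#' @param divide Character vector of lamina labels to divide into rami
#'   (must be attested-divisible; the division is expressed in the chart
#'   where the intralaminar fossa is seen).
#' @param spdl Logical; insert a spinodiapophyseal lamina into the lateral
#'   chart (implied by `dorsal_complex`; incompatible with `cervical_eprl`,
#'   whose eprl it would cross).
#' @param taxon,position,sacral_mode Metadata passed to [vertebra_graph()].
#' @return A `vertebra_graph`.
#' @examples
#' g <- make_archetype("cervical_simple")
#' length(enumerate_faces(g$charts$lateral))  # 4
#' @export
make_archetype <- function(kind = c("cervical_simple", "cervical_eprl",
                                    "dorsal_simple", "dorsal_complex",
                                    "caudal_simple"),
                           divide = character(0), spdl = FALSE,
                           taxon = "archetype", position = "", sacral_mode = FALSE) {
  kind <- match.arg(kind)
  if (!nzchar(position))
    position <- switch(kind, cervical_simple = "cv", cervical_eprl = "cv",
                       dorsal_simple = "dv", dorsal_complex = "dv",
                       caudal_simple = "ca")

  lateral <- switch(kind,
    cervical_simple = list(id = "lateral", nodes = .lateral_nodes(),
                           edges = .lateral_edges_cervical()),
    cervical_eprl = {
      d <- list(id = "lateral", nodes = .lateral_nodes(),
                edges = .lateral_edges_cervical())
      d$edges <- c(d$edges, list(.e("eprl", "pr", "po")))
      d
    },
    dorsal_simple = list(id = "lateral", nodes = .lateral_nodes(with_pa = TRUE),
                         edges = .lateral_edges_dorsal(complex = FALSE)),
    dorsal_complex = list(id = "lateral", nodes = .lateral_nodes(with_pa = TRUE),
                          edges = .lateral_edges_dorsal(complex = TRUE)),
    caudal_simple = {
      d <- list(id = "lateral", nodes = .lateral_nodes(),
                edges = .lateral_edges_cervical())
      keep <- c("sprl", "spol", "prdl", "podl", "acdl", "pcdl")
      d$edges <- Filter(function(e) e$id %in% keep, d$edges)
      d
    })

  if (spdl) {
    if (kind == "cervical_eprl")
      stop("spdl insertion is incompatible with the eprl (the laminae would cross)",
           call. = FALSE)
    if (kind == "dorsal_complex") {
      # already present
    } else {
      lateral$edges <- c(lateral$edges, list(.e("spdl", "s", "d")))
    }
  }

  if (kind == "caudal_simple") {
    anterior <- .frontal_chart_caudal("anterior", "pr", "sprl")
    posterior <- .frontal_chart_caudal("posterior", "po", "spol")
  } else {
    anterior <- .frontal_chart("anterior", "pr", "sprl", "cprl")
    posterior <- .frontal_chart("posterior", "po", "spol", "cpol")
  }

  drawings <- list(lateral = lateral, anterior = anterior, posterior = posterior)

  for (lab in unique(divide)) {
    row <- .lamina_lookup(lab)
    if (!row$divisible)
      stop("lamina ", lab, " is not attested as occurring divided", call. = FALSE)
    target <- .division_chart[[lab]]
    present <- any(vapply(drawings[[target]]$edges,
                          function(e) lab %in% (e$laminae %||% character(0)),
                          logical(1)))
    if (!present)
      stop("lamina ", lab, " not present in the ", target,
           " chart of archetype ", kind, call. = FALSE)
    drawings[[target]] <- .divide_in_drawing(drawings[[target]], lab)
  }

  charts <- lapply(drawings, function(d)
    .chart_from_drawing(d$id, d$nodes, d$edges))
  vertebra_graph(charts, taxon = taxon,
                 position = position, sacral_mode = sacral_mode)
}
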