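# Helpers: independent brute-force face oracle, chart surgery, and a
# deterministic generator of perturbed archetypes.

# all edge subsets that form a single simple cycle (vertex degrees 2,
# connected); feasible because charts are small
all_cycle_subsets <- function(chart) {
  edges <- chart$edges
  m <- nrow(edges)
  stopifnot(m <= 14)
  cycles <- list()
  for (mask in 1:(2^m - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) != 0)
    if (length(idx) < 2) next
    ends <- c(edges$from[idx], edges$to[idx])
    deg <- table(ends)
    if (any(deg != 2)) next
    # connectivity over the subset
    verts <- names(deg)
    seen <- verts[1]; frontier <- seen
    while (length(frontier)) {
      nb <- unique(c(edges$to[idx][edges$from[idx] %in% frontier],
                     edges$from[idx][edges$to[idx] %in% frontier]))
      frontier <- setdiff(nb, seen)
      seen <- c(seen, frontier)
    }
    if (length(seen) == length(verts))
      cycles[[length(cycles) + 1]] <- sort(edges$id[idx])
  }
  cycles
}

# GF(2) independence of a list of cycles (edge-id sets) over the edge set
gf2_independent <- function(cycles, edge_ids) {
  mat <- NULL
  for (cy in cycles) {
    red <- as.integer(edge_ids %in% cy)
    if (!is.null(mat)) {
      for (r in seq_len(nrow(mat))) {
        piv <- which(mat[r, ] == 1)[1]
        if (red[piv] == 1) red <- (red + mat[r, ]) %% 2
      }
    }
    if (all(red == 0)) return(FALSE)
    mat <- rbind(mat, red)
  }
  TRUE
}

# enclosed area of a cycle (edge-id set), from the schematic drawing kept on
# archetype charts: order the edges into a closed walk, build the polygon
# (nodes plus bend points) and apply the shoelace formula
cycle_area <- function(chart, cycle_ids) {
  drawing <- attr(chart, "drawing")
  stopifnot(!is.null(drawing))
  edges <- chart$edges
  idx <- match(cycle_ids, edges$id)
  remaining <- idx
  i <- remaining[1]; remaining <- remaining[-1]
  walk <- list(list(edge = i, from = edges$from[i], to = edges$to[i]))
  at <- edges$to[i]
  while (length(remaining)) {
    nxt <- remaining[edges$from[remaining] == at | edges$to[remaining] == at][1]
    remaining <- setdiff(remaining, nxt)
    from <- at
    at <- if (edges$from[nxt] == at) edges$to[nxt] else edges$from[nxt]
    walk[[length(walk) + 1]] <- list(edge = nxt, from = from, to = at)
  }
  pts <- NULL
  for (st in walk) {
    b <- drawing$bends[[edges$id[st$edge]]]
    if (edges$from[st$edge] != st$from && length(b)) b <- rev(b)
    seg <- do.call(rbind, c(list(drawing$coords[[st$from]]), b))
    pts <- rbind(pts, seg)
  }
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2)
}

face_edge_sets <- function(chart) {
  lapply(enumerate_faces(chart), function(f) sort(unique(f$edge_ids)))
}

same_set_of_sets <- function(a, b) {
  key <- function(s) paste(s, collapse = "|")
  setequal(vapply(a, key, ""), vapply(b, key, ""))
}

# Independent region oracle: brute-force all simple cycles, then select the
# E - V + 1 atomic regions greedily by enclosed area under GF(2)
# independence. Any non-facial cycle encloses two or more faces and so has
# strictly larger area than each of them, which makes the greedy selection
# exactly the set of bounded faces.
brute_force_regions <- function(chart) {
  cycles <- all_cycle_subsets(chart)
  areas <- vapply(cycles, function(cy) cycle_area(chart, cy), 0)
  cycles <- cycles[order(areas)]
  target <- nrow(chart$edges) -
    length(unique(c(chart$edges$from, chart$edges$to))) + 1
  basis <- list(); mat <- NULL
  eids <- chart$edges$id
  for (cy in cycles) {
    red <- as.integer(eids %in% cy)
    if (!is.null(mat)) {
      for (r in seq_len(nrow(mat))) {
        piv <- which(mat[r, ] == 1)[1]
        if (red[piv] == 1) red <- (red + mat[r, ]) %% 2
      }
    }
    if (any(red == 1)) {
      basis[[length(basis) + 1]] <- cy
      mat <- rbind(mat, red)
      if (length(basis) == target) break
    }
  }
  stopifnot(length(basis) == target)
  basis
}

# mirror a chart: reverse every cyclic order and flip the witness direction
reflect_chart <- function(chart) {
  chart$rotation <- lapply(chart$rotation, rev)
  i <- match(chart$outer$edge, chart$edges$id)
  other <- if (chart$edges$from[i] == chart$outer$from) chart$edges$to[i]
           else chart$edges$from[i]
  chart$outer$from <- other
  chart
}

# rename every node id (rotation keys, edge endpoints, witness follow)
relabel_chart <- function(chart, f = function(id) paste0("n_", id)) {
  map <- stats::setNames(f(chart$nodes$id), chart$nodes$id)
  chart$nodes$id <- unname(map[chart$nodes$id])
  chart$edges$from <- unname(map[chart$edges$from])
  chart$edges$to <- unname(map[chart$edges$to])
  names(chart$rotation) <- unname(map[names(chart$rotation)])
  chart$outer$from <- unname(map[chart$outer$from])
  chart
}

# deterministic random perturbation of an archetype: random kind, random
# admissible divisions, random spdl insertion
random_archetype <- function() {
  kind <- sample(c("cervical_simple", "cervical_eprl", "dorsal_simple",
                   "dorsal_complex", "caudal_simple"), 1)
  divisible <- switch(kind,
    cervical_simple = c("cprl", "cpol", "spol", "pcdl", "prdl"),
    cervical_eprl   = c("cprl", "cpol", "spol", "pcdl", "prdl"),
    dorsal_simple   = c("cprl", "cpol", "spol", "pcdl", "prdl", "ppdl"),
    dorsal_complex  = c("cprl", "cpol", "spol", "pcdl", "prdl", "ppdl"),
    caudal_simple   = c("pcdl", "prdl"))
  divide <- sample(divisible, sample(0:2, 1))
  spdl <- kind %in% c("cervical_simple", "dorsal_simple", "caudal_simple") &&
    runif(1) < 0.3
  make_archetype(kind, divide = divide, spdl = spdl)
}

abbrev_set <- function(graph) {
  named <- assign_fossa_names(graph)
  sort(named$abbreviation[!is.na(named$abbreviation)])
}
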