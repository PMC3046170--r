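# Embedded-graph machinery: face traversal, archetype construction, and the
# structural invariants of the embedding.

test_that("archetype construction is deterministic", {
  a <- make_archetype("cervical_simple")
  b <- make_archetype("cervical_simple")
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_vertebra_file(a, p1); write_vertebra_file(b, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the cervical below-table subchart bounds prcdf, cdf and pocdf", {
  g <- make_archetype("cervical_simple")
  faces <- enumerate_faces(g$charts$lateral)
  sets <- lapply(faces, `[[`, "landmarks_effective")
  below <- Filter(function(s) !"s" %in% s, sets)
  expect_length(below, 3)
  keys <- vapply(below, paste, "", collapse = ",")
  expect_setequal(keys, c("c,d,pr", "c,d", "c,d,po"))
})

test_that("bounded-face count obeys Euler's formula and boundaries cover 2E", {
  set.seed(421)
  for (rep in 1:40) {
    g <- random_archetype()
    for (ch in g$charts) {
      faces <- enumerate_faces(ch)
      expect_identical(length(faces), nrow(ch$edges) - nrow(ch$nodes) + 1L)
      # every directed edge on exactly one face: bounded walks + outer = 2E
      blen <- sum(vapply(faces, function(f) length(f$edge_ids), integer(1)))
      expect_identical(blen + attr(faces, "outer_length"),
                       2L * nrow(ch$edges))
      keys <- unlist(lapply(faces, function(f)
        paste(f$walk$edge, f$walk$from, sep = "@")))
      expect_false(anyDuplicated(keys) > 0)
    }
  }
})

test_that("face boundaries agree with the brute-force region oracle", {
  set.seed(99)
  graphs <- c(lapply(c("cervical_simple", "cervical_eprl", "dorsal_simple",
                       "dorsal_complex", "caudal_simple"), make_archetype),
              replicate(10, random_archetype(), simplify = FALSE))
  for (g in graphs) {
    for (ch in g$charts) {
      if (nrow(ch$edges) > 12) next
      faces <- face_edge_sets(ch)
      expect_true(same_set_of_sets(faces, brute_force_regions(ch)),
                  label = paste("face/region-oracle agreement in",
                                ch$id, "chart"))
      # the boundaries are simple cycles and GF(2)-independent
      key <- function(s) paste(s, collapse = "|")
      expect_true(all(vapply(faces, key, "") %in%
                        vapply(all_cycle_subsets(ch), key, "")))
      expect_true(gf2_independent(faces, ch$edges$id))
    }
  }
})

test_that("naming is invariant under node relabeling", {
  g <- make_archetype("dorsal_complex")
  g$charts <- lapply(g$charts, relabel_chart)
  expect_identical(abbrev_set(g), abbrev_set(make_archetype("dorsal_complex")))
})

test_that("naming is invariant under reflection of the embedding", {
  for (kind in c("cervical_simple", "cervical_eprl", "dorsal_complex")) {
    g <- make_archetype(kind)
    m <- g
    m$charts <- lapply(m$charts, reflect_chart)
    expect_identical(abbrev_set(m), abbrev_set(g))
  }
})

test_that("adding a dividing lamina adds one face per edge and preserves the rest", {
  base <- make_archetype("cervical_simple")
  base_named <- assign_fossa_names(base)

  # eprl: one added edge, one added face, below-table names untouched
  eprl <- make_archetype("cervical_eprl")
  expect_identical(length(enumerate_faces(eprl$charts$lateral)),
                   length(enumerate_faces(base$charts$lateral)) + 1L)
  named <- assign_fossa_names(eprl)
  expect_true(all(c("prcdf", "cdf", "pocdf") %in% named$abbreviation))

  # spdl: splits the sdf, below-table names untouched
  spdl <- make_archetype("cervical_simple", spdl = TRUE)
  expect_identical(length(enumerate_faces(spdl$charts$lateral)),
                   length(enumerate_faces(base$charts$lateral)) + 1L)
  named <- assign_fossa_names(spdl)
  expect_false("sdf" %in% named$abbreviation)
  expect_true(all(c("prsdf", "posdf", "prcdf", "cdf", "pocdf") %in%
                    named$abbreviation))

  # cprl division: two added edges (left and right), two added faces in the
  # anterior chart; faces away from the cprl keep their names
  div <- make_archetype("cervical_simple", divide = "cprl")
  expect_identical(length(enumerate_faces(div$charts$anterior)),
                   length(enumerate_faces(base$charts$anterior)) + 2L)
  named <- assign_fossa_names(div)
  away <- base_named$abbreviation[base_named$boundary_laminae != "cprl"]
  expect_true(all(away %in% named$abbreviation))
})

test_that("dorsal_complex minus its parapophyseal division laminae matches dorsal_simple", {
  cx <- make_archetype("dorsal_complex")$charts$lateral
  keep <- !vapply(cx$edges$laminae, function(l)
    any(l %in% c("pcpl", "prpl")), logical(1))
  stripped <- sort(paste(cx$edges$from[keep], cx$edges$to[keep],
                         vapply(cx$edges$laminae[keep], paste, "", collapse = "+")))
  simple <- make_archetype("dorsal_simple", spdl = TRUE)$charts$lateral
  ref <- sort(paste(simple$edges$from, simple$edges$to,
                    vapply(simple$edges$laminae, paste, "", collapse = "+")))
  expect_identical(stripped, ref)
})

test_that("invalid embeddings and options are rejected", {
  g <- make_archetype("cervical_simple")
  ch <- g$charts$lateral
  ch$rotation$d <- ch$rotation$d[-1]
  expect_error(validate_chart(ch), "invalid embedding")
  expect_error(make_archetype("cervical_simple", divide = "acdl"),
               "not attested as occurring divided")
  expect_error(make_archetype("cervical_eprl", spdl = TRUE), "incompatible")
  expect_error(make_archetype("nonesuch"), "arg")
})

test_that("disconnected charts are rejected", {
  nodes <- data.frame(id = c("a", "b", "x", "y"),
                      landmark = c("c", "d", "pr", "s"),
                      side = "left", stringsAsFactors = FALSE)
  edges <- data.frame(id = c("e1", "e2"), from = c("a", "x"), to = c("b", "y"),
                      stringsAsFactors = FALSE)
  edges$laminae <- I(list("acdl", "sprl"))
  rot <- list(a = "e1", b = "e1", x = "e2", y = "e2")
  expect_error(vertebra_chart("lateral", nodes, edges, rot,
                              outer = list(edge = "e1", from = "a")),
               "disconnected chart")
})
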