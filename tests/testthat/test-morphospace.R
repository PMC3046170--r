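# Complexity scoring above and below the zygodiapophyseal table.

test_that("fossa names zone above or below the table", {
  expect_identical(zone_of("sprf"), "above_table")
  expect_identical(zone_of("prsdf"), "above_table")
  expect_identical(zone_of("sdf1"), "above_table")
  expect_identical(zone_of("sdf2"), "above_table")
  expect_identical(zone_of("pocdf"), "below_table")
  expect_identical(zone_of("cpaf"), "below_table")
  expect_identical(zone_of("prpadf"), "below_table")
  # intralaminar fossae take their parent lamina's zone
  expect_identical(zone_of("spol-f"), "above_table")
  expect_identical(zone_of("cprl-f"), "below_table")
  expect_identical(zone_of("prdl-f"), "below_table")
  expect_identical(zone_of("prdl-f", table_plane = "above"), "above_table")
  expect_error(zone_of("xyzf"), "unparseable")
})

test_that("the worked vertebra scores four, then five, above-table fossae", {
  inv <- new_fossa_inventory(data.frame(
    abbreviation = c("sprf", "spof", "prsdf", "posdf"),
    laterality = c("midline", "midline", "paired", "paired"),
    divided = FALSE, stringsAsFactors = FALSE))
  expect_identical(complexity_score(inv)$above, 4L)
  expect_identical(complexity_score(inv)$below, 0L)
  inv$divided[inv$abbreviation == "sprf"] <- TRUE
  expect_identical(complexity_score(inv)$above, 5L)
})

test_that("an empty inventory scores zero", {
  inv <- new_fossa_inventory(data.frame(abbreviation = character(0),
                                        laterality = character(0),
                                        divided = logical(0)))
  sc <- complexity_score(inv)
  expect_identical(sc$above, 0L)
  expect_identical(sc$below, 0L)
})

test_that("scores are monotone under item addition and midline division", {
  set.seed(7)
  pool <- vapply(enumerate_catalogue("table1")$names, `[[`, "", "abbreviation")
  pool <- setdiff(pool, c("sdf1", "sdf2"))
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    items <- data.frame(
      abbreviation = sample(pool, n),
      laterality = sample(c("midline", "paired"), n, replace = TRUE),
      divided = FALSE, stringsAsFactors = FALSE)
    inv <- new_fossa_inventory(items)
    sc <- complexity_score(inv)
    # adding an item never decreases either count
    extra <- rbind(items, data.frame(abbreviation = "cprl-f",
                                     laterality = "paired", divided = FALSE))
    sc2 <- complexity_score(new_fossa_inventory(extra))
    expect_gte(sc2$above, sc$above)
    expect_gte(sc2$below, sc$below)
    # dividing a midline item raises its zone's count by exactly one
    mid <- which(items$laterality == "midline")
    if (length(mid)) {
      i <- mid[1]
      items2 <- items; items2$divided[i] <- TRUE
      sc3 <- complexity_score(new_fossa_inventory(items2))
      z <- zone_of(items$abbreviation[i])
      if (z == "above_table") {
        expect_identical(sc3$above, sc$above + 1L)
        expect_identical(sc3$below, sc$below)
      } else {
        expect_identical(sc3$below, sc$below + 1L)
        expect_identical(sc3$above, sc$above)
      }
      # a divided paired item is not double-counted
      items3 <- items
      pr <- which(items$laterality == "paired")
      if (length(pr)) {
        items3$divided[pr[1]] <- TRUE
        sc4 <- complexity_score(new_fossa_inventory(items3))
        expect_identical(sc4$above + sc4$below, sc$above + sc$below)
      }
    }
  }
})

test_that("archetype-extracted inventories score as hand counts", {
  # cervical_simple: above = sdf + sprf + spof; below = prcdf, cdf, pocdf,
  # cprf, cpof
  sc <- complexity_score(fossa_inventory(make_archetype("cervical_simple")))
  expect_identical(sc$above, 3L)
  expect_identical(sc$below, 5L)
  # the eprl adds one above-table fossa (sdf -> sdf1 + sdf2)
  sc2 <- complexity_score(fossa_inventory(make_archetype("cervical_eprl")))
  expect_identical(sc2$above, 4L)
  expect_identical(sc2$below, 5L)
  # dorsal_complex: above prsdf, posdf, sprf, spof; below pacdf, cpaf,
  # pacprf, prpadf, pocdf, cprf, cpof
  sc3 <- complexity_score(fossa_inventory(make_archetype("dorsal_complex")))
  expect_identical(sc3$above, 4L)
  expect_identical(sc3$below, 7L)
})

test_that("inventories mixing sdf with its subdivisions are rejected", {
  bad <- data.frame(abbreviation = c("sdf", "sdf1"),
                    laterality = "paired", divided = FALSE)
  expect_error(new_fossa_inventory(bad), "either the undivided sdf")
})

test_that("inventory TSV round-trips through the readers and scorers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    taxon = c("Taxon_a", "Taxon_a", "Taxon_b"),
    position = c("cv6", "cv6", "dv4"),
    abbreviation = c("sdf", "cdf", "pacdf"),
    laterality = "paired", divided = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invs <- read_inventories(path)
  expect_length(invs, 2)
  out <- withr::local_tempfile(fileext = ".tsv")
  scores <- write_complexity_scores(invs, out)
  expect_identical(nrow(scores), 2L)
  expect_identical(sum(scores$above), 1L)  # only the sdf is above
  expect_identical(sum(scores$below), 2L)
})
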