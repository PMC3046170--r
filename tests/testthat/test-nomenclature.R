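# The naming grammar: composition, abbreviation, expansion, parsing,
# catalogue enumeration.

test_that("bipartite and tripartite names compose as published", {
  cases <- list(
    list(lm = c("c", "d"), abbr = "cdf", full = "centrodiapophyseal fossa"),
    list(lm = c("s", "po"), abbr = "spof", full = "spinopostzygapophyseal fossa"),
    list(lm = c("c", "d", "pr"), abbr = "prcdf",
         full = "prezygapophyseal centrodiapophyseal fossa"),
    list(lm = c("c", "pa"), abbr = "cpaf", full = "centroparapophyseal fossa"),
    list(lm = c("pa", "d"), abbr = "padf", full = "paradiapophyseal fossa"),
    list(lm = c("pr", "pa", "d"), abbr = "prpadf",
         full = "prezygapophyseal paradiapophyseal fossa"),
    list(lm = c("pa", "c", "pr"), abbr = "pacprf",
         full = "parapophyseal centroprezygapophyseal fossa"),
    list(lm = c("s", "pr"), abbr = "sprf", full = "spinoprezygapophyseal fossa")
  )
  for (cs in cases) {
    nm <- compose_name(cs$lm)
    expect_identical(abbreviate_name(nm), cs$abbr)
    expect_identical(expand_name(nm), cs$full)
  }
})

test_that("landmark order does not matter and landmarks are never reused", {
  nm1 <- compose_name(c("pr", "c", "d"))
  nm2 <- compose_name(c("d", "pr", "c"))
  expect_identical(nm1$abbreviation, nm2$abbreviation)
  # duplicated input collapses to the set
  expect_identical(compose_name(c("c", "d", "d"))$abbreviation, "cdf")
})

test_that("the symmetric-flank rule names the undivided sdf and cdf", {
  expect_identical(compose_name(c("s", "d", "pr", "po"))$abbreviation, "sdf")
  expect_identical(compose_name(c("c", "d", "pr", "po"))$abbreviation, "cdf")
})

test_that("eprl context is required for the three-primary-landmark sets", {
  expect_error(compose_name(c("s", "pr", "po")), "eprl context required")
  expect_error(compose_name(c("d", "pr", "po")), "eprl context required")
  expect_identical(compose_name(c("s", "pr", "po"), eprl = TRUE)$abbreviation, "sdf1")
  expect_identical(compose_name(c("d", "pr", "po"), eprl = TRUE)$abbreviation, "sdf2")
})

test_that("degenerate and impossible landmark sets are rejected with the violated rule", {
  expect_error(compose_name("d"), "underdetermined fossa")
  expect_error(compose_name(c("s", "c")), "no table landmark")
  expect_error(compose_name(c("c", "pr", "po")), "impossible combination")
  expect_error(compose_name(c("pa", "s", "d")), "impossible combination")
  expect_error(compose_name(c("pa", "po")), "impossible combination")
  expect_error(compose_name(c("pa", "c", "po")), "impossible combination")
  expect_error(compose_name(c("d", "pr")), "impossible combination")
  expect_error(compose_name(c("q", "d")), "unknown landmark code")
})

test_that("sacral mode truncates tripartite names to their bipartite base", {
  expect_identical(compose_name(c("c", "d", "pr"), sacral = TRUE)$abbreviation,
                   "cdf")
  expect_identical(compose_name(c("c", "d"), sacral = TRUE)$abbreviation, "cdf")
})

test_that("exhaustive tripartite enumeration yields exactly the six attested names", {
  # brute force over all 6 bipartite bases x 3 tertiary candidates
  valid <- character(0)
  for (p in c("d", "pr", "po")) for (s in c("s", "c")) for (t in c("pa", "pr", "po")) {
    nm <- tryCatch(compose_name(c(p, s, t)), error = function(e) NULL)
    if (!is.null(nm) && !is.null(nm$tertiary))
      valid <- c(valid, nm$abbreviation)
  }
  expect_setequal(unique(valid),
                  c("pacdf", "prcdf", "pocdf", "prsdf", "posdf", "pacprf"))
})

test_that("catalogue modes reproduce the published counts and members", {
  base <- enumerate_catalogue("base")
  abbr <- vapply(base$names, `[[`, "", "abbreviation")
  tri <- vapply(base$names, function(x) !is.null(x$tertiary), logical(1))
  expect_setequal(abbr[!tri], c("sdf", "cdf", "sprf", "cprf", "spof", "cpof"))
  expect_setequal(abbr[tri],
                  c("pacdf", "prcdf", "pocdf", "prsdf", "posdf", "pacprf"))

  ext <- enumerate_catalogue("extended")
  abbr <- vapply(ext$names, `[[`, "", "abbreviation")
  tri <- vapply(ext$names, function(x) !is.null(x$tertiary), logical(1))
  expect_length(abbr[!tri], 8)
  expect_length(abbr[tri], 7)
  expect_true(all(c("cpaf", "padf", "prpadf") %in% abbr))

  t1 <- enumerate_catalogue("table1")
  abbr <- vapply(t1$names, `[[`, "", "abbreviation")
  expect_length(abbr, 16)
  expect_false("padf" %in% abbr)
  expect_true(all(c("sdf1", "sdf2") %in% abbr))
  # deterministic order: bipartite/special first, then tripartite, each
  # lexicographic
  expect_identical(abbr, abbr[order(vapply(t1$names, function(x)
    !is.null(x$tertiary), logical(1)), abbr, method = "radix")])
})

test_that("abbreviations are injective over each catalogue", {
  for (mode in c("base", "extended", "table1")) {
    abbr <- vapply(enumerate_catalogue(mode)$names, `[[`, "", "abbreviation")
    expect_false(anyDuplicated(abbr) > 0)
    # no generated name reuses a landmark code
    for (nm in enumerate_catalogue(mode)$names) {
      codes <- c(nm$primary, nm$secondary, nm$tertiary)
      expect_false(anyDuplicated(codes) > 0)
    }
  }
})

test_that("parse_name inverts abbreviate_name over every catalogue member", {
  for (mode in c("base", "extended", "table1")) {
    for (nm in enumerate_catalogue(mode)$names) {
      back <- parse_name(nm$abbreviation)
      expect_identical(abbreviate_name(back), nm$abbreviation)
      expect_identical(back$full_name, nm$full_name)
      # full names parse back too
      expect_identical(parse_name(nm$full_name)$abbreviation, nm$abbreviation)
    }
  }
})

test_that("parse_name handles special and intralaminar names", {
  nm <- parse_name("spol-f")
  expect_identical(nm$special, "intralaminar")
  expect_identical(nm$parent_lamina, "spol")
  expect_identical(nm$full_name, "spinopostzygapophyseal lamina fossa")
  expect_identical(parse_name("centroprezygapophyseal lamina fossa")$abbreviation,
                   "cprl-f")
  expect_identical(parse_name("sdf2")$special, "sdf2")
  expect_identical(parse_name("pocdf")$tertiary, "po")
  expect_identical(parse_name("pocdf")$secondary, "c")
  expect_identical(parse_name("pocdf")$primary, "d")
})

test_that("attested spelling variants parse but are never emitted", {
  v <- parse_name("prezygapophyseal parapodiapophyseal fossa")
  expect_identical(v$abbreviation, "prpadf")
  expect_identical(v$full_name, "prezygapophyseal paradiapophyseal fossa")
  # synonym-level extension from a published figure abbreviation list
  syn <- parse_name("prcpaf")
  expect_identical(syn$abbreviation, "prcpaf")
  expect_false("prcpaf" %in%
    vapply(enumerate_catalogue("extended")$names, `[[`, "", "abbreviation"))
})

test_that("unparseable and invalid strings are rejected", {
  expect_error(parse_name("xyzf"), "unparseable name")
  expect_error(parse_name("qq-f"), "unparseable name")
  expect_error(parse_name("prcd"), "unparseable name")
  expect_error(parse_name("prcpof"), "impossible combination")
  expect_error(parse_name("ddf"), "impossible combination|unparseable")
})

test_that("catalogue export table is well-formed", {
  df <- catalogue_table("table1")
  expect_identical(nrow(df), 16L)
  expect_true(all(c("abbreviation", "full_name", "primary", "secondary",
                    "tertiary", "special", "in_base", "in_extended",
                    "in_table1") %in% names(df)))
  expect_true(all(df$in_table1))
  expect_identical(sum(df$in_base), 12L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalogue("extended", path)
  back <- read.delim(path)
  expect_identical(nrow(back), 15L)
})
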