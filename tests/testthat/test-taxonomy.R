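test_that("normalize_lineage drops unclassified and incertae sedis components and prefixes ranks", {
  out <- normalize_lineage(c("Bacteria", "unclassified_Bacteria", "G1"),
                           c("domain", "phylum", "genus"))
  expect_identical(unname(out), c("domain__Bacteria", "genus__G1"))
  expect_identical(names(out), c("domain", "genus"))

  out2 <- normalize_lineage(
    c("Bacteria", "Firmicutes", "Bacilli_incertae_sedis", "G1"),
    c("domain", "phylum", "class", "genus"))
  expect_false("class" %in% names(out2))

  # the same name at two ranks stays distinguishable via prefixes
  out3 <- normalize_lineage(c("Bacteria", "Actinobacteria",
                              "Actinobacteria"),
                            c("domain", "phylum", "class"))
  expect_identical(unname(out3[c("phylum", "class")]),
                   c("phylum__Actinobacteria", "class__Actinobacteria"))
})

test_that("normalize_lineage is idempotent and validates rank structure", {
  lin <- normalize_lineage(c("Bacteria", "P1", "C1", "O1", "F1", "G1"),
                           tax_ranks())
  expect_identical(normalize_lineage(unname(lin)), lin)
  expect_error(normalize_lineage(c("A", "B"), c("phylum", "phylum")),
               "same rank")
  expect_error(normalize_lineage(c("A", "B"), c("genus", "phylum")),
               "increase in depth")
})

test_that("parse_taxonomy_table handles prefixed, positional and empty inputs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\tdomain__Bacteria;phylum__P1;genus__G1;", f)
  ts <- parse_taxonomy_table(f)
  expect_equal(nrow(ts), 1L)
  expect_identical(ts$phylum, "phylum__P1")
  expect_identical(ts$genus, "genus__G1")
  expect_true(all(is.na(ts[, c("class", "order", "family")])))

  writeLines("s1\tBacteria;P1;C1;O1;F1;G1", f)
  ts2 <- parse_taxonomy_table(
    f, taxonomy_dialect("positional", ranks = tax_ranks()))
  expect_identical(ts2$class, "class__C1")
  expect_equal(sum(!is.na(ts2[1, tax_ranks()])), 6L)

  writeLines(character(0), f)
  expect_equal(nrow(parse_taxonomy_table(f)), 0L)
})

test_that("parse_taxonomy_table reports malformed lines and duplicate IDs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tdomain__Bacteria;", "oops-no-tab"), f)
  expect_error(parse_taxonomy_table(f), "line 2")
  writeLines(c("s1\tdomain__Bacteria;", "s1\tdomain__Bacteria;"), f)
  expect_error(parse_taxonomy_table(f), "s1")
})

test_that("taxonomy write -> parse round-trips byte-identically", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a1\tdomain__Bacteria;phylum__P1;genus__G1;species__Sp one;",
               "a2\tdomain__Bacteria;phylum__P2;class__C2;genus__G2;"), f1)
  ts <- parse_taxonomy_table(f1)
  write_taxonomy_table(ts, f2)
  expect_identical(readLines(f2), readLines(f1))
  expect_identical(parse_taxonomy_table(f2), ts)
})

test_that("species names lose subspecies designations during parsing", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\tdomain__Bacteria;genus__G1;species__Bacillus cereus subsp. thuringiensis;",
             f)
  ts <- parse_taxonomy_table(f)
  expect_identical(ts$species, "Bacillus cereus")
})

test_that("trim_to_genus clears species and leaves lineages untouched", {
  ts <- make_ts("s1", "ACGT", "G1", species = "sp x")
  tr <- trim_to_genus(ts)
  expect_true(is.na(tr$species))
  expect_identical(tr$genus, ts$genus)
  # genus-terminal and gap lineages are no-ops beyond the species field
  ts$genus <- NA_character_
  expect_identical(trim_to_genus(ts)$family, ts$family)
})

test_that("ranks_omitted_below reflects hierarchy gaps", {
  paths <- data.frame(
    domain = "domain__Bacteria",
    phylum = c("phylum__P1", "phylum__P2", "phylum__P3"),
    class = c("class__C1", "class__C2", NA),
    order = c("order__O1", NA, NA),
    family = c("family__F1", NA, NA),
    genus = c("genus__G1", "genus__G2", NA),
    stringsAsFactors = FALSE
  )
  tree <- taxonomy_tree(paths)
  expect_setequal(ranks_omitted_below(tree, "phylum__P3"),
                  c("class", "order", "family", "genus"))
  expect_setequal(ranks_omitted_below(tree, "phylum__P2"),
                  c("order", "family"))
  expect_length(ranks_omitted_below(tree, "phylum__P1"), 0L)
  expect_error(ranks_omitted_below(tree, "phylum__Px"), "unknown taxon")
})

test_that("every rank appears at most once per parsed record", {
  fx <- fixture_spec(seed = 3)
  sim <- gen_alignment(fx)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy_table(sim$training, f)
  ts <- parse_taxonomy_table(f)
  for (r in tax_ranks()) {
    pr <- ts[[r]][!is.na(ts[[r]])]
    expect_true(all(startsWith(pr, paste0(r, "__"))))
  }
})
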