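test_that("abbreviation rule counts capitals and digits strictly over half", {
  expect_true(is_abbreviation("DNA"))       # 3/3
  expect_false(is_abbreviation("water"))    # 0/5
  expect_true(is_abbreviation("Ab1"))       # 2/3 > 1.5
  expect_false(is_abbreviation("Abc1"))     # 2/4, tie is not a majority
  expect_true(is_abbreviation("H2 O2"))     # whitespace excluded: 4/4
  expect_error(is_abbreviation(""), "non-empty")
})

test_that("terms are routed by abbreviation status and stoplist filters whole terms", {
  entries <- compound_entries("C1", "InChI=1S/X",
                              list(c("Aspirin", "ASA")))
  lex <- build_lexicon(entries, stoplist = character())
  expect_true("aspirin" %in% lex$folded$key)
  expect_true("ASA" %in% lex$exact$key)
  expect_false("Aspirin" %in% lex$exact$key)
  # routing invariant: every stored term sits in exactly the map
  # is_abbreviation() says
  for (k in lex$exact$key) expect_true(is_abbreviation(k))
  for (k in lex$folded$key) expect_false(is_abbreviation(k))

  lex2 <- tiny_lexicon(stoplist = c("lead"))
  expect_equal(length(lexicon_lookup(lex2, "lead")$ids), 0L)
  expect_equal(lexicon_lookup(lex2, "lead acetate")$ids, "C4")
  # stoplist matching is case-insensitive
  lex3 <- tiny_lexicon(stoplist = c("LEAD"))
  expect_equal(length(lexicon_lookup(lex3, "lead")$ids), 0L)

  empty <- build_lexicon(compound_entries(character(), character(), list()))
  expect_equal(length(lexicon_terms(empty)), 0L)
})

test_that("merging collapses identical InChI strings and unions terms", {
  a <- compound_entries("B9", "InChI=1S/X", list("p"), "dbA")
  b <- compound_entries("A1", "InChI=1S/X", list("q"), "dbB")
  c_ <- compound_entries("C5", "InChI=1S/Y", list("r"), "dbB")
  m <- merge_lexicons(list(a, b, c_))
  expect_equal(nrow(m), 2L)
  i <- which(m$inchi == "InChI=1S/X")
  expect_equal(m$compound_id[i], "A1")  # smallest member id survives
  expect_setequal(m$terms[[i]], c("p", "q"))
  expect_equal(m$source_db[i], "dbA+dbB")

  # entries without an InChI are skipped with a warning
  d <- compound_entries("D1", "", list("s"))
  expect_warning(m2 <- merge_lexicons(list(a, d)), "without an InChI")
  expect_equal(nrow(m2), 1L)
})

test_that("merging is idempotent and order-independent", {
  world <- synth_world(seed = 77L)
  a <- world$compounds$a
  b <- world$compounds$b
  m1 <- merge_lexicons(list(a, b))
  m2 <- merge_lexicons(list(b, a))
  m3 <- merge_lexicons(list(a, a, b, b, a))
  expect_identical(m1, m2)
  expect_identical(m1, m3)
  expect_equal(nrow(m1), world$compounds$n_distinct_inchi)
  # overlap-fraction extremes
  cfg <- world$cfg
  full <- make_compounds(cfg, overlap_fraction = 1)
  expect_equal(nrow(merge_lexicons(list(full$a, full$b))), nrow(full$a))
  none <- make_compounds(cfg, overlap_fraction = 0)
  expect_equal(nrow(merge_lexicons(list(none$a, none$b))),
               nrow(none$a) + nrow(none$b))
})

test_that("lexicon source files round-trip", {
  world <- synth_world(seed = 31L, n_compounds = 15L)
  path <- withr::local_tempfile()
  merged <- merge_lexicons(list(world$compounds$a, world$compounds$b))
  write_lexicon_entries(merged, path)
  back <- read_lexicon_entries(path, source_db = merged$source_db[1])
  expect_equal(back$compound_id, merged$compound_id)
  expect_equal(back$inchi, merged$inchi)
  expect_equal(lapply(back$terms, sort), lapply(merged$terms, sort))
})

test_that("stoplisted terms are unreachable after build", {
  stop_terms <- c("about", "all", "make")
  entries <- compound_entries(
    c("C1", "C2"), c("InChI=1S/A", "InChI=1S/B"),
    list(c("about", "aboutanol"), c("all", "make", "benzol"))
  )
  lex <- build_lexicon(entries, stoplist = stop_terms)
  for (t in stop_terms) {
    expect_equal(length(lexicon_lookup(lex, t)$ids), 0L)
  }
  expect_gt(length(lexicon_lookup(lex, "aboutanol")$ids), 0L)
  # add/remove round trip
  lex <- lexicon_add_terms(lex, c("newterm", "NT1"))
  expect_gt(length(lexicon_lookup(lex, "NewTerm")$ids), 0L)
  expect_gt(length(lexicon_lookup(lex, "NT1")$ids), 0L)
  expect_equal(length(lexicon_lookup(lex, "nt1")$ids), 0L)  # abbreviation stays case-sensitive
  lex <- lexicon_remove_terms(lex, c("newterm", "NT1"))
  expect_equal(length(lexicon_lookup(lex, "newterm")$ids), 0L)
  expect_equal(length(lexicon_lookup(lex, "NT1")$ids), 0L)
})
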