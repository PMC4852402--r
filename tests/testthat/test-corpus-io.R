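test_that("records parse line-by-line and reject malformed input", {
  path <- withr::local_tempfile()
  writeLines(c("P1\tA title\tAn abstract", "P2\t\tOnly abstract"), path)
  corpus <- read_records(path)
  expect_equal(n_records(corpus), 2L)
  expect_equal(corpus$records$title[1], "A title")
  expect_equal(corpus$records$title[2], "")

  writeLines(character(), path)
  expect_equal(n_records(read_records(path)), 0L)

  writeLines("P1\tonly-two-fields", path)
  expect_error(read_records(path), "line 1")
  writeLines(c("P1\ta\tb", "P1\tc\td"), path)
  expect_error(read_records(path), "duplicate doc_id")
  expect_error(read_records(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("annotations are slice-checked against the corpus", {
  corpus <- tiny_corpus()
  path <- withr::local_tempfile()
  writeLines("P1\tT\t0\t7\tAspirin", path)
  spans <- read_annotations(path, corpus)
  expect_equal(nrow(spans), 1L)
  expect_equal(spans$source, "gold")
  expect_equal(spans$surface, "Aspirin")

  writeLines("P1\tT\t0\t7\tIbuprofen", path)
  expect_error(read_annotations(path, corpus), "surface mismatch")
  writeLines("P1\tT\t0\t99\tAspirin", path)
  expect_error(read_annotations(path, corpus), "out of range")
  writeLines("PX\tT\t0\t7\tAspirin", path)
  expect_error(read_annotations(path, corpus), "unknown doc_id")
  # optional class column is preserved
  writeLines("P1\tT\t0\t7\tAspirin\ttrivial", path)
  expect_equal(read_annotations(path, corpus)$class, "trivial")
})

test_that("prediction files carry per-document confidence ranks", {
  corpus <- tiny_corpus()
  spans <- validate_spans(mention_spans(
    c("P1", "P1", "P2"), c("A", "T", "T"), c(0, 0, 9), c(7, 7, 13),
    c("Aspirin", "Aspirin", "DMSO"), source = "dict",
    confidence = c(0.4, 0.9, 1)
  ), corpus)
  path <- withr::local_tempfile()
  write_predictions(spans, path)
  lines <- readLines(path)
  expect_equal(lines[1], "P1\tT:0:7\t1\t0.9")
  expect_equal(lines[2], "P1\tA:0:7\t2\t0.4")
  expect_equal(lines[3], "P2\tT:9:13\t1\t1")
  expect_error(write_predictions(mention_spans("P1", "T", 0, 7, "Aspirin"),
                                 path), "validate")
})

test_that("record, annotation and prediction round trips are stable", {
  world <- synth_world(seed = 402L, n_records = 20L)
  corpus <- world$corpus
  d <- withr::local_tempdir()
  rp <- file.path(d, "records.tsv")
  ap <- file.path(d, "gold.tsv")
  pp <- file.path(d, "pred.tsv")

  write_records(corpus, rp)
  back <- read_records(rp)
  expect_identical(back$records, corpus$records)

  write_annotations(corpus$gold, ap)
  g2 <- read_annotations(ap, back)
  o <- order(g2$doc_id, g2$passage, g2$start, g2$end)
  g1 <- corpus$gold[order(corpus$gold$doc_id, corpus$gold$passage,
                          corpus$gold$start, corpus$gold$end), ]
  expect_equal(g2[o, c("doc_id", "passage", "start", "end", "surface")],
               g1[, c("doc_id", "passage", "start", "end", "surface")],
               ignore_attr = TRUE)

  pred <- tag_corpus_dict(corpus, world$lexicon)
  write_predictions(pred, pp)
  p2 <- read_predictions(pp, corpus, source = "dict")
  expect_setequal(span_key <- paste(p2$doc_id, p2$passage, p2$start, p2$end),
                  paste(pred$doc_id, pred$passage, pred$start, pred$end))
  # byte-identical across repeated writes
  pp2 <- file.path(d, "pred2.tsv")
  write_predictions(pred, pp2)
  expect_identical(readLines(pp), readLines(pp2))
})

test_that("corpus validation enforces the span invariants", {
  expect_error(chem_corpus(data.frame(doc_id = "", title = "t",
                                      abstract = "a")), "non-empty")
  corpus <- tiny_corpus()
  bad <- mention_spans("P1", "T", 3, 2, "x")
  expect_error(validate_spans(bad, corpus), "out of range")
  ok <- validate_spans(mention_spans("P1", "T", 0, 7, "Aspirin"), corpus)
  expect_true(attr(ok, "validated"))
})
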