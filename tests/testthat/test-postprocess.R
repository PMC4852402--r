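test_that("tagging consistency propagates surfaces tagged at least twice", {
  text <- "ibuprofen was mixed with ibuprofen and more ibuprofen today"
  sp <- mention_spans("d", "A", c(0, 25), c(9, 34),
                      c("ibuprofen", "ibuprofen"),
                      source = "crf", confidence = c(0.8, 0.6))
  out <- enforce_consistency(sp, text)
  expect_equal(nrow(out), 3L)
  added <- out[out$start == 44, ]
  expect_equal(added$confidence, 0.7)  # mean of the existing spans
  # below the threshold nothing happens
  one <- sp[1, ]
  expect_equal(nrow(enforce_consistency(one, text)), 1L)
  # idempotent
  expect_equal(nrow(enforce_consistency(out, text)), 3L)
})

test_that("consistency matching is case-sensitive and token-aligned", {
  text <- "Abc abc Abc abcdef"
  sp <- mention_spans("d", "A", c(0, 8), c(3, 11), c("Abc", "Abc"),
                      source = "crf", confidence = 1)
  out <- enforce_consistency(sp, text)
  # lowercase "abc" and the prefix inside "abcdef" are not propagated
  expect_equal(nrow(out), 2L)
})

test_that("abbreviation definitions propagate tags to both forms", {
  text <- "dimethyl sulfoxide (DMSO) was used; DMSO again"
  sp <- mention_spans("d", "A", 0, 18, "dimethyl sulfoxide",
                      source = "crf", confidence = 0.9)
  out <- resolve_abbreviations(sp, text)
  expect_true(any(out$surface == "DMSO" & out$start == 20))
  expect_true(any(out$surface == "DMSO" & out$start == 36))
  # short form tagged -> long form gains a span too
  sp2 <- mention_spans("d", "A", 20, 24, "DMSO", source = "crf",
                       confidence = 0.9)
  out2 <- resolve_abbreviations(sp2, text)
  expect_true(any(out2$start == 0 & out2$end == 18))
  # untagged pairs change nothing
  t3 <- "United States (US) trade"
  expect_equal(nrow(resolve_abbreviations(empty_spans(), t3)), 0L)
  # no parentheses: identity
  t4 <- "no definitions here"
  sp4 <- mention_spans("d", "A", 0, 2, "no", source = "crf", confidence = 1)
  expect_identical(resolve_abbreviations(sp4, t4), sp4)
})

test_that("boundary revision balances brackets by extension or trimming", {
  text <- "a 2-(chloroethyl) derivative"
  r <- revise_boundaries(2, 16, text)   # "2-(chloroethyl" + following ")"
  expect_equal(c(r$start, r$end), c(2, 17))
  text2 <- "pure aspirin) here"
  r2 <- revise_boundaries(5, 13, text2)  # "aspirin)" with no "("
  expect_equal(c(r2$start, r2$end), c(5, 12))
  r3 <- revise_boundaries(2, 17, text)   # balanced span unchanged
  expect_equal(c(r3$start, r3$end), c(2, 17))
  # result is always balanced or the input
  set.seed(30)
  chars <- c(letters[1:4], "(", ")", "[", "]")
  for (i in 1:60) {
    tx <- paste(sample(chars, 12, replace = TRUE), collapse = "")
    s <- sample(0:6, 1); e <- s + sample(2:5, 1)
    r <- revise_boundaries(s, e, tx)
    surf <- substr(tx, r$start + 1, r$end)
    imb <- sapply(list(c("(", ")"), c("[", "]")), function(p) {
      stringi::stri_count_fixed(surf, p[1]) -
        stringi::stri_count_fixed(surf, p[2])
    })
    expect_true(all(imb == 0) || (r$start == s && r$end == e))
  }
})

test_that("identifier regexes find CAS numbers with word boundaries", {
  ids <- tag_identifiers("water is 7732-18-5 here")
  expect_equal(ids$surface, "7732-18-5")
  expect_equal(nrow(tag_identifiers("12-34 is no CAS number")), 0L)
  ids2 <- tag_identifiers("CAS 50-00-0.")
  expect_equal(ids2$surface, "50-00-0")  # trailing period excluded
  # checksum flag filters invalid check digits
  cfg <- postprocess_config(cas_checksum = TRUE)
  expect_equal(tag_identifiers("7732-18-5 ok", cfg)$surface, "7732-18-5")
  expect_equal(nrow(tag_identifiers("7732-18-4 bad", cfg)), 0L)
  expect_error(postprocess_config(identifier_patterns = c(bad = "([")),
               "compile")
})

test_that("the full chain emits only slice-valid passage-bounded spans", {
  records <- data.frame(
    doc_id = "Z1",
    title = "benzol (BZ) report",
    abstract = "benzol and benzol plus BZ and CAS 7732-18-5 end",
    stringsAsFactors = FALSE
  )
  corpus <- chem_corpus(records)
  spans <- validate_spans(mention_spans(
    c("Z1", "Z1", "Z1"), c("T", "A", "A"), c(0, 0, 11), c(6, 6, 17),
    c("benzol", "benzol", "benzol"), source = "crf", confidence = 0.9
  ), corpus)
  out <- postprocess_spans(spans, corpus)
  expect_true(attr(out, "validated"))
  # consistency: nothing new in title (count 1), abstract already has both
  # abbreviation: BZ defined in the title, so tagged there (rules act
  # within one passage; the bare abstract BZ has no definition)
  expect_true(any(out$passage == "T" & out$surface == "BZ"))
  # identifier: CAS number tagged
  expect_true(any(out$surface == "7732-18-5"))
  # idempotence of the chain on its own output
  out2 <- postprocess_spans(out, corpus)
  expect_equal(nrow(out2), nrow(out))
})
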