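make_tuning_world <- function() {
  # "goodterm" fires mostly on gold, "lead" mostly as an ordinary word
  records <- data.frame(
    doc_id = c("D1", "D2", "D3"),
    title = c("goodterm salt", "lead in paint", "lead acetate sample"),
    abstract = c("the goodterm was pure and lead was found",
                 "goodterm and goodterm again with lead",
                 "no chemicals here at all"),
    stringsAsFactors = FALSE
  )
  gold <- mention_spans(
    c("D1", "D1", "D2", "D2", "D3"),
    c("T", "A", "A", "A", "T"),
    c(0, 4, 0, 13, 0), c(8, 12, 8, 21, 12),
    c("goodterm", "goodterm", "goodterm", "goodterm", "lead acetate"),
    source = "gold"
  )
  corpus <- chem_corpus(records, gold = gold)
  entries <- compound_entries(
    c("C1", "C2"), c("InChI=1S/G", "InChI=1S/L"),
    list("goodterm", c("lead", "lead acetate"))
  )
  list(corpus = corpus, lexicon = build_lexicon(entries, character()))
}

test_that("term statistics aggregate exact-match TPs and FPs by lookup key", {
  w <- make_tuning_world()
  pred <- tag_corpus_dict(w$corpus, w$lexicon)
  stats <- collect_term_stats(pred, w$corpus$gold, w$corpus)
  good <- stats[stats$term == "goodterm", ]
  expect_equal(good$tp, 4L)
  expect_equal(good$fp, 0L)
  expect_equal(good$ratio, Inf)
  lead <- stats[stats$term == "lead", ]
  expect_equal(lead$tp, 0L)
  expect_equal(lead$fp, 3L)  # D1 A, D2 T, D2 A bare "lead"
  expect_equal(lead$ratio, 0)
  la <- stats[stats$term == "lead acetate", ]
  expect_equal(la$tp, 1L)
  expect_equal(la$fp, 0L)
  # no predictions -> empty stats
  expect_equal(nrow(collect_term_stats(empty_spans(), w$corpus$gold,
                                       w$corpus)), 0L)
})

test_that("statistics agree with a hand-built 5-fires-1-match example", {
  records <- data.frame(
    doc_id = "H1", title = "amber light",
    abstract = "amber and amber and amber with amber glow",
    stringsAsFactors = FALSE
  )
  gold <- mention_spans("H1", "T", 0, 5, "amber", source = "gold")
  corpus <- chem_corpus(records, gold = gold)
  lex <- build_lexicon(compound_entries("C1", "InChI=1S/A", list("amber")),
                       character())
  stats <- collect_term_stats(tag_corpus_dict(corpus, lex), gold, corpus)
  expect_equal(stats$tp, 1L)
  expect_equal(stats$fp, 4L)
  expect_equal(stats$ratio, 0.25)
  expect_equal(derive_exclusions(stats, tuning_config()), "amber")
})

test_that("exclusion keeps ratios at or above threshold and removes below", {
  stats <- data.frame(
    term = c("a", "b", "c", "d"),
    tp = c(1L, 3L, 0L, 5L), fp = c(4L, 1L, 1L, 0L),
    ratio = c(0.25, 3, 0, Inf), stringsAsFactors = FALSE
  )
  excl <- derive_exclusions(stats, tuning_config(exclusion_threshold = 0.3))
  expect_setequal(excl, c("a", "c"))
})

test_that("excluded terms re-tag to zero detections (self-consistency)", {
  w <- make_tuning_world()
  pred <- tag_corpus_dict(w$corpus, w$lexicon)
  stats <- collect_term_stats(pred, w$corpus$gold, w$corpus)
  excl <- derive_exclusions(stats)
  expect_true("lead" %in% excl)
  lex2 <- lexicon_remove_terms(w$lexicon, excl)
  pred2 <- tag_corpus_dict(w$corpus, lex2)
  expect_false(any(pred2$term_key %in% excl))
  # idempotence: a second derivation pass removes nothing new
  stats2 <- collect_term_stats(pred2, w$corpus$gold, w$corpus)
  expect_equal(length(derive_exclusions(stats2)), 0L)
})

test_that("inclusion admits missed terms by their re-tag condition", {
  records <- data.frame(
    doc_id = c("M1", "M2"),
    title = c("novochem works", "badword here"),
    abstract = c("we tried novochem twice novochem",
                 "badword and badword and badword and badword again"),
    stringsAsFactors = FALSE
  )
  gold <- mention_spans(
    c("M1", "M1", "M1", "M2"), c("T", "A", "A", "T"),
    c(0, 9, 24, 0), c(8, 17, 32, 7),
    c("novochem", "novochem", "novochem", "badword"), source = "gold"
  )
  corpus <- chem_corpus(records, gold = gold)
  lex <- build_lexicon(compound_entries("C1", "InChI=1S/Z", list("zeta")),
                       character())
  pred <- tag_corpus_dict(corpus, lex)  # finds nothing
  incl <- derive_inclusions(gold, pred, corpus, lex,
                            tuning_config(inclusion_threshold = 0.5))
  # novochem: every occurrence is gold -> fp = 0 -> admitted
  expect_true("novochem" %in% incl)
  # badword: 1 gold, 4 non-gold occurrences -> ratio 0.25 -> rejected
  expect_false("badword" %in% incl)
})

test_that("every admitted term re-verifies its own admission condition", {
  world <- synth_world(seed = 21L, n_records = 40L, homograph = 0.15,
                       unseen = 0.25)
  corpus <- world$corpus
  lex <- world$lexicon
  pred <- tag_corpus_dict(corpus, lex)
  cfg <- tuning_config()
  incl <- derive_inclusions(corpus$gold, pred, corpus, lex, cfg)
  for (term in incl) {
    lex2 <- lexicon_add_terms(lex, term)
    p2 <- tag_corpus_dict(corpus, lex2)
    mine <- p2[p2$term_key == ifelse(is_abbreviation(term), term,
                                     tolower(term)), , drop = FALSE]
    tp <- sum(paste(mine$doc_id, mine$passage, mine$start, mine$end) %in%
                paste(corpus$gold$doc_id, corpus$gold$passage,
                      corpus$gold$start, corpus$gold$end))
    fp <- nrow(mine) - tp
    expect_true(fp == 0L || tp / fp > cfg$inclusion_threshold,
                label = sprintf("admission condition for '%s'", term))
  }
})
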