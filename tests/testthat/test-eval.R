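test_that("metrics follow the count formulas with two-decimal rendering", {
  m <- metrics_from_counts(detection_counts(tp = 2, fp = 1, fn = 2, tn = 5))
  expect_equal(render_pct(m$precision), "66.67")
  expect_equal(render_pct(m$recall), "50.00")
  expect_equal(render_pct(m$f_score), "57.14")
  expect_equal(render_pct(m$specificity), "83.33")
  expect_equal(render_pct(m$accuracy), "70.00")
  # perfect detection
  p <- metrics_from_counts(detection_counts(3, 0, 0))
  expect_equal(render_pct(c(p$precision, p$recall, p$f_score)),
               rep("100.00", 3))
  # all-zero counts: metrics absent, not zero
  z <- metrics_from_counts(detection_counts(0, 0, 0))
  expect_true(is.na(z$precision) && is.na(z$recall) && is.na(z$f_score))
})

test_that("harmonic-mean and weighted-accuracy identities hold", {
  expect_equal(render_pct(f_from_precision_recall(84.88, 85.55)), "85.21")
  expect_equal(render_pct(accuracy_from_sens_spec(97.00, 82.74,
                                                  8937, 5063)), "91.84")
  expect_true(is.na(f_from_precision_recall(0, 0)))
})

test_that("mention evaluation matches exactly and pools micro-averaged", {
  gold <- mention_spans(c("d1", "d1"), c("T", "A"), c(0, 5), c(7, 10),
                        c("x", "y"), source = "gold")
  pred <- mention_spans(c("d1", "d1"), c("T", "A"), c(0, 4), c(7, 10),
                        c("x", "z"), source = "dict")
  r <- evaluate_mentions(pred, gold)
  expect_equal(r$counts$tp, 1)
  expect_equal(r$counts$fp, 1)
  expect_equal(r$counts$fn, 1)
  expect_equal(render_pct(r$metrics$f_score), "50.00")
  # identical sets give 100
  perfect <- evaluate_mentions(gold, gold)
  expect_equal(render_pct(perfect$metrics$f_score), "100.00")
  # duplicates collapse before counting
  expect_message(dup <- evaluate_mentions(rbind(pred, pred), gold),
                 "duplicate")
  expect_equal(dup$counts$fp, 1)
  # document order does not matter
  sh <- evaluate_mentions(pred[2:1, ], gold[2:1, ])
  expect_equal(sh$counts$tp, r$counts$tp)
})

test_that("evaluation agrees with brute-force recounting on random sets", {
  set.seed(17)
  for (i in 1:200) {
    w <- random_span_set()
    got <- suppressMessages(evaluate_mentions(w$pred, w$gold))
    pred <- w$pred[!duplicated(paste(w$pred$doc_id, w$pred$passage,
                                     w$pred$start, w$pred$end)), ]
    want <- oracle_mention_counts(pred, w$gold)
    expect_equal(got$counts$tp, want$tp)
    expect_equal(got$counts$fp, want$fp)
    expect_equal(got$counts$fn, want$fn)
    # structural invariants
    expect_equal(got$counts$tp + got$counts$fn,
                 nrow(unique(w$gold[, c("doc_id", "passage", "start", "end")])))
    m <- got$metrics
    if (!is.na(m$f_score)) {
      expect_gte(m$f_score, min(m$precision, m$recall) - 1e-9)
      expect_lte(m$f_score, max(m$precision, m$recall) + 1e-9)
    }
  }
})

test_that("ensemble union keeps everything and merges exact duplicates", {
  a <- mention_spans("d1", "T", 0, 7, "aspirin", source = "dict",
                     confidence = 1)
  b <- mention_spans(c("d1", "d1"), c("T", "T"), c(0, 10), c(7, 15),
                     c("aspirin", "other"), source = "crf",
                     confidence = c(0.6, 0.8))
  u <- ensemble_union(a, b)
  expect_equal(nrow(u), 2L)
  expect_equal(u$confidence[u$start == 0], 1)  # max of member confidences
  expect_true(all(u$source == "ensemble"))
  # overlapping-but-different spans are both kept
  c_ <- mention_spans("d1", "T", 2, 9, "pirin x", source = "crf",
                      confidence = 0.5)
  expect_equal(nrow(ensemble_union(a, c_)), 2L)
})

test_that("union recall is never below the best member recall", {
  world <- synth_world(seed = 55L, n_records = 30L, unseen = 0.3)
  gold <- world$corpus$gold
  dict <- tag_corpus_dict(world$corpus, world$lexicon)
  # a fake second system: the gold spans of even records only
  crf <- gold[seq(2, nrow(gold), by = 2), ]
  crf$source <- "crf"
  u <- ensemble_union(dict, crf)
  ru <- evaluate_mentions(u, gold)$metrics$recall
  rd <- evaluate_mentions(dict, gold)$metrics$recall
  rc <- evaluate_mentions(crf, gold)$metrics$recall
  expect_gte(ru, max(rd, rc))
})

test_that("passage classification is span-count-driven, per passage", {
  world <- synth_world(seed = 70L, n_records = 15L)
  spans <- tag_corpus_dict(world$corpus, world$lexicon)
  labels <- classify_passages(spans, world$corpus)
  expect_equal(nrow(labels), 2L * n_records(world$corpus))
  for (i in sample(nrow(labels), 10)) {
    n <- sum(spans$doc_id == labels$doc_id[i] &
               spans$passage == labels$passage[i])
    expect_equal(labels$label[i] == "chemical", n > 0)
  }
  expect_equal(classify_passage(spans[0, ]), "non-chemical")
  expect_equal(classify_passage(spans[1:3, ]), "chemical")
})

test_that("passage-level confusion counts drive sensitivity and specificity", {
  pred <- data.frame(doc_id = c("a", "b", "c"), passage = "T",
                     label = c("chemical", "chemical", "non-chemical"),
                     stringsAsFactors = FALSE)
  gold <- data.frame(doc_id = c("a", "b", "c"), passage = "T",
                     label = c("chemical", "non-chemical", "non-chemical"),
                     stringsAsFactors = FALSE)
  r <- evaluate_cpd(pred, gold)
  expect_equal(unlist(r$counts[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 0, tn = 1))
  expect_equal(render_pct(r$metrics$accuracy), "66.67")
  # mismatched coverage is refused loudly
  expect_error(evaluate_cpd(pred[1:2, ], gold), "different passages")
  # all correct
  perfect <- evaluate_cpd(gold, gold)
  expect_equal(render_pct(perfect$metrics$accuracy), "100.00")
})
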