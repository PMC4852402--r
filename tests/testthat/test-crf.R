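test_that("BIO encoding and decoding are exact inverses on aligned spans", {
  text <- "alpha beta gamma delta"
  toks <- tokenize(text)
  spans <- data.frame(start = c(0L, 11L), end = c(10L, 16L))
  labels <- bio_encode(spans, toks)
  expect_equal(labels, c("B", "I", "B", "O"))
  back <- bio_decode(labels, toks, text)
  expect_equal(back[, c("start", "end")], spans, ignore_attr = TRUE)
  expect_equal(back$surface, c("alpha beta", "gamma"))
  # all-O decodes to nothing
  expect_equal(nrow(bio_decode(rep("O", 4), toks, text)), 0L)
})

test_that("random token-aligned span sets round-trip through BIO", {
  set.seed(4)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    words <- replicate(n, paste(sample(letters, sample(2:6, 1),
                                       replace = TRUE), collapse = ""))
    text <- paste(words, collapse = " ")
    toks <- tokenize(text)
    # non-overlapping random token runs
    k <- sample(0:3, 1)
    free <- seq_len(n)
    spans <- NULL
    for (s in seq_len(k)) {
      if (!length(free)) break
      i <- sample(free, 1)
      j <- min(i + sample(0:2, 1), max(free[free >= i]))
      if (!all(i:j %in% free)) next
      spans <- rbind(spans, data.frame(start = toks$start[i],
                                       end = toks$end[j]))
      free <- setdiff(free, (i - 1):(j + 1))
    }
    labels <- bio_encode(spans, toks)
    back <- bio_decode(labels, toks, text)
    want <- if (is.null(spans)) {
      data.frame(start = integer(), end = integer())
    } else spans[order(spans$start), ]
    expect_equal(back[, c("start", "end")], want, ignore_attr = TRUE)
  }
})

test_that("invalid BIO sequences are repaired by treating bare I as B", {
  text <- "one two three"
  toks <- tokenize(text)
  got <- bio_decode(c("O", "I", "I"), toks, text)
  expect_equal(nrow(got), 1L)
  expect_equal(got$surface, "two three")
})

test_that("degenerate training inputs are refused", {
  expect_error(crf_train(list()), "no training sequences")
  text <- "plain words only"
  toks <- tokenize(text)
  seqs <- list(list(doc_id = "d", passage = "T", text = text, tokens = toks,
                    features = token_features(toks),
                    labels = rep("O", nrow(toks))))
  expect_error(crf_train(seqs), "no B label")
})

test_that("the CRF separates flagged tokens and overfits separable data", {
  # tokens carrying a unique feature flag are the mentions
  set.seed(8)
  mk_seq <- function(n, flag_at) {
    words <- replicate(n, paste(sample(letters[1:6], 3, replace = TRUE),
                                collapse = ""))
    text <- paste(words, collapse = " ")
    toks <- tokenize(text)
    feats <- lapply(seq_len(n), function(i) {
      c(sprintf("pos=%d", i %% 3),
        if (i %in% flag_at) "chemflag=TRUE" else "chemflag=FALSE")
    })
    labels <- ifelse(seq_len(n) %in% flag_at, "B", "O")
    list(doc_id = "d", passage = "A", text = text, tokens = toks,
         features = feats, labels = labels)
  }
  train <- lapply(1:20, function(i) mk_seq(8, sample(8, 2)))
  test <- lapply(1:10, function(i) mk_seq(8, sample(8, 2)))
  model <- crf_train(train, max_iter = 80)
  # held-out sequences with the same flag are recovered
  pred <- crf_predict(model, test)
  for (k in seq_along(test)) {
    expect_equal(pred[[k]]$labels, test[[k]]$labels)
    expect_true(all(pred[[k]]$marginal >= 0 & pred[[k]]$marginal <= 1))
  }
  # training data reproduced (>= 95% of labels)
  fit <- crf_predict(model, train)
  agree <- mean(unlist(Map(function(a, b) a$labels == b$labels, fit, train)))
  expect_gte(agree, 0.95)
})

test_that("prediction is deterministic and rejects alien feature schemas", {
  world <- synth_world(seed = 63L, n_records = 20L)
  seqs <- make_crf_sequences(world$corpus)
  model <- crf_train(seqs, max_iter = 60)
  s1 <- tag_corpus_crf(world$corpus, model)
  s2 <- tag_corpus_crf(world$corpus, model)
  expect_identical(s1, s2)
  alien <- list(list(doc_id = "d", passage = "T", text = "x y",
                     tokens = tokenize("x y"),
                     features = list("zz=1", "zz=2")))
  expect_error(crf_predict(model, alien), "schema mismatch")
})

test_that("pre-processing keeps CRF spans valid in original coordinates", {
  records <- data.frame(
    doc_id = "U1", title = "α-pinene study",
    abstract = "the α-pinene and [|] markers plus α-pinene again",
    stringsAsFactors = FALSE
  )
  gold <- mention_spans(c("U1", "U1", "U1"), c("T", "A", "A"),
                        c(0, 4, 34), c(8, 12, 42),
                        c("α-pinene", "α-pinene", "α-pinene"),
                        source = "gold")
  corpus <- chem_corpus(records, gold = gold)
  seqs <- make_crf_sequences(corpus)
  model <- crf_train(seqs, max_iter = 60)
  spans <- tag_corpus_crf(corpus, model)
  expect_true(attr(spans, "validated"))
  expect_true(all(spans$surface == "α-pinene"))
})
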