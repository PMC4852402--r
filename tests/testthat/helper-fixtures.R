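# Shared fixtures and independent oracles used across the suite.

tiny_corpus <- function() {
  chem_corpus(data.frame(
    doc_id = c("P1", "P2"),
    title = c("Aspirin works", "Study of DMSO effects"),
    abstract = c("Aspirin reduces pain and fever today",
                 "dmso was added to the ethyl acetate solution"),
    stringsAsFactors = FALSE
  ))
}

tiny_lexicon <- function(stoplist = character()) {
  entries <- compound_entries(
    c("C1", "C2", "C3", "C4"),
    paste0("InChI=1S/T", 1:4),
    list(c("Aspirin", "ASA"), c("DMSO"), c("ethyl", "ethyl acetate"),
         c("lead", "lead acetate")),
    source_db = "test"
  )
  build_lexicon(entries, stoplist = stoplist)
}

# brute-force reference matcher: enumerate every token window up to max_len,
# look it up, then resolve leftmost-longest greedily
oracle_match <- function(tokens, text, lexicon, max_len = 8L) {
  idx <- lexicon_index(lexicon)
  n <- nrow(tokens)
  hits <- list()
  for (i in seq_len(n)) {
    for (len in seq_len(min(max_len, n - i + 1L))) {
      cand <- paste(tokens$surface[i:(i + len - 1L)], collapse = " ")
      got <- lexicon_lookup(lexicon, cand, index = idx)
      if (length(got$ids)) {
        hits[[length(hits) + 1L]] <- list(i = i, len = len)
      }
    }
  }
  taken <- rep(FALSE, n)
  out <- data.frame(start = integer(), end = integer())
  i <- 1L
  while (i <= n) {
    mine <- Filter(function(h) h$i == i, hits)
    if (length(mine)) {
      len <- max(vapply(mine, function(h) h$len, 0L))
      out <- rbind(out, data.frame(start = tokens$start[i],
                                   end = tokens$end[i + len - 1L]))
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  out
}

# brute-force mention evaluation by nested scanning
oracle_mention_counts <- function(pred, gold) {
  key <- function(df) paste(df$doc_id, df$passage, df$start, df$end)
  pk <- unique(key(pred))
  gk <- unique(key(gold))
  tp <- 0L
  for (p in pk) if (p %in% gk) tp <- tp + 1L
  list(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
}

random_span_set <- function(n_docs = 3L, max_spans = 6L) {
  mk <- function(source) {
    rows <- list()
    for (d in seq_len(n_docs)) {
      k <- sample(0:max_spans, 1L)
      if (k == 0L) next
      starts <- sort(sample(0:40, k))
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = paste0("D", d),
        passage = sample(c("T", "A"), k, replace = TRUE),
        start = starts, end = starts + sample(1:5, k, replace = TRUE),
        surface = "x", source = source,
        confidence = 1, stringsAsFactors = FALSE
      )
    }
    if (length(rows)) do.call(rbind, rows) else empty_spans()
  }
  list(pred = mk("dict"), gold = mk("gold"))
}

synth_world <- function(seed, n_compounds = 40L, n_records = 60L,
                        mentions = 2, homograph = 0, unseen = 0,
                        stoplist = character()) {
  cfg <- simulation_config(
    n_compounds = n_compounds, n_records = n_records,
    mentions_per_passage = mentions,
    ambiguous_homograph_fraction = homograph,
    unseen_chemical_fraction = unseen, seed = seed
  )
  comp <- make_compounds(cfg)
  lex <- build_lexicon(merge_lexicons(list(comp$a, comp$b)),
                       stoplist = stoplist)
  corpus <- make_corpus(lex, cfg)
  list(cfg = cfg, compounds = comp, lexicon = lex, corpus = corpus)
}
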