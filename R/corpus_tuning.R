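#' Tuning configuration
#'
#' Thresholds for corpus-driven term exclusion and inclusion. A term already
#' in the dictionary is dropped when its ratio of true-positive to
#' false-positive detections on the tuning corpus falls below
#' `exclusion_threshold`; a missed term is added when re-indexing it yields
#' no false positives at all or a ratio above `inclusion_threshold`.
#'
#' @param exclusion_threshold Positive real; default 0.3.
#' @param inclusion_threshold Positive real; default 0.5.
#' @return A list of class `tuning_config`.
#' @export
tuning_config <- function(exclusion_threshold = 0.3, inclusion_threshold = 0.5) {
  stopifnot(exclusion_threshold > 0, inclusion_threshold > 0)
  structure(list(exclusion_threshold = exclusion_threshold,
                 inclusion_threshold = inclusion_threshold),
            class = "tuning_config")
}

# key under which a span aggregates in term statistics
stats_key_for <- function(spans) {
  if (!is.null(spans$term_key)) {
    ifelse(is.na(spans$term_key), term_key(spans$surface), spans$term_key)
  } else {
    term_key(spans$surface)
  }
}

#' Collect per-term true/false-positive statistics
#'
#' Each predicted span is a true positive when a gold span matches it
#' exactly on (document, passage, start, end), otherwise a false positive.
#' Counts aggregate by the span's lexicon lookup key (case-folded unless the
#' surface is an abbreviation), so all case variants of a term pool into one
#' row.
#'
#' @param predictions Predicted span data frame (a `term_key` column, as
#'   emitted by [tag_corpus_dict()], is used when present).
#' @param gold Gold span data frame.
#' @param corpus The corpus both refer to.
#' @return A data frame with columns `term`, `tp`, `fp` and `ratio`
#'   (`tp / fp`, `Inf` when `fp == 0`), ordered by term.
#' @export
collect_term_stats <- function(predictions, gold, corpus) {
  predictions <- validate_spans(predictions, corpus)
  gold <- validate_spans(gold, corpus)
  if (nrow(predictions) == 0L) {
    return(data.frame(term = character(), tp = integer(), fp = integer(),
                      ratio = numeric(), stringsAsFactors = FALSE))
  }
  predictions <- predictions[!duplicated(span_ids(predictions)), , drop = FALSE]
  is_tp <- span_ids(predictions) %in% span_ids(gold)
  key <- stats_key_for(predictions)
  tp <- tapply(is_tp, key, sum)
  fp <- tapply(!is_tp, key, sum)
  terms <- sort(names(tp))
  tp <- as.integer(tp[terms]); fp <- as.integer(fp[terms])
  data.frame(term = terms, tp = tp, fp = fp,
             ratio = ifelse(fp == 0L, Inf, tp / fp),
             stringsAsFactors = FALSE)
}

span_ids <- function(spans) {
  paste(spans$doc_id, spans$passage, spans$start, spans$end, sep = "\r")
}

#' Derive term exclusions from tuning statistics
#'
#' Returns the terms that produced at least one false positive and whose
#' true-positive/false-positive ratio is below the exclusion threshold
#' (default 0.3). The threshold guards overall well-behaved terms against
#' removal over an occasional stray detection.
#'
#' @param stats Output of [collect_term_stats()].
#' @param config A [tuning_config()].
#' @return Character vector of term keys to remove from the lexicon.
#' @export
derive_exclusions <- function(stats, config = tuning_config()) {
  stats$term[stats$fp > 0L & stats$ratio < config$exclusion_threshold]
}

# gold spans with no overlapping prediction in the same passage
missed_gold <- function(gold, predictions) {
  if (nrow(gold) == 0L) return(gold)
  if (nrow(predictions) == 0L) return(gold)
  overlapped <- vapply(seq_len(nrow(gold)), function(i) {
    p <- predictions[predictions$doc_id == gold$doc_id[i] &
                       predictions$passage == gold$passage[i], , drop = FALSE]
    any(p$start < gold$end[i] & p$end > gold$start[i])
  }, TRUE)
  gold[!overlapped, , drop = FALSE]
}

#' Derive term inclusions from missed gold mentions
#'
#' Candidate terms are the surfaces of gold mentions that no predicted span
#' overlaps at all. Each candidate is temporarily added to the lexicon, the
#' corpus is re-tagged, and the candidate is admitted only when that re-tag
#' produces no false positives, or a true/false-positive ratio above the
#' inclusion threshold (default 0.5).
#'
#' @param gold Gold span data frame.
#' @param predictions Current predicted spans on the same corpus.
#' @param corpus The tuning corpus.
#' @param lexicon The current `chem_lexicon`.
#' @param config A [tuning_config()].
#' @param max_len Match window passed to the re-tagging runs.
#' @return Character vector of admitted surface terms.
#' @export
derive_inclusions <- function(gold, predictions, corpus, lexicon,
                              config = tuning_config(), max_len = 8L) {
  gold <- validate_spans(gold, corpus)
  predictions <- validate_spans(predictions, corpus)
  cands <- unique(normalize_term(missed_gold(gold, predictions)$surface))
  keep <- character()
  for (surf in cands) {
    lex2 <- lexicon_add_terms(lexicon, surf)
    pred2 <- tag_corpus_dict(corpus, lex2, max_len = max_len)
    key <- term_key(surf)
    mine <- pred2[stats_key_for(pred2) == key, , drop = FALSE]
    if (nrow(mine) == 0L) next
    tp <- sum(span_ids(mine) %in% span_ids(gold))
    fp <- nrow(mine) - tp
    if (fp == 0L || tp / fp > config$inclusion_threshold) keep <- c(keep, surf)
  }
  keep
}

#' One round of corpus-driven lexicon tuning
#'
#' Convenience wrapper: tags the tuning corpus, derives exclusions and
#' (optionally) inclusions, and returns the revised lexicon together with
#' the supporting statistics.
#'
#' @param corpus Tuning corpus carrying gold annotations.
#' @param lexicon Starting `chem_lexicon`.
#' @param config A [tuning_config()].
#' @param include Whether to run term inclusion after exclusion.
#' @param max_len Match window.
#' @return A list with `lexicon` (revised), `excluded`, `included`, `stats`.
#' @export
tune_lexicon <- function(corpus, lexicon, config = tuning_config(),
                         include = TRUE, max_len = 8L) {
  if (is.null(corpus$gold)) stop("tuning requires a corpus with gold annotations")
  pred <- tag_corpus_dict(corpus, lexicon, max_len = max_len)
  stats <- collect_term_stats(pred, corpus$gold, corpus)
  excl <- derive_exclusions(stats, config)
  lex2 <- lexicon_remove_terms(lexicon, excl)
  incl <- character()
  if (include) {
    pred2 <- tag_corpus_dict(corpus, lex2, max_len = max_len)
    incl <- derive_inclusions(corpus$gold, pred2, corpus, lex2,
                              config = config, max_len = max_len)
    lex2 <- lexicon_add_terms(lex2, incl)
  }
  list(lexicon = lex2, excluded = excl, included = incl, stats = stats)
}
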