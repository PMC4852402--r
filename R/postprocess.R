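#' Post-processing configuration
#'
#' @param consistency_min_count A surface must be tagged at least this many
#'   times in a passage before its remaining occurrences are propagated
#'   (minimum, and default, 2).
#' @param identifier_patterns Named character vector of regular expressions
#'   tagged as chemical database identifiers. The default recognizes CAS
#'   registry numbers.
#' @param cas_checksum Additionally validate the CAS check digit (off by
#'   default; the identifier step is purely regex-driven otherwise).
#' @param steps Which steps [postprocess_spans()] runs, in order.
#' @return A list of class `postprocess_config`.
#' @export
postprocess_config <- function(consistency_min_count = 2L,
                               identifier_patterns = c(cas = "\\b[1-9][0-9]{1,6}-[0-9]{2}-[0-9]\\b"),
                               cas_checksum = FALSE,
                               steps = c("consistency", "abbreviations",
                                         "boundaries", "identifiers")) {
  stopifnot(consistency_min_count >= 2L)
  for (p in identifier_patterns) {
    ok <- tryCatch({
      stringi::stri_detect_regex("x", p)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop(sprintf("identifier pattern does not compile: %s", p))
  }
  structure(list(consistency_min_count = as.integer(consistency_min_count),
                 identifier_patterns = identifier_patterns,
                 cas_checksum = cas_checksum,
                 steps = steps),
            class = "postprocess_config")
}

# occurrences of `surface` in `text` that start at a token start and end at
# a token end; returns 0-based starts
aligned_occurrences <- function(surface, text, tokens) {
  loc <- stringi::stri_locate_all_fixed(text, surface)[[1]]
  if (all(is.na(loc[, 1L]))) return(integer())
  s0 <- loc[, 1L] - 1L
  e0 <- loc[, 2L]
  ok <- s0 %in% tokens$start & e0 %in% tokens$end
  s0[ok]
}

#' Enforce tagging consistency within a passage
#'
#' For each surface tagged at least `consistency_min_count` times in the
#' passage, every other case-sensitive, token-boundary-aligned occurrence
#' gains a span with confidence equal to the mean confidence of the
#' existing ones. Existing spans are unchanged; the operation is
#' idempotent.
#'
#' @param spans Spans of one passage (passage-local coordinates are read
#'   from the usual span columns).
#' @param text The passage text.
#' @param config A [postprocess_config()].
#' @return The augmented span data frame.
#' @export
enforce_consistency <- function(spans, text, config = postprocess_config()) {
  if (nrow(spans) < config$consistency_min_count) return(spans)
  tokens <- tokenize(text)
  counts <- table(spans$surface)
  for (surf in names(counts)[counts >= config$consistency_min_count]) {
    have <- spans$surface == surf
    occ <- aligned_occurrences(surf, text, tokens)
    new_s <- setdiff(occ, spans$start[have])
    new_s <- new_s[!vapply(new_s, function(s) {
      any(spans$start < s + nchar(surf) & spans$end > s)  # overlap guard
    }, TRUE)]
    if (length(new_s) == 0L) next
    add <- spans[rep(which(have)[1L], length(new_s)), , drop = FALSE]
    add$start <- as.integer(new_s)
    add$end <- as.integer(new_s + nchar(surf))
    add$confidence <- mean(spans$confidence[have])
    spans <- rbind(spans, add)
  }
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  rownames(spans) <- NULL
  spans
}

# Schwartz/Hearst-style short-form / long-form alignment.
# Returns the 0-based start of the long form, or NA if no alignment.
align_long_form <- function(short, text_before) {
  words <- tokenize(text_before)
  if (nrow(words) == 0L) return(NA_integer_)
  max_words <- min(nchar(short) + 5L, 2L * nchar(short))
  first <- max(1L, nrow(words) - max_words + 1L)
  lf_start <- words$start[first]
  lf <- substr(text_before, lf_start + 1L, nchar(text_before))
  s_chars <- stringi::stri_trans_tolower(
    strsplit(short, "", fixed = TRUE)[[1]])
  l_chars <- stringi::stri_trans_tolower(
    strsplit(lf, "", fixed = TRUE)[[1]])
  si <- length(s_chars); li <- length(l_chars)
  while (si > 0L) {
    ch <- s_chars[si]
    if (!stringi::stri_detect_regex(ch, "[a-z0-9]")) { si <- si - 1L; next }
    # the first short-form character must match at the start of a word
    repeat {
      if (li <= 0L) return(NA_integer_)
      hit <- l_chars[li] == ch &&
        (si > 1L || li == 1L || !stringi::stri_detect_regex(l_chars[li - 1L], "[a-z0-9]"))
      if (hit) break
      li <- li - 1L
    }
    si <- si - 1L; li <- li - 1L
  }
  # long form runs from the matched word to the end of text_before
  cand <- lf_start + li  # 0-based offset of first matched char
  w <- words$start[words$start <= cand]
  if (length(w) == 0L) return(NA_integer_)
  max(w)
}

find_abbrev_pairs <- function(text) {
  # candidate short forms: parenthesized, <= 10 chars, at least one letter,
  # no internal whitespace
  m <- stringi::stri_locate_all_regex(text, "\\(([^()\\s]{1,10})\\)")[[1]]
  if (all(is.na(m[, 1L]))) {
    return(data.frame(sf_start = integer(), sf_end = integer(),
                      lf_start = integer(), lf_end = integer(),
                      short = character(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (r in seq_len(nrow(m))) {
    sf_start <- m[r, 1L]       # 1-based "("
    sf_end <- m[r, 2L]         # 1-based ")"
    short <- substr(text, sf_start + 1L, sf_end - 1L)
    if (!stringi::stri_detect_regex(short, "[A-Za-z]")) next
    before <- substr(text, 1L, sf_start - 1L)
    before <- sub("\\s+$", "", before)
    lf_start <- align_long_form(short, before)
    if (is.na(lf_start)) next
    out[[length(out) + 1L]] <- data.frame(
      sf_start = sf_start, sf_end = sf_end - 1L,  # 0-based [start,end)
      lf_start = lf_start, lf_end = nchar(before),
      short = short, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(sf_start = integer(), sf_end = integer(),
                      lf_start = integer(), lf_end = integer(),
                      short = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Resolve abbreviation definitions within a passage
#'
#' Detects definitions of the form `long form (SF)` using short-form /
#' long-form letter alignment (the short form is at most 10 characters and
#' its letters must align right-to-left into the long form, the first one
#' at a word start). If either side of a definition is already tagged, both
#' sides and all later occurrences of the short form are tagged.
#'
#' @param spans Spans of one passage.
#' @param text The passage text.
#' @return The augmented span data frame.
#' @export
resolve_abbreviations <- function(spans, text) {
  pairs <- find_abbrev_pairs(text)
  if (nrow(pairs) == 0L) return(spans)
  tokens <- tokenize(text)
  for (r in seq_len(nrow(pairs))) {
    p <- pairs[r, ]
    lf_hit <- any(spans$start < p$lf_end & spans$end > p$lf_start)
    sf_hit <- any(spans$start == p$sf_start & spans$end == p$sf_end)
    if (!lf_hit && !sf_hit) next
    trigger <- spans$start < p$lf_end & spans$end > p$lf_start |
      (spans$start == p$sf_start & spans$end == p$sf_end)
    conf <- mean(spans$confidence[trigger])
    template <- spans[which(trigger)[1L], , drop = FALSE]
    add_span <- function(s, e) {
      if (any(spans$start == s & spans$end == e)) return(invisible())
      if (any(spans$start < e & spans$end > s)) return(invisible())
      row <- template
      row$start <- as.integer(s); row$end <- as.integer(e)
      row$surface <- substr(text, s + 1L, e)
      row$confidence <- conf
      spans <<- rbind(spans, row)
    }
    add_span(p$lf_start, p$lf_end)
    add_span(p$sf_start, p$sf_end)
    later <- aligned_occurrences(p$short, text, tokens)
    for (s in later[later > p$sf_start]) add_span(s, s + nchar(p$short))
  }
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  rownames(spans) <- NULL
  spans
}

bracket_imbalance <- function(s) {
  vapply(seq_along(OPENERS), function(k) {
    stringi::stri_count_fixed(s, OPENERS[k]) -
      stringi::stri_count_fixed(s, CLOSERS[k])
  }, 0L)
}

#' Revise unbalanced bracket boundaries of one span
#'
#' If bracket or parenthesis counts inside the span are unbalanced, first
#' try extending the span by one character on the side whose neighbouring
#' character restores balance; otherwise trim the unbalanced bracket at the
#' span edge. The result is balanced or, when neither repair applies, the
#' span is returned unchanged.
#'
#' @param start,end 0-based, end-exclusive span offsets.
#' @param text Passage text.
#' @return A list with the (possibly revised) `start` and `end`.
#' @export
revise_boundaries <- function(start, end, text) {
  surf <- substr(text, start + 1L, end)
  imb <- bracket_imbalance(surf)
  if (all(imb == 0L)) return(list(start = start, end = end))
  # try one-character extensions
  if (end < nchar(text)) {
    ext <- substr(text, start + 1L, end + 1L)
    if (all(bracket_imbalance(ext) == 0L)) {
      return(list(start = start, end = end + 1L))
    }
  }
  if (start > 0L) {
    ext <- substr(text, start, end)
    if (all(bracket_imbalance(ext) == 0L)) {
      return(list(start = start - 1L, end = end))
    }
  }
  # trim unbalanced brackets at the edges
  s <- start; e <- end
  repeat {
    surf <- substr(text, s + 1L, e)
    imb <- bracket_imbalance(surf)
    if (all(imb == 0L) || e - s <= 1L) break
    first <- substr(surf, 1L, 1L)
    last <- substr(surf, nchar(surf), nchar(surf))
    k_first_open <- match(first, OPENERS)
    k_first_close <- match(first, CLOSERS)
    k_last_close <- match(last, CLOSERS)
    k_last_open <- match(last, OPENERS)
    if (!is.na(k_last_close) && imb[k_last_close] < 0L) {
      e <- e - 1L
    } else if (!is.na(k_first_open) && imb[k_first_open] > 0L) {
      s <- s + 1L
    } else if (!is.na(k_first_close) && imb[k_first_close] < 0L) {
      s <- s + 1L
    } else if (!is.na(k_last_open) && imb[k_last_open] > 0L) {
      e <- e - 1L
    } else {
      break
    }
  }
  if (all(bracket_imbalance(substr(text, s + 1L, e)) == 0L)) {
    list(start = s, end = e)
  } else {
    list(start = start, end = end)  # unrepairable; leave as-is
  }
}

cas_checksum_ok <- function(cas) {
  digits <- as.integer(strsplit(gsub("-", "", cas), "")[[1]])
  n <- length(digits)
  check <- digits[n]
  body <- rev(digits[-n])
  sum(body * seq_along(body)) %% 10L == check
}

#' Tag chemical database identifiers by regular expression
#'
#' Each match of each configured pattern becomes a span (source `"crf"`,
#' confidence 1). The default pattern finds CAS registry numbers with word
#' boundaries, so trailing punctuation is excluded.
#'
#' @param text Passage text.
#' @param config A [postprocess_config()].
#' @return Data frame with `start`, `end`, `surface` (passage-local).
#' @export
tag_identifiers <- function(text, config = postprocess_config()) {
  out <- list()
  for (nm in names(config$identifier_patterns)) {
    loc <- stringi::stri_locate_all_regex(text, config$identifier_patterns[[nm]])[[1]]
    if (all(is.na(loc[, 1L]))) next
    s0 <- loc[, 1L] - 1L; e0 <- loc[, 2L]
    surf <- substring(text, loc[, 1L], loc[, 2L])
    if (nm == "cas" && isTRUE(config$cas_checksum)) {
      ok <- vapply(surf, cas_checksum_ok, TRUE)
      s0 <- s0[ok]; e0 <- e0[ok]; surf <- surf[ok]
    }
    if (length(s0)) {
      out[[length(out) + 1L]] <- data.frame(
        start = as.integer(s0), end = as.integer(e0), surface = surf,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- unique(res[order(res$start, res$end), , drop = FALSE])
  rownames(res) <- NULL
  res
}

#' Apply the full post-processing chain to predicted spans
#'
#' Runs, per passage and in order: tagging consistency, abbreviation
#' resolution, bracket boundary revision and identifier tagging (the steps
#' are selectable through the config). Spans never cross passage
#' boundaries, and every emitted span still satisfies the slice invariant.
#'
#' @param spans Predicted spans (typically CRF output).
#' @param corpus The corpus the spans refer to.
#' @param config A [postprocess_config()].
#' @return A validated span data frame.
#' @export
postprocess_spans <- function(spans, corpus, config = postprocess_config()) {
  spans <- validate_spans(spans, corpus)
  keys <- unique(rbind(
    spans[, c("doc_id", "passage")],
    expand.grid(doc_id = corpus$records$doc_id, passage = c("T", "A"),
                stringsAsFactors = FALSE)
  ))
  out <- list()
  for (i in seq_len(nrow(keys))) {
    d <- keys$doc_id[i]; p <- keys$passage[i]
    text <- passage_text(corpus, d, p)
    sp <- spans[spans$doc_id == d & spans$passage == p, , drop = FALSE]
    if (!nzchar(text)) next
    if ("consistency" %in% config$steps && nrow(sp)) {
      sp <- enforce_consistency(sp, text, config)
    }
    if ("abbreviations" %in% config$steps && nrow(sp)) {
      sp <- resolve_abbreviations(sp, text)
    }
    if ("boundaries" %in% config$steps && nrow(sp)) {
      for (r in seq_len(nrow(sp))) {
        rev <- revise_boundaries(sp$start[r], sp$end[r], text)
        sp$start[r] <- rev$start; sp$end[r] <- rev$end
      }
      sp$surface <- substr_many(text, sp$start, sp$end)
      sp <- sp[!duplicated(sp[, c("start", "end")]), , drop = FALSE]
    }
    if ("identifiers" %in% config$steps) {
      ids <- tag_identifiers(text, config)
      if (nrow(ids)) {
        new <- !vapply(seq_len(nrow(ids)), function(k) {
          any(sp$start == ids$start[k] & sp$end == ids$end[k])
        }, TRUE)
        if (any(new)) {
          add <- mention_spans(d, p, ids$start[new], ids$end[new],
                               ids$surface[new], source = "crf",
                               confidence = 1)
          common <- intersect(names(sp), names(add))
          sp <- if (nrow(sp)) rbind(sp[, common, drop = FALSE],
                                    add[, common, drop = FALSE]) else add
        }
      }
    }
    if (nrow(sp)) out[[length(out) + 1L]] <- sp
  }
  res <- if (length(out)) {
    cols <- Reduce(intersect, lapply(out, names))
    do.call(rbind, lapply(out, function(x) x[, cols, drop = FALSE]))
  } else {
    empty_spans()
  }
  res <- res[order(res$doc_id, res$passage, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  validate_spans(res, corpus)
}
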