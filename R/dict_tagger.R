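OPENERS <- c("(", "[", "{")
CLOSERS <- c(")", "]", "}")
CLOSE_OF <- c("(" = ")", "[" = "]", "{" = "}")
OPEN_OF <- c(")" = "(", "]" = "[", "}" = "{")
TRAIL_PUNCT <- c(".", ",", ";", ":", "!", "?", "\"", "'")
LEAD_PUNCT <- c("\"", "'", ",", ";", ":", ".")

#' Tokenize passage text
#'
#' Whitespace-delimited chunks are split further at their edges: leading
#' opening brackets and quotes, and trailing periods, commas, semicolons,
#' colons, quotes and *unbalanced* closing brackets become one-character
#' tokens of their own. Characters inside a word are never split, so
#' chemical names such as `1,2-dichloroethane` or `2-(chloroethyl)benzene`
#' stay single tokens; a trailing closing bracket is only detached when the
#' chunk holds no matching opener (`pure)` loses its `)`, `(chloroethyl)`
#' does not). Token offsets are 0-based, end-exclusive code point positions,
#' so concatenating token slices and inter-token gaps reconstructs the text.
#'
#' @param text A single passage string.
#' @return A data frame with columns `surface`, `start`, `end`; zero rows
#'   for empty text.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  empty <- data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  loc <- stringi::stri_locate_all_regex(text, "\\S+")[[1]]
  if (all(is.na(loc[, 1L]))) return(empty)
  out_s <- integer(); out_e <- integer()
  for (r in seq_len(nrow(loc))) {
    s <- loc[r, 1L]; e <- loc[r, 2L]  # 1-based inclusive
    # peel leading punctuation
    while (e > s) {
      ch <- substr(text, s, s)
      if (ch %in% LEAD_PUNCT) {
        out_s <- c(out_s, s); out_e <- c(out_e, s); s <- s + 1L
      } else if (ch %in% OPENERS) {
        out_s <- c(out_s, s); out_e <- c(out_e, s); s <- s + 1L
      } else break
    }
    # peel trailing punctuation into a pending stack
    pend <- integer()
    while (e > s) {
      ch <- substr(text, e, e)
      if (ch %in% TRAIL_PUNCT) {
        pend <- c(e, pend); e <- e - 1L
      } else if (ch %in% CLOSERS) {
        chunk <- substr(text, s, e)
        op <- OPEN_OF[[ch]]
        if (stringi::stri_count_fixed(chunk, ch) >
            stringi::stri_count_fixed(chunk, op)) {
          pend <- c(e, pend); e <- e - 1L
        } else break
      } else break
    }
    out_s <- c(out_s, s); out_e <- c(out_e, e)
    if (length(pend)) { out_s <- c(out_s, pend); out_e <- c(out_e, pend) }
  }
  data.frame(
    surface = substring(text, out_s, out_e),
    start = out_s - 1L, end = out_e,
    stringsAsFactors = FALSE
  )
}

#' Match lexicon terms in a tokenized passage
#'
#' Scans token windows (up to `max_len` tokens, joined by single spaces) and
#' looks each candidate up with partial case sensitivity: the verbatim
#' candidate against the abbreviation table first, then the case-folded
#' candidate against the general table. Matching is leftmost-longest and
#' greedy: at each position the longest matching window wins and scanning
#' resumes after its last token, so emitted spans never overlap.
#'
#' @param tokens Token data frame from [tokenize()].
#' @param text The passage text the tokens came from.
#' @param lexicon A `chem_lexicon`.
#' @param max_len Maximum window length in tokens (lexicon terms longer than
#'   this are unreachable).
#' @param index Optional prebuilt [lexicon_index()] for repeated calls.
#' @return A data frame of matches: `start`, `end`, `surface`, `term_key`,
#'   `confidence` (always 1).
#' @export
match_lexicon <- function(tokens, text, lexicon, max_len = 8L, index = NULL) {
  if (is.null(index)) index <- lexicon_index(lexicon)
  n <- nrow(tokens)
  res_s <- integer(); res_e <- integer(); res_k <- character()
  i <- 1L
  while (i <= n) {
    hit_len <- 0L; hit_key <- NA_character_
    for (len in seq.int(min(max_len, n - i + 1L), 1L)) {
      cand <- paste(tokens$surface[i:(i + len - 1L)], collapse = " ")
      got <- get0(cand, envir = index$exact, ifnotfound = NULL)
      key <- cand
      if (is.null(got)) {
        key <- casefold_term(cand)
        got <- get0(key, envir = index$folded, ifnotfound = NULL)
      }
      if (!is.null(got)) { hit_len <- len; hit_key <- key; break }
    }
    if (hit_len > 0L) {
      res_s <- c(res_s, tokens$start[i])
      res_e <- c(res_e, tokens$end[i + hit_len - 1L])
      res_k <- c(res_k, hit_key)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  data.frame(
    start = res_s, end = res_e,
    surface = substr_many(text, res_s, res_e),
    term_key = res_k, confidence = rep(1, length(res_s)),
    stringsAsFactors = FALSE
  )
}

substr_many <- function(text, start0, end0) {
  if (length(start0) == 0L) return(character())
  substring(text, start0 + 1L, end0)
}

#' Tag every passage of a corpus with the dictionary
#'
#' Applies [tokenize()] and [match_lexicon()] to every title and abstract.
#' Deterministic: identical inputs give identical output.
#'
#' @param corpus A `chem_corpus`.
#' @param lexicon A `chem_lexicon`.
#' @param max_len Maximum match window in tokens.
#' @return A validated span data frame with `source = "dict"`, confidence 1,
#'   and a `term_key` column recording each span's lexicon lookup key.
#' @export
tag_corpus_dict <- function(corpus, lexicon, max_len = 8L) {
  index <- lexicon_index(lexicon)
  recs <- corpus$records
  out <- vector("list", 2L * nrow(recs))
  k <- 0L
  for (i in seq_len(nrow(recs))) {
    for (p in c("T", "A")) {
      text <- if (p == "T") recs$title[i] else recs$abstract[i]
      if (!nzchar(text)) next
      m <- match_lexicon(tokenize(text), text, lexicon,
                         max_len = max_len, index = index)
      if (nrow(m) == 0L) next
      k <- k + 1L
      sp <- mention_spans(recs$doc_id[i], p, m$start, m$end, m$surface,
                          source = "dict", confidence = m$confidence)
      sp$term_key <- m$term_key
      out[[k]] <- sp
    }
  }
  if (k == 0L) {
    spans <- empty_spans()
    spans$term_key <- character()
  } else {
    spans <- do.call(rbind, out[seq_len(k)])
  }
  validate_spans(spans, corpus)
}
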