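#' Decide whether a term is an abbreviation
#'
#' A term counts as an abbreviation when the majority of its characters are
#' capitals or digits. "Majority" is strict: the number of characters in
#' `[A-Z0-9]` must exceed half of the non-whitespace character count.
#' Abbreviations are matched case-sensitively by the dictionary tagger; all
#' other terms case-insensitively.
#'
#' @param term Character vector of terms (each non-empty).
#' @return Logical vector.
#' @examples
#' is_abbreviation(c("DNA", "water", "Ab1"))
#' @export
is_abbreviation <- function(term) {
  term <- as.character(term)
  if (any(is.na(term)) || any(!nzchar(term))) stop("terms must be non-empty")
  caps <- stringi::stri_count_regex(term, "[A-Z0-9]")
  nonws <- stringi::stri_count_regex(term, "\\S")
  caps > nonws / 2
}

casefold_term <- function(x) stringi::stri_trans_tolower(x)

normalize_term <- function(x) {
  stringi::stri_replace_all_regex(stringi::stri_trim_both(x), "\\s+", " ")
}

# lookup key used for term statistics and exclusion: abbreviations keep their
# case, everything else is case-folded
term_key <- function(term) {
  ifelse(is_abbreviation(term), term, casefold_term(term))
}

#' Construct compound entries
#'
#' One entry per compound: an opaque compound id, an InChI string (compared
#' literally; this package never parses structures), a set of surface terms
#' and a source label.
#'
#' @param compound_id Character vector of ids.
#' @param inchi Character vector of InChI strings.
#' @param terms List of character vectors (one set of terms per compound), or
#'   a character vector of `|`-separated terms.
#' @param source_db Source dictionary label.
#' @return A data frame of class `compound_entries` with a list column
#'   `terms`.
#' @export
compound_entries <- function(compound_id, inchi, terms, source_db = "local") {
  if (is.character(terms)) terms <- stringi::stri_split_fixed(terms, "|")
  terms <- lapply(terms, function(t) {
    t <- normalize_term(as.character(t))
    unique(t[nzchar(t)])
  })
  df <- data.frame(compound_id = as.character(compound_id),
                   inchi = as.character(inchi),
                   source_db = rep_len(as.character(source_db),
                                       length(compound_id)),
                   stringsAsFactors = FALSE)
  df$terms <- unname(terms)
  class(df) <- c("compound_entries", "data.frame")
  df
}

#' Read compound entries from a lexicon source file
#'
#' Format: `compound_id TAB inchi TAB term1|term2|...` (UTF-8).
#'
#' @param path Path to the file.
#' @param source_db Label recorded as the provenance of all entries.
#' @return A `compound_entries` data frame.
#' @export
read_lexicon_entries <- function(path, source_db = basename(path)) {
  lines <- read_utf8_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(compound_entries(character(), character(), list()))
  }
  parts <- split_fields(lines, 3L, path, "lexicon")
  m <- do.call(rbind, parts)
  compound_entries(m[, 1L], m[, 2L], m[, 3L], source_db = source_db)
}

#' Write compound entries to a lexicon source file
#' @param entries A `compound_entries` data frame.
#' @param path Output path.
#' @export
write_lexicon_entries <- function(entries, path) {
  lines <- paste(entries$compound_id, entries$inchi,
                 vapply(entries$terms, paste, "", collapse = "|"),
                 sep = "\t")
  write_utf8_lines(lines, path)
}

#' Merge compound dictionaries by structure identity
#'
#' Entries whose InChI strings are byte-identical describe the same compound
#' and are collapsed into a single entry: terms and source labels are
#' unioned, and the surviving compound id is the lexicographically smallest
#' member id. Entries without an InChI cannot be identified across sources
#' and are skipped with a warning. The operation is idempotent and
#' order-independent.
#'
#' @param sources A list of `compound_entries` data frames (or a single one).
#' @return A merged `compound_entries` data frame, one entry per distinct
#'   InChI, ordered by compound id.
#' @export
merge_lexicons <- function(sources) {
  if (is.data.frame(sources)) sources <- list(sources)
  all <- do.call(rbind, lapply(sources, function(s) {
    class(s) <- "data.frame"
    s
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(compound_entries(character(), character(), list()))
  }
  no_inchi <- is.na(all$inchi) | !nzchar(all$inchi)
  if (any(no_inchi)) {
    warning(sprintf("skipping %d entr%s without an InChI (no structure to merge on)",
                    sum(no_inchi), if (sum(no_inchi) == 1L) "y" else "ies"))
    all <- all[!no_inchi, , drop = FALSE]
  }
  if (nrow(all) == 0L) return(compound_entries(character(), character(), list()))
  groups <- split(seq_len(nrow(all)), all$inchi)
  ids <- vapply(groups, function(ix) min(all$compound_id[ix]), "")
  o <- order(ids)
  groups <- groups[o]
  out <- compound_entries(
    compound_id = unname(ids[o]),
    inchi = names(groups),
    terms = lapply(groups, function(ix) {
      sort(unique(unlist(all$terms[ix], use.names = FALSE)))
    }),
    source_db = unname(vapply(groups, function(ix) {
      paste(sort(unique(all$source_db[ix])), collapse = "+")
    }, ""))
  )
  rownames(out) <- NULL
  out
}

#' Read a stoplist
#'
#' One term per line; `#` starts a comment; blank lines ignored. Stoplist
#' terms are matched case-insensitively against whole lexicon terms.
#'
#' @param path Path to the stoplist file.
#' @return Character vector of stoplist terms.
#' @export
read_stoplist <- function(path) {
  lines <- read_utf8_lines(path)
  lines <- stringi::stri_trim_both(stringi::stri_replace_first_regex(lines, "#.*$", ""))
  lines[nzchar(lines)]
}

#' Default stoplist
#'
#' Common English words and ambiguous everyday terms that appear verbatim in
#' chemical lexicons (for example `lead` or `crystal`) and overwhelm
#' precision if left in. Whole-term removal only: `lead acetate` is never
#' touched by the stoplist entry `lead`. User-replaceable.
#'
#' @return Character vector of terms.
#' @export
default_stoplist <- function() {
  c("about", "all", "make", "acid", "crystal", "lead",
    "a", "an", "the", "and", "or", "of", "in", "on", "at", "by", "to",
    "for", "with", "from", "as", "is", "are", "was", "were", "be", "been",
    "this", "that", "it", "its", "same", "base", "gold", "iron", "salt",
    "oil", "gas", "water-free", "compound", "mixture", "agent", "solution")
}

#' Build a matchable lexicon from compound entries
#'
#' Each term is routed by [is_abbreviation()]: abbreviations go into a
#' case-sensitive (exact) table, all other terms into a case-folded table.
#' Stoplist terms are removed (case-insensitive whole-term match). Ambiguous
#' terms keep the full set of compound ids they are linked to. Internal
#' whitespace of multi-word terms is normalized to single spaces so that
#' matching is insensitive to spacing.
#'
#' @param entries A `compound_entries` data frame.
#' @param stoplist Character vector of stop terms (e.g. [default_stoplist()]
#'   or [read_stoplist()]); may be empty.
#' @return An object of class `chem_lexicon`.
#' @export
build_lexicon <- function(entries, stoplist = default_stoplist()) {
  if (nrow(entries) > 0L) {
    n_terms <- lengths(entries$terms)
    term <- unlist(entries$terms, use.names = FALSE)
    cid <- rep(entries$compound_id, n_terms)
    src <- rep(entries$source_db, n_terms)
  } else {
    term <- character(); cid <- character(); src <- character()
  }
  keep <- !(casefold_term(term) %in% casefold_term(stoplist))
  term <- term[keep]; cid <- cid[keep]; src <- src[keep]
  abb <- if (length(term)) is_abbreviation(term) else logical()
  key <- ifelse(abb, term, casefold_term(term))
  pairs <- data.frame(key = key, term = term, compound_id = cid,
                      source_db = src, abbrev = abb,
                      stringsAsFactors = FALSE)
  pairs <- unique(pairs[order(pairs$key, pairs$compound_id), , drop = FALSE])
  rownames(pairs) <- NULL
  agg <- function(p) {
    if (nrow(p) == 0L) {
      return(data.frame(key = character(), stringsAsFactors = FALSE,
                        ids = I(list())))
    }
    g <- split(p$compound_id, p$key)
    data.frame(key = names(g), ids = I(lapply(g, unique)),
               stringsAsFactors = FALSE)
  }
  lex <- structure(list(
    exact = agg(pairs[pairs$abbrev, , drop = FALSE]),
    folded = agg(pairs[!pairs$abbrev, , drop = FALSE]),
    compounds = entries[, c("compound_id", "inchi", "source_db")],
    provenance = unique(pairs[, c("term", "source_db")]),
    stoplist = stoplist
  ), class = "chem_lexicon")
  lex
}

#' @export
print.chem_lexicon <- function(x, ...) {
  cat(sprintf("<chem_lexicon> %d case-folded terms, %d abbreviations, %d compounds\n",
              nrow(x$folded), nrow(x$exact), nrow(x$compounds)))
  invisible(x)
}

#' All terms stored in a lexicon
#' @param lexicon A `chem_lexicon`.
#' @return Character vector of stored lookup keys (abbreviations verbatim,
#'   other terms case-folded).
#' @export
lexicon_terms <- function(lexicon) {
  sort(c(lexicon$exact$key, lexicon$folded$key))
}

# hashed environments for fast repeated lookup during matching
lexicon_index <- function(lexicon) {
  mkenv <- function(df) {
    e <- new.env(parent = emptyenv(), hash = TRUE,
                 size = max(29L, nrow(df) * 2L))
    if (nrow(df)) {
      for (i in seq_len(nrow(df))) assign(df$key[i], df$ids[[i]], envir = e)
    }
    e
  }
  list(exact = mkenv(lexicon$exact), folded = mkenv(lexicon$folded))
}

#' Look up a candidate term
#'
#' Tries the case-sensitive abbreviation table with the verbatim candidate
#' first, then the case-folded table with the case-folded candidate.
#'
#' @param lexicon A `chem_lexicon`.
#' @param term Candidate surface string.
#' @param index Optional prebuilt index from repeated-use callers.
#' @return A list with `ids` (character vector of compound ids, empty if no
#'   hit) and `key` (the lookup key that matched, or `NA`).
#' @export
lexicon_lookup <- function(lexicon, term, index = NULL) {
  if (is.null(index)) index <- lexicon_index(lexicon)
  hit <- get0(term, envir = index$exact, ifnotfound = NULL)
  if (!is.null(hit)) return(list(ids = hit, key = term))
  k <- casefold_term(term)
  hit <- get0(k, envir = index$folded, ifnotfound = NULL)
  if (!is.null(hit)) return(list(ids = hit, key = k))
  list(ids = character(), key = NA_character_)
}

#' Add terms to a lexicon
#'
#' Used by term inclusion: each term is routed through [is_abbreviation()]
#' like any dictionary term. Terms already covered by the stoplist recorded
#' in the lexicon are still added (inclusion outranks the static stoplist by
#' construction: the corpus evidence has already been examined).
#'
#' @param lexicon A `chem_lexicon`.
#' @param terms Character vector of surface terms.
#' @param compound_id Id to associate with the added terms.
#' @return The extended `chem_lexicon`.
#' @export
lexicon_add_terms <- function(lexicon, terms, compound_id = "INCLUDED") {
  terms <- normalize_term(terms)
  terms <- unique(terms[nzchar(terms)])
  if (length(terms) == 0L) return(lexicon)
  abb <- is_abbreviation(terms)
  add <- function(df, keys) {
    for (k in keys) {
      i <- match(k, df$key)
      if (is.na(i)) {
        df <- rbind(df, data.frame(key = k, ids = I(list(compound_id)),
                                   stringsAsFactors = FALSE))
      } else {
        df$ids[[i]] <- unique(c(df$ids[[i]], compound_id))
      }
    }
    df[order(df$key), , drop = FALSE]
  }
  lexicon$exact <- add(lexicon$exact, terms[abb])
  lexicon$folded <- add(lexicon$folded, casefold_term(terms[!abb]))
  lexicon
}

#' Remove terms from a lexicon
#'
#' Used by term exclusion. Removal is by lookup key: a non-abbreviation key
#' removes every case variant at once (the folded table stores only folded
#' keys), an abbreviation key removes the exact entry.
#'
#' @param lexicon A `chem_lexicon`.
#' @param terms Character vector of terms or lookup keys.
#' @return The reduced `chem_lexicon`.
#' @export
lexicon_remove_terms <- function(lexicon, terms) {
  if (length(terms) == 0L) return(lexicon)
  keys <- unique(c(terms, term_key(terms), casefold_term(terms)))
  lexicon$exact <- lexicon$exact[!(lexicon$exact$key %in% keys), , drop = FALSE]
  lexicon$folded <- lexicon$folded[!(lexicon$folded$key %in% keys), , drop = FALSE]
  rownames(lexicon$exact) <- rownames(lexicon$folded) <- NULL
  lexicon
}
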