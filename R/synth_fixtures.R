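# Deterministic synthetic patent corpora with implanted chemical mentions.
# The generator emulates the statistical structure the recognizers face:
# pseudo-systematic names built from a chemical morpheme grammar (so
# morphology carries signal the statistical tagger can generalize from),
# ambiguous homographs that are chemicals in some contexts and ordinary
# words in others (to exercise exclusion ratios), and chemical-looking
# terms deliberately left out of the lexicon (dictionary false negatives).

SYN_PREFIXES <- c("meth", "eth", "prop", "but", "pent", "hex", "di", "tri",
                  "tetra", "chloro", "fluoro", "bromo", "iodo", "hydroxy",
                  "amino", "nitro", "cyclo", "iso", "neo", "sulfo")
SYN_CORES <- c("benz", "phen", "naphth", "tolu", "pyrid", "imidazol",
               "furan", "thiophen", "anilin", "indol", "purin", "oxazol",
               "quinol", "pyrrol", "azol")
SYN_SUFFIXES <- c("ol", "ane", "ene", "one", "ine", "ate", "ide", "yne",
                  "amide", "oxide")

common_words <- function() {
  c("the", "a", "an", "of", "in", "on", "and", "or", "with", "for", "to",
    "was", "were", "is", "are", "be", "been", "this", "that", "method",
    "process", "invention", "provides", "composition", "comprising",
    "useful", "treatment", "disease", "patient", "disclosed", "herein",
    "present", "preparation", "mixture", "reaction", "product", "yield",
    "obtained", "using", "under", "conditions", "temperature", "pressure",
    "solvent", "step", "further", "wherein", "said", "such", "high",
    "low", "novel", "improved", "effective", "suitable", "formula",
    "derivative", "agent", "carrier", "dose", "therapy", "activity",
    "lead", "gold", "iron", "crystal", "acid", "salt", "base", "oil")
}

# words that may double as chemical synonyms (the ambiguous homographs)
homograph_pool <- function() {
  c("lead", "gold", "iron", "crystal", "acid", "salt", "base", "oil")
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic corpus generator. All fractions are in
#' `[0, 1]`; the seed is mandatory so every fixture is reproducible.
#'
#' @param n_compounds Number of compounds per generated collection.
#' @param synonyms_per_compound Extra synonyms per compound.
#' @param abbreviation_fraction Fraction of compounds that also get an
#'   uppercase abbreviation synonym (matched case-sensitively downstream).
#' @param n_records Number of patent records.
#' @param mentions_per_passage Poisson mean of implanted mentions per
#'   passage (titles and abstracts separately).
#' @param ambiguous_homograph_fraction Probability that a mention uses a
#'   term that is also an ordinary English word; the same words are also
#'   sprinkled into the text as ordinary words (not gold).
#' @param unseen_chemical_fraction Probability that a mention uses a
#'   chemical-looking term absent from the lexicon, creating dictionary
#'   false negatives that only the statistical tagger can recover.
#' @param seed Integer seed (required).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_compounds = 60L, synonyms_per_compound = 2L,
                              abbreviation_fraction = 0.2, n_records = 100L,
                              mentions_per_passage = 2,
                              ambiguous_homograph_fraction = 0,
                              unseen_chemical_fraction = 0,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  fr <- c(abbreviation_fraction, ambiguous_homograph_fraction,
          unseen_chemical_fraction)
  stopifnot(all(fr >= 0 & fr <= 1), n_compounds >= 1L, n_records >= 1L,
            mentions_per_passage >= 0)
  structure(list(
    n_compounds = as.integer(n_compounds),
    synonyms_per_compound = as.integer(synonyms_per_compound),
    abbreviation_fraction = abbreviation_fraction,
    n_records = as.integer(n_records),
    mentions_per_passage = mentions_per_passage,
    ambiguous_homograph_fraction = ambiguous_homograph_fraction,
    unseen_chemical_fraction = unseen_chemical_fraction,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# draw n distinct pseudo-systematic names, avoiding `avoid` (case-folded)
make_names <- function(n, avoid = character()) {
  avoid <- casefold_term(avoid)
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200L * n) stop("name grammar exhausted; lower n_compounds")
    k <- sample(1:2, 1L)
    nm <- paste0(paste(sample(SYN_PREFIXES, k), collapse = ""),
                 sample(SYN_CORES, 1L), sample(SYN_SUFFIXES, 1L))
    if (!(nm %in% out) && !(nm %in% avoid)) out <- c(out, nm)
  }
  out
}

make_abbrev <- function(i) {
  sprintf("%s%d", paste(sample(LETTERS, sample(2:3, 1L)), collapse = ""), i)
}

#' Generate two overlapping compound collections
#'
#' Builds pseudo-systematic names from a chemical morpheme grammar
#' (prefix + ring + suffix), adds synonyms, optional uppercase
#' abbreviations and, at the configured rate, ambiguous homograph synonyms.
#' A fraction of compounds appears in both collections with byte-identical
#' synthetic InChI strings, so [merge_lexicons()] collapses exactly those.
#'
#' @param config A [simulation_config()].
#' @param overlap_fraction Fraction of compounds shared between the two
#'   collections.
#' @return A list with `a` and `b` (`compound_entries`), plus
#'   `n_distinct_inchi`, the bookkept number of distinct structures.
#' @export
make_compounds <- function(config, overlap_fraction = 0.5) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  with_seed(config$seed * 2L + 11L, {
    n <- config$n_compounds
    n_shared <- round(n * overlap_fraction)
    n_total <- 2L * n - n_shared
    names_all <- make_names(n_total * (1L + config$synonyms_per_compound))
    terms <- split(names_all, rep(seq_len(n_total),
                                  each = 1L + config$synonyms_per_compound))
    hg <- homograph_pool()
    for (i in seq_len(n_total)) {
      if (stats::runif(1) < config$abbreviation_fraction) {
        terms[[i]] <- c(terms[[i]], make_abbrev(i))
      }
      if (stats::runif(1) < config$ambiguous_homograph_fraction &&
          length(hg)) {
        terms[[i]] <- c(terms[[i]], hg[1L])
        hg <- hg[-1L]
      }
    }
    inchi <- sprintf("InChI=1S/SYN%05d/c%d-%d", seq_len(n_total),
                     seq_len(n_total), seq_len(n_total) + 1L)
    shared <- seq_len(n_shared)
    a_ix <- seq_len(n)
    b_extra <- if (n_total > n) seq.int(n + 1L, n_total) else integer()
    b_ix <- c(shared, b_extra)
    a <- compound_entries(sprintf("A%04d", a_ix), inchi[a_ix],
                          terms[a_ix], source_db = "synthA")
    b <- compound_entries(sprintf("B%04d", b_ix), inchi[b_ix],
                          terms[b_ix], source_db = "synthB")
    list(a = a, b = b, n_distinct_inchi = n_total)
  })
}

# assemble one sentence; returns list(words, is_mention, kind)
build_sentence <- function(n_filler, mentions, kinds, noise_words) {
  filler <- sample(common_words(), n_filler, replace = TRUE)
  words <- c(filler, noise_words)
  flags <- rep("filler", length(words))
  if (length(noise_words)) {
    flags[seq.int(length(filler) + 1L, length(words))] <- "noise"
  }
  o <- sample(length(words))
  words <- words[o]; flags <- flags[o]
  if (length(mentions)) {
    pos <- sort(sample(length(words) + 1L, length(mentions),
                       replace = TRUE))
    for (k in seq_along(mentions)) {
      at <- pos[k] + k - 1L
      words <- append(words, mentions[k], after = at - 1L)
      flags <- append(flags, paste0("mention:", kinds[k]), after = at - 1L)
    }
  }
  list(words = words, flags = flags)
}

#' Generate a synthetic patent corpus with gold annotations
#'
#' Writes templated patent-like titles and abstracts with mentions
#' implanted at recorded offsets. Mentions are drawn from the lexicon
#' (dictionary-recallable), from homograph terms (also injected as
#' ordinary, non-gold words) and from unseen chemical-looking terms, at the
#' configured rates. Mention surfaces are whitespace-delimited and never
#' cross sentence boundaries, so gold offsets are immune to tokenizer
#' details; no text field contains a TAB. Deterministic per seed.
#'
#' @param lexicon A non-empty `chem_lexicon` whose terms are implanted.
#' @param config A [simulation_config()].
#' @return A `chem_corpus` with gold spans (their `class` column records
#'   each mention's kind: `seen`, `homograph` or `unseen`) and an
#'   `implants` attribute summarizing the generated composition.
#' @export
make_corpus <- function(lexicon, config) {
  keys <- lexicon_terms(lexicon)
  if (length(keys) == 0L) stop("lexicon is empty")
  hg <- intersect(lexicon$folded$key, homograph_pool())
  regular <- setdiff(keys, hg)
  with_seed(config$seed, {
    n_unseen_pool <- max(20L, config$n_compounds)
    unseen_pool <- make_names(n_unseen_pool, avoid = c(keys, common_words()))
    doc_ids <- sprintf("SYNPAT%05d", seq_len(config$n_records))
    titles <- character(config$n_records)
    abstracts <- character(config$n_records)
    gold <- vector("list", 2L * config$n_records)
    gi <- 0L
    draw_mentions <- function(n) {
      if (n == 0L) return(list(surf = character(), kind = character()))
      kind <- character(n); surf <- character(n)
      for (k in seq_len(n)) {
        u <- stats::runif(1)
        if (u < config$unseen_chemical_fraction) {
          kind[k] <- "unseen"; surf[k] <- sample(unseen_pool, 1L)
        } else if (length(hg) &&
                   stats::runif(1) < config$ambiguous_homograph_fraction) {
          kind[k] <- "homograph"; surf[k] <- sample(hg, 1L)
        } else {
          kind[k] <- "seen"; surf[k] <- sample(regular, 1L)
        }
      }
      list(surf = surf, kind = kind)
    }
    build_passage <- function(n_sentences, n_mentions) {
      m <- draw_mentions(n_mentions)
      sent_of <- if (n_mentions) sample(n_sentences, n_mentions,
                                        replace = TRUE) else integer()
      text <- ""
      starts <- integer(); ends <- integer()
      surfs <- character(); kinds <- character()
      for (s in seq_len(n_sentences)) {
        mine <- which(sent_of == s)
        noise <- character()
        if (length(hg) && stats::runif(1) < 0.4) {
          noise <- sample(hg, 1L)
        }
        sen <- build_sentence(sample(4:9, 1L), m$surf[mine], m$kind[mine],
                              noise)
        offset <- nchar(text)
        pos <- offset
        for (w in seq_along(sen$words)) {
          word <- sen$words[w]
          if (startsWith(sen$flags[w], "mention:")) {
            starts <- c(starts, pos)
            ends <- c(ends, pos + nchar(word))
            surfs <- c(surfs, word)
            kinds <- c(kinds, sub("^mention:", "", sen$flags[w]))
          }
          text <- paste0(text, word,
                         if (w < length(sen$words)) " " else "")
          pos <- pos + nchar(word) + 1L
        }
        text <- paste0(text, if (s < n_sentences) ". " else ".")
      }
      list(text = text, starts = starts, ends = ends, surfs = surfs,
           kinds = kinds)
    }
    for (i in seq_len(config$n_records)) {
      for (p in c("T", "A")) {
        n_sent <- if (p == "T") 1L else sample(2:4, 1L)
        n_m <- stats::rpois(1L, config$mentions_per_passage)
        pb <- build_passage(n_sent, n_m)
        if (p == "T") titles[i] <- pb$text else abstracts[i] <- pb$text
        if (length(pb$starts)) {
          gi <- gi + 1L
          g <- mention_spans(doc_ids[i], p, pb$starts, pb$ends, pb$surfs,
                             source = "gold", confidence = 1)
          g$class <- pb$kinds
          gold[[gi]] <- g
        }
      }
    }
    gold <- if (gi) do.call(rbind, gold[seq_len(gi)]) else {
      g <- empty_spans(); g$class <- character(); g
    }
    # drop exact duplicates (same surface implanted twice at one offset is
    # impossible by construction, but two homographs may coincide with a
    # noise word boundary; keep gold well-formed regardless)
    gold <- gold[!duplicated(gold[, c("doc_id", "passage", "start", "end")]), ,
                 drop = FALSE]
    corpus <- chem_corpus(
      data.frame(doc_id = doc_ids, title = titles, abstract = abstracts,
                 stringsAsFactors = FALSE),
      gold = gold
    )
    attr(corpus, "implants") <- table(factor(
      corpus$gold$class, levels = c("seen", "homograph", "unseen")))
    corpus
  })
}

#' Split a corpus into two halves
#'
#' Record-level split (odd/even positions) used for train/test experiments
#' on synthetic corpora.
#'
#' @param corpus A `chem_corpus` with gold annotations.
#' @return A list with `train` and `test` corpora.
#' @export
split_corpus <- function(corpus) {
  ix <- seq_len(nrow(corpus$records))
  pick <- function(sel) {
    recs <- corpus$records[sel, , drop = FALSE]
    g <- corpus$gold[corpus$gold$doc_id %in% recs$doc_id, , drop = FALSE]
    chem_corpus(recs, gold = g)
  }
  list(train = pick(ix %% 2L == 1L), test = pick(ix %% 2L == 0L))
}
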