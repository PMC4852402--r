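# --- small built-in linguistic helpers -------------------------------------
# The POS tagger and lemmatizer are deliberately rule-based (suffix
# heuristics plus closed-class word lists): they need no model files, are
# deterministic, and provide exactly the kind of coarse contextual signal
# the sequence tagger consumes. Both are pluggable via arguments to
# token_features().

#' Element symbols and names
#'
#' Gazetteer of the chemical elements: symbols (matched case-sensitively
#' against the token surface) and full English names (matched after case
#' folding).
#'
#' @return A list with character vectors `symbols` and `names`.
#' @export
chem_elements <- function() {
  list(
    symbols = c(
      "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg",
      "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr",
      "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br",
      "Kr", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd",
      "Ag", "Cd", "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La",
      "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm",
      "Yb", "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
      "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th", "Pa",
      "U"
    ),
    names = c(
      "hydrogen", "helium", "lithium", "beryllium", "boron", "carbon",
      "nitrogen", "oxygen", "fluorine", "neon", "sodium", "magnesium",
      "aluminium", "aluminum", "silicon", "phosphorus", "sulfur",
      "sulphur", "chlorine", "argon", "potassium", "calcium", "titanium",
      "vanadium", "chromium", "manganese", "iron", "cobalt", "nickel",
      "copper", "zinc", "gallium", "germanium", "arsenic", "selenium",
      "bromine", "krypton", "silver", "cadmium", "tin", "antimony",
      "tellurium", "iodine", "xenon", "barium", "tungsten", "platinum",
      "gold", "mercury", "lead", "bismuth", "radium", "thorium", "uranium"
    )
  )
}

#' Default chemical morpheme list
#'
#' Substrings characteristic of chemical nomenclature: trivial ring names,
#' halogen and substituent prefixes, and the classic functional-group
#' suffixes. A token containing any of them raises the ring-morpheme
#' feature.
#'
#' @return Character vector of lowercase morphemes.
#' @export
default_ring_morphemes <- function() {
  c("benz", "phen", "naphth", "tolu", "pyrid", "pyrimid", "imidazol",
    "furan", "thiophen", "anilin", "indol", "purin", "oxazol", "quinol",
    "meth", "ethyl", "propyl", "butyl", "acet", "oxy", "hydroxy", "amin",
    "nitro", "chloro", "fluoro", "bromo", "iodo", "cyclo", "sulf",
    "carb", "ol", "ane", "ene", "yne", "one", "ine", "ate", "ide", "yl")
}

# light suffix-stripping stemmer; longest rule first, stem kept >= 3 chars
STEM_RULES <- c(
  "ational" = "ate", "ization" = "ize", "fulness" = "ful",
  "ations" = "ate", "ation" = "ate", "ities" = "ity", "iveness" = "ive",
  "ments" = "ment", "ingly" = "", "edly" = "", "ying" = "y",
  "ies" = "y", "ing" = "", "ed" = "", "ly" = "", "es" = "", "s" = ""
)

#' Stem a token by suffix stripping
#'
#' A small deterministic suffix stripper (longest matching rule wins, the
#' stem is never shortened below three characters). It is not a full Porter
#' stemmer; its job is only to pool inflectional variants into one feature
#' value.
#'
#' @param words Character vector (any case; stemming operates on the
#'   lowercased form).
#' @return Character vector of stems.
#' @export
stem_words <- function(words) {
  w <- stringi::stri_trans_tolower(words)
  out <- w
  for (suf in names(STEM_RULES)) {
    cand <- endsWith(out, suf) & out == w  # only words not already stemmed
    if (!any(cand)) next
    base <- substr(out[cand], 1L, nchar(out[cand]) - nchar(suf))
    repl <- paste0(base, STEM_RULES[[suf]])
    ok <- nchar(repl) >= 3L
    out[cand][ok] <- repl[ok]
  }
  out
}

POS_DET <- c("the", "a", "an", "this", "that", "these", "those", "each",
             "every", "no", "any", "some")
POS_PREP <- c("of", "in", "on", "at", "by", "with", "from", "for", "to",
              "into", "under", "over", "between", "through", "during",
              "against", "as", "via")
POS_CONJ <- c("and", "or", "but", "nor", "than", "because", "while",
              "whereas")
POS_PRON <- c("it", "its", "they", "their", "we", "our", "he", "she", "his",
              "her", "which", "who", "whose")
POS_BE <- c("is", "are", "was", "were", "be", "been", "being", "has",
            "have", "had", "can", "may", "might", "must", "should",
            "will", "would", "do", "does", "did")

#' Rule-based part-of-speech tagging
#'
#' Coarse Penn-style tags from closed-class word lists and suffix
#' heuristics. Intended as a feature provider for the sequence tagger, not
#' as a linguistic resource; an external tagger can be substituted by
#' passing its output to [token_features()].
#'
#' @param surfaces Character vector of token surfaces.
#' @return Character vector of tags.
#' @export
pos_tag_words <- function(surfaces) {
  w <- stringi::stri_trans_tolower(surfaces)
  tag <- rep("NN", length(surfaces))
  tag[stringi::stri_detect_regex(surfaces, "^[[:punct:]]+$")] <- "PUNCT"
  tag[stringi::stri_detect_regex(surfaces, "^[0-9]+([.,][0-9]+)*$")] <- "CD"
  tag[w %in% POS_DET] <- "DT"
  tag[w %in% POS_PREP] <- "IN"
  tag[w %in% POS_CONJ] <- "CC"
  tag[w %in% POS_PRON] <- "PRP"
  tag[w %in% POS_BE] <- "VB"
  open <- tag == "NN"
  tag[open & endsWith(w, "ly")] <- "RB"
  tag[open & endsWith(w, "ing") & nchar(w) > 4L] <- "VBG"
  tag[open & endsWith(w, "ed") & nchar(w) > 3L] <- "VBD"
  open <- tag == "NN"
  tag[open & endsWith(w, "s") & !endsWith(w, "ss") & nchar(w) > 3L] <- "NNS"
  tag[tag %in% c("NN", "NNS") &
        stringi::stri_detect_regex(surfaces, "^[A-Z]")] <- "NNP"
  tag
}

#' Rule-based lemmatization
#'
#' Lowercases and removes plural and simple verbal inflections. Like
#' [pos_tag_words()], a deterministic built-in provider that an external
#' lemmatizer can replace.
#'
#' @param surfaces Character vector of token surfaces.
#' @return Character vector of lemmas.
#' @export
lemmatize_words <- function(surfaces) {
  w <- stringi::stri_trans_tolower(surfaces)
  out <- w
  ies <- endsWith(w, "ies") & nchar(w) > 4L
  out[ies] <- paste0(substr(w[ies], 1L, nchar(w[ies]) - 3L), "y")
  es <- out == w & stringi::stri_detect_regex(w, "(xes|ses|ches|shes|zes)$")
  out[es] <- substr(w[es], 1L, nchar(w[es]) - 2L)
  s <- out == w & endsWith(w, "s") & !endsWith(w, "ss") & nchar(w) > 3L
  out[s] <- substr(w[s], 1L, nchar(w[s]) - 1L)
  out
}

#' Character-class word shape
#'
#' Maps uppercase to `X`, lowercase to `x`, digits to `d`, leaving other
#' characters as-is; the collapsed variant squeezes runs (`H2SO4` has shape
#' `XdXXd` and collapsed shape `XdXd`).
#'
#' @param surfaces Character vector.
#' @param collapse Squeeze repeated shape characters?
#' @return Character vector of shapes.
#' @export
word_shape <- function(surfaces, collapse = FALSE) {
  sh <- stringi::stri_replace_all_regex(surfaces, "[A-Z]", "X")
  sh <- stringi::stri_replace_all_regex(sh, "[a-z]", "x")
  sh <- stringi::stri_replace_all_regex(sh, "[0-9]", "d")
  if (collapse) sh <- stringi::stri_replace_all_regex(sh, "(.)\\1+", "$1")
  sh
}

#' Feature extraction configuration
#'
#' @param affix_lengths Prefix/suffix lengths to emit (default 1–4).
#' @param window Context half-width in tokens whose features are copied
#'   with positional prefixes (default 2).
#' @param element_gazetteer Output of [chem_elements()] or a compatible
#'   list.
#' @param ring_morphemes Character vector of chemical morpheme substrings.
#' @param cluster_count Number of word-vector clusters `K` expected from the
#'   cluster model (informational; the model itself carries its `K`).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(affix_lengths = 1:4, window = 2L,
                           element_gazetteer = chem_elements(),
                           ring_morphemes = default_ring_morphemes(),
                           cluster_count = 1000L) {
  stopifnot(window >= 0L, cluster_count >= 2L, all(affix_lengths >= 1L))
  structure(list(affix_lengths = as.integer(affix_lengths),
                 window = as.integer(window),
                 element_gazetteer = element_gazetteer,
                 ring_morphemes = ring_morphemes,
                 cluster_count = as.integer(cluster_count)),
            class = "feature_config")
}

count_bucket <- function(n) {
  ifelse(n >= 3L, "3+", as.character(n))
}

#' Per-token feature maps for the sequence tagger
#'
#' For every token emits: lowercased surface, stem, prefixes and suffixes of
#' the configured lengths, bucketed digit/uppercase/lowercase counts, an
#' element-gazetteer flag, a chemical-morpheme flag, raw and collapsed word
#' shapes, a part-of-speech tag, a lemma, and the word-vector cluster id (or
#' `UNK`). All features of neighbouring tokens within the window are copied
#' with positional prefixes (`[-1]w=...`), with `BOS`/`EOS` markers beyond
#' the sequence edges. Extraction is pure: identical inputs yield identical
#' feature maps.
#'
#' @param tokens Token data frame from [tokenize()].
#' @param config A [feature_config()].
#' @param pos_tags Optional character vector of POS tags (same length as
#'   tokens); computed with [pos_tag_words()] when `NULL`.
#' @param lemmas Optional character vector of lemmas; computed with
#'   [lemmatize_words()] when `NULL`.
#' @param clusters Optional `cluster_model` from [build_clusters()]; when
#'   absent the cluster feature is omitted.
#' @return A list (one element per token) of character vectors of
#'   `name=value` feature strings.
#' @export
token_features <- function(tokens, config = feature_config(),
                           pos_tags = NULL, lemmas = NULL, clusters = NULL) {
  n <- nrow(tokens)
  if (n == 0L) return(list())
  surf <- tokens$surface
  if (is.null(pos_tags)) pos_tags <- pos_tag_words(surf)
  if (is.null(lemmas)) lemmas <- lemmatize_words(surf)
  if (length(pos_tags) != n || length(lemmas) != n) {
    stop("pos_tags/lemmas must have one entry per token")
  }
  low <- stringi::stri_trans_tolower(surf)
  base <- vector("list", n)
  stems <- stem_words(surf)
  dig <- count_bucket(stringi::stri_count_regex(surf, "[0-9]"))
  upp <- count_bucket(stringi::stri_count_regex(surf, "[A-Z]"))
  lwr <- count_bucket(stringi::stri_count_regex(surf, "[a-z]"))
  elem <- surf %in% config$element_gazetteer$symbols |
    low %in% config$element_gazetteer$names
  ring <- rep(FALSE, n)
  for (m in config$ring_morphemes) {
    ring <- ring | stringi::stri_detect_fixed(low, m)
  }
  sh <- word_shape(surf)
  sh2 <- word_shape(surf, collapse = TRUE)
  cl <- if (is.null(clusters)) NULL else clusters_lookup(clusters, low)
  nc <- nchar(surf)
  for (i in seq_len(n)) {
    f <- c(
      paste0("w=", low[i]),
      paste0("stem=", stems[i]),
      paste0("dcount=", dig[i]),
      paste0("ucount=", upp[i]),
      paste0("lcount=", lwr[i]),
      paste0("elem=", elem[i]),
      paste0("ring=", ring[i]),
      paste0("shape=", sh[i]),
      paste0("shape2=", sh2[i]),
      paste0("pos=", pos_tags[i]),
      paste0("lemma=", lemmas[i])
    )
    for (L in config$affix_lengths) {
      if (nc[i] >= L) {
        f <- c(f,
               paste0("pre", L, "=", substr(low[i], 1L, L)),
               paste0("suf", L, "=", substr(low[i], nc[i] - L + 1L, nc[i])))
      }
    }
    if (!is.null(cl)) {
      f <- c(f, paste0("cl=", if (is.na(cl[i])) "UNK" else cl[i]))
    }
    base[[i]] <- f
  }
  if (config$window == 0L) return(base)
  out <- vector("list", n)
  offs <- setdiff(seq.int(-config$window, config$window), 0L)
  for (i in seq_len(n)) {
    f <- base[[i]]
    for (d in offs) {
      j <- i + d
      if (j < 1L) {
        f <- c(f, paste0("[", d, "]BOS"))
      } else if (j > n) {
        f <- c(f, paste0("[", d, "]EOS"))
      } else {
        f <- c(f, paste0("[", d, "]", base[[j]]))
      }
    }
    out[[i]] <- f
  }
  out
}
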