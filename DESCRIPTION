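Package: chemner
Title: Dictionary and CRF Ensemble Recognition of Chemical Mentions in Patent Text
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing chemical entity mentions in patent titles
    and abstracts. Combines a lexicon-based tagger (leftmost-longest matching
    with case-sensitive handling of abbreviations, stoplists, and
    corpus-driven term exclusion/inclusion) with a linear-chain conditional
    random field tagger using morphological, part-of-speech, lemma and
    word-vector-cluster features, followed by tagging-consistency,
    abbreviation-resolution, bracket-boundary and identifier-regex
    post-processing. Includes passage-level chemical classification,
    micro-averaged evaluation metrics, a deterministic synthetic corpus
    generator for offline testing, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    stringi,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
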