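---
title: "Methods: dictionary and CRF ensemble recognition of chemical mentions in patent text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary and CRF ensemble recognition of chemical mentions in patent text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemner)
```

## The recognition problem

Medicinal-chemistry patents are a primary source of compound prior art, but
the chemical entities in them are mostly locked in free text. `chemner`
addresses two coupled tasks on patent titles and abstracts: finding every
chemical mention with exact character offsets (mention-level recognition),
and classifying each title and abstract as chemical-related or not
(passage-level detection). The package follows the classic two-track
architecture for this problem: a lexicon-driven tagger, which is precise and
directly links mentions to compound records, and a statistical sequence
tagger, which generalizes to systematic and family names that no lexicon
covers. The union of both outputs is the ensemble prediction.

All offsets in the package are 0-based, end-exclusive, counted in Unicode
code points within one passage (title or abstract separately). The central
invariant — enforced by `validate_spans()` at every I/O and tagging boundary
— is that a span's surface always equals the passage text sliced
`[start, end)`. Every component is written so that this invariant cannot
silently break: pre-processing is length-preserving, tokenization stores
offsets into the original string, and file readers re-check the slice.

## Dictionary track

**Lexicon model.** Compound entries carry an opaque id, an InChI string and
a set of surface terms. InChI strings are compared as opaque bytes: two
entries with identical strings denote the same structure, and
`merge_lexicons()` collapses them, unioning terms and keeping the
lexicographically smallest id. No structure interpretation (MOL parsing,
InChI canonicalization) happens anywhere; entries without an InChI cannot be
identified across sources and are skipped with a warning.

**Partial case sensitivity.** A term is an *abbreviation* when a strict
majority of its non-whitespace characters are capitals or digits
(`is_abbreviation()`); ties are not a majority. Abbreviations are stored and
matched case-sensitively ("DMSO" does not match "dmso"); all other terms are
case-folded (full Unicode folding). The same routing defines the *lookup
key* used everywhere downstream (term statistics, exclusion), so removing a
term removes all its case variants at once.

**Matching.** `match_lexicon()` scans token windows (up to 8 tokens, joined
by single spaces) leftmost-longest and greedily: the longest window that
matches at a position wins, and scanning resumes after it, so dictionary
spans never overlap. The window bound keeps matching linear; terms longer
than the window are stored but unreachable. Hyphen/space interchange is
deliberately not attempted, keeping every match auditable against the
lexicon.

**Tokenizer.** The reference tokenizer for this task family is not publicly
specified, so the built-in one is a stated approximation behind a small
interface: whitespace chunks are split at their edges only — leading opening
brackets and quotes, trailing sentence punctuation, and trailing closing
brackets *without a matching opener inside the chunk* become one-character
tokens. This keeps `1,2-dichloroethane` and `2-(chloroethyl)benzene` intact
while splitting `(pure)` into three tokens. The known cost: a chunk like
`(R)-ibuprofen` loses its leading `(` into a separate token. Mentions in the
synthetic corpora are whitespace-delimited precisely so that fixture gold
offsets cannot depend on these edge rules.

**Corpus tuning.** Two corpus-driven revisions refine a lexicon against a
training corpus with gold annotations:

* *Exclusion* (`derive_exclusions()`): every predicted span is an exact
  true positive or a false positive; counts pool per lookup key. A term with
  at least one false positive and TP/FP ratio below **0.3** is removed. The
  threshold protects well-behaved terms from an occasional stray hit; 0 FPs
  give a ratio of `Inf` and are never excluded.
* *Inclusion* (`derive_inclusions()`): candidates are gold surfaces missed
  entirely (no overlapping prediction). Each candidate is added temporarily,
  the corpus re-tagged, and the candidate kept only if it produces no false
  positives at all or a TP/FP ratio above **0.5**.

Both rules are self-consistent by construction and the test suite audits
this: excluded terms re-tag to zero detections, admitted terms re-verify
their own admission condition, and a second exclusion pass removes nothing.

## Statistical track

**Pre-processing.** `preprocess_text()` blanks a vertical bar enclosed by
brackets (`[|]` becomes `[ ]`) and transliterates non-ASCII characters to
one-character ASCII stand-ins (Greek letters to the first Latin letter of
their name, typographic dashes and quotes to ASCII, anything else through a
general transliteration truncated to one character, else `?`). Both steps
preserve string length, so spans predicted on the cleaned text are valid in
original coordinates. The one-character rule sacrifices richer
transliterations (`α` becomes `a`, not `alpha`) for offset safety — a
deliberate trade.

**Features.** Per token: lowercased surface, a light suffix-stripping stem,
prefixes/suffixes of lengths 1–4, digit/uppercase/lowercase counts bucketed
0/1/2/3+, an element-gazetteer flag (symbols case-sensitive, names folded),
a chemical-morpheme flag (trivial rings, halogen prefixes, functional-group
suffixes), raw and collapsed word shapes, a part-of-speech tag, a lemma,
and a word-vector cluster id. All features of neighbours within a ±2-token
window are copied with positional prefixes. The POS tagger and lemmatizer
are deterministic rule-based providers (closed-class word lists plus suffix
heuristics) so that no model download is ever needed; both are pluggable
arguments of `token_features()` for anyone with a better provider.

**Word-vector clusters.** `build_clusters()` learns one dense vector per
word and partitions them into `K` clusters; a token's cluster id becomes a
categorical feature shared by distributionally similar words. The embedding
trainer is spectral — positive pointwise mutual information over a ±2-token
co-occurrence window, factorized by truncated SVD — because it is exactly
deterministic, which keeps the whole pipeline reproducible from one seed.
Any trainer producing a dense matrix satisfies the same contract. K-means
runs with a fixed seed; `K` must not exceed the vocabulary. On real-scale
corpora values of `K` in the hundreds to a thousand are typical; synthetic
vocabularies here are small, so tests use small `K`.

**Sequence model.** Mentions are encoded per token as B/I/O (single entity
class, since the mention task is class-blind). The tagger is a linear-chain
conditional random field: emission weights on the sparse binary features,
a 3×3 transition matrix, and start/end weights. Training maximizes the
L2-penalized conditional likelihood with L-BFGS; the objective and its
exact gradient come from forward–backward in log space (implemented in
C++). Weights start at zero, so training is deterministic — the `seed`
recorded in the model documents provenance rather than driving randomness.
Decoding is Viterbi; each decoded token also gets its posterior marginal,
and a span's confidence is the minimum marginal over its tokens. Invalid
BIO output cannot occur from Viterbi, but `bio_decode()` still repairs a
bare `I` as `B` for robustness against external label sources.

Defaults: `l2 = 1`, `max_iter = 150` (L-BFGS converges far earlier on the
synthetic corpora), window ±2, affix lengths 1–4. All are arguments.

**Post-processing.** Four passage-local steps, in order:

1. *Tagging consistency*: a surface tagged ≥2 times has its remaining
   case-sensitive, token-aligned occurrences tagged too (confidence = mean
   of the existing ones). Idempotent. It operates within one passage;
   propagation across the title/abstract boundary is deliberately not done.
2. *Abbreviation resolution*: definitions `long form (SF)` are found by the
   classic rightward letter alignment (short form ≤10 characters, one word,
   every letter matched right-to-left in the long form, the first at a word
   start). If either side is tagged, both sides and later short-form
   occurrences are tagged.
3. *Boundary revision*: spans with unbalanced brackets first try a
   one-character extension that balances them, then trim unbalanced
   brackets at the edges; a span that cannot be balanced is left unchanged.
4. *Identifier tagging*: regex spans for chemical database identifiers;
   the default pattern is the CAS registry number
   `\b[1-9]\d{1,6}-\d{2}-\d\b` with word boundaries. An optional checksum
   validation of the CAS check digit is off by default, keeping the step
   purely regex-defined.

**Ensemble.** The union of dictionary and CRF spans: identical offsets
merge keeping the maximum confidence; overlapping-but-different spans are
both kept. Union recall therefore never falls below the best member's
recall — asserted as a property test. Passage classification is
definitional: a passage is chemical-related exactly when at least one
mention was recognized in it; titles and abstracts are classified
separately.

## Evaluation

Mention evaluation is exact-offset and micro-averaged: a prediction is a
true positive only if a gold span matches its (document, passage, start,
end) exactly; counts pool over all documents before computing
recall = TP/(TP+FN), precision = TP/(TP+FP) and F = 2PR/(P+R). Passage
evaluation adds specificity = TN/(TN+FP) and
accuracy = (TP+TN)/(TP+FN+FP+TN). All metrics are kept at full precision
internally and rendered at two decimals, half-up, only for display. A
metric with a zero denominator is absent, never zero. Two helper
identities, `f_from_precision_recall()` and `accuracy_from_sens_spec()`,
recompute an F-score from a precision/recall pair and an accuracy from
sensitivity, specificity and class sizes — useful for checking reported
figures whose underlying counts are known only through these pairs.

## The synthetic corpus generator

Real annotated patent corpora are large, licensed and external; the
generator supplies deterministic stand-ins with *known composition* so
every stage is testable offline:

* Pseudo-systematic names come from a morpheme grammar
  (prefix(es) + ring + suffix, e.g. strings like "chlorobenzol"), so
  chemical tokens are morphologically marked the way real nomenclature is —
  this is what lets the CRF generalize to terms it never saw.
* A configurable fraction of mentions uses *homographs* (words like "lead"
  that are chemicals in some contexts), and the same words are sprinkled
  into sentences as ordinary words that are *not* gold — this produces
  honest false positives with tunable TP/FP ratios, exercising the
  exclusion and inclusion machinery.
* A configurable fraction of mentions uses chemical-looking terms withheld
  from the lexicon, creating dictionary false negatives; measured
  dictionary recall on such a corpus must equal one minus that fraction up
  to binomial error, and the suite asserts exactly that.
* Mention surfaces are whitespace-delimited, never cross sentence
  boundaries, and contain no tabs, so gold offsets are independent of
  tokenizer edge rules and survive the tab-separated file formats.

What the generator does **not** emulate: real IUPAC grammar and its
punctuation-heavy names, OCR noise, legal boilerplate, nested or
discontinuous mentions, and realistic class imbalance between chemical and
non-chemical passages. Passing the synthetic suite therefore demonstrates
the correctness of the machinery (matching, tuning semantics, learning,
evaluation), not corpus-level performance on real patents: the reported
corpus figures for the real task are reproduced in this package only
through their metric identities, not re-derived from text.

## Numerical choices and problem sizes

* Ties: the abbreviation majority is strict; metric rendering is half-up;
  prediction files order ties by (passage, start, end) so output is
  byte-stable.
* Degenerate inputs: empty corpora, empty lexicons and all-`O` label
  sequences are legal everywhere except CRF training, which refuses data
  with no mention and no features; all-zero counts yield absent metrics.
* Determinism: one seed drives each generator call; embedding training is
  exactly deterministic; K-means and CRF training are seeded or
  deterministic from a zero start. Identical seeds give byte-identical
  fixture files and identical pipeline outputs.
* Problem sizes in the shipped tests and acceptance script: 40 synthetic
  compounds; 60-record corpora for exactness checks, 200 records (split in
  half) for the learning check, 420 records (about 2 100 mentions) for the
  known-composition check. These sizes were chosen once as the smallest
  desk-scale conditions at which the binomial tolerance (three standard
  errors at about 2 000 mentions) is meaningful; the full suite runs in
  about two minutes on one CPU.

## Known limitations

* The tokenizer is an approximation of an unpublished reference; its edge
  behaviour is isolated behind `tokenize()` so an adapter can replace it.
* The built-in POS/lemma providers are coarse; they exist to make the
  feature set self-contained, not to be linguistically complete.
* Exact-offset evaluation only; approximate matching credit is out of
  scope.
* The dictionary track carries no spelling-variant generation; a variant
  absent from the lexicon is simply unseen (and may be recovered by the
  CRF or by term inclusion).
* Single entity class: mention categories (systematic, family, trivial)
  are read from annotation files and preserved, but never scored
  separately.
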