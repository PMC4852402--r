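# chemner

Recognition of chemical entity mentions in patent titles and abstracts, by
an ensemble of a dictionary-based tagger and a statistical sequence tagger,
with passage-level chemical classification and exact-offset evaluation.

## What problem this solves, and for whom

Patent text is a primary source of compound prior art, but its chemistry is
buried in free text. Text-mining practitioners working on patent corpora
need three things this package provides end to end:

1. **Mention recognition (exact offsets).** A lexicon tagger matches
   compound terms by leftmost-longest token windows with *partial case
   sensitivity*: terms whose characters are in the majority capitals and
   digits are abbreviations and match case-sensitively; everything else
   matches case-folded. Lexicons are built from compound entries keyed by
   InChI identity (identical strings ⇒ same compound, entries merged), with
   stoplists, and are revised against a training corpus: a term is
   **excluded** when its ratio of true-positive to false-positive
   detections falls below 0.3, and a missed term is **included** when
   re-indexing it yields no false positives or a ratio above 0.5. In
   parallel, a linear-chain **conditional random field** tags tokens B/I/O
   using stems, affixes, character counts, chemical morphemes, element
   gazetteers, word shapes, POS tags, lemmas and word-vector cluster
   features, followed by tmChem-style post-processing (tagging consistency,
   abbreviation resolution, bracket boundary revision, CAS-number regexes).
   The ensemble output is the union of both span sets.
2. **Passage classification.** A title or abstract is chemical-related
   exactly when at least one mention was recognized in it.
3. **Evaluation.** Micro-averaged recall = TP/(TP+FN),
   precision = TP/(TP+FP), F = 2PR/(P+R) for mentions (exact-offset
   matching), and sensitivity/specificity/accuracy for passages.

Because real annotated patent corpora are licensed and external, the
package ships a deterministic synthetic-corpus generator whose composition
is known exactly (implanted mentions, ambiguous homographs, unseen
chemical-looking terms), so the whole pipeline is testable offline. Real
corpora in the same tab-separated formats flow through the identical I/O
layer.

## Worked example

```r
library(chemner)

cfg <- simulation_config(
  n_compounds = 40, n_records = 120, mentions_per_passage = 2,
  ambiguous_homograph_fraction = 0.1,   # terms like "lead": chemical or not
  unseen_chemical_fraction = 0.3,       # mentions absent from the lexicon
  seed = 7
)
comp    <- make_compounds(cfg)                               # two sources, shared InChIs
lexicon <- build_lexicon(merge_lexicons(list(comp$a, comp$b)),
                         stoplist = character())
corpus  <- make_corpus(lexicon, cfg)                         # gold offsets recorded
halves  <- split_corpus(corpus)

res <- run_pipeline(halves$train, halves$test, lexicon, seed = 7)
print(res$dict$mentions$metrics)
print(res$crf$mentions$metrics)
print(res$ensemble$mentions$metrics)
render_pct(res$ensemble$cpd$metrics$accuracy)
res$excluded
```

Output:

```
dict:     precision=100.00  recall=84.71  f_score=91.72
crf:      precision=99.54   recall=90.08  f_score=94.58
ensemble: precision=99.56   recall=93.39  f_score=96.38
CPD accuracy (ensemble): "97.50"
excluded terms: crystal, gold, iron, lead
```

Reading this: tuning excluded the four homograph terms whose false
positives on the training half overwhelmed their true positives (ratio
below 0.3), and term inclusion recovered missed surfaces, so the tuned
dictionary reaches 84.7% recall at perfect precision despite 30% of
mentions being absent from the original lexicon. The CRF generalizes to
unseen chemical-looking terms from their morphology (90.1% recall), and the
ensemble union dominates both members' recall, as it must. The passage
classifier then labels 97.5% of titles/abstracts correctly.

A command-line mirror of the same pipeline ships in `inst/cli/chemner`
(subcommands `simulate`, `build-lexicon`, `tag-dict`, `tune-terms`,
`train-crf`, `tag-crf`, `ensemble`, `evaluate`, `run-all`).

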