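#' Run the full recognition pipeline on a train/test corpus pair
#'
#' Wires the stages together the way the ensemble system is meant to be
#' used: (1) tune the lexicon on the training corpus (term exclusion at
#' ratio threshold 0.3, optional term inclusion at 0.5); (2) tag the test
#' corpus with the tuned dictionary; (3) train the CRF on the training
#' corpus, tag the test corpus, post-process; (4) take the union of both
#' span sets as the ensemble output; (5) evaluate mentions (micro-averaged
#' P/R/F) and passage classification (sensitivity/specificity/accuracy)
#' against the test gold.
#'
#' @param train Training `chem_corpus` with gold annotations.
#' @param test Evaluation `chem_corpus` with gold annotations.
#' @param lexicon Starting `chem_lexicon`.
#' @param feature_cfg A [feature_config()].
#' @param tuning_cfg A [tuning_config()].
#' @param post_cfg A [postprocess_config()].
#' @param clusters Optional `cluster_model` shared by training and tagging.
#' @param include_missed Run term inclusion after exclusion.
#' @param l2,max_iter CRF training hyperparameters.
#' @param seed Seed recorded in the CRF model.
#' @return A list with the tuned lexicon, the three span sets and, per
#'   system (`dict`, `crf`, `ensemble`), mention and CPD evaluations.
#' @export
run_pipeline <- function(train, test, lexicon,
                         feature_cfg = feature_config(),
                         tuning_cfg = tuning_config(),
                         post_cfg = postprocess_config(),
                         clusters = NULL, include_missed = TRUE,
                         l2 = 1, max_iter = 150L, seed = 1L) {
  tuned <- tune_lexicon(train, lexicon, config = tuning_cfg,
                        include = include_missed)
  dict_spans <- tag_corpus_dict(test, tuned$lexicon)

  train_seqs <- make_crf_sequences(train, feature_cfg, clusters = clusters)
  model <- crf_train(train_seqs, l2 = l2, max_iter = max_iter, seed = seed)
  crf_spans <- tag_corpus_crf(test, model, feature_cfg, clusters = clusters)
  crf_spans <- postprocess_spans(crf_spans, test, post_cfg)

  ens_spans <- ensemble_union(dict_spans, crf_spans)

  gold_cpd <- cpd_gold_labels(test)
  eval_one <- function(spans) {
    list(
      mentions = evaluate_mentions(spans, test$gold),
      cpd = evaluate_cpd(classify_passages(spans, test), gold_cpd)
    )
  }
  list(
    lexicon = tuned$lexicon, excluded = tuned$excluded,
    included = tuned$included, model = model,
    spans = list(dict = dict_spans, crf = crf_spans, ensemble = ens_spans),
    dict = eval_one(dict_spans), crf = eval_one(crf_spans),
    ensemble = eval_one(ens_spans)
  )
}
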