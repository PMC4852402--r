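#' Detection counts
#'
#' @param tp,fp,fn True-positive, false-positive and false-negative counts.
#' @param tn True-negative count; undefined for mention-level evaluation
#'   and then stored as `NA`.
#' @return A list of class `detection_counts`.
#' @export
detection_counts <- function(tp, fp, fn, tn = NA_integer_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, is.na(tn) || tn >= 0)
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn)),
            class = "detection_counts")
}

#' Evaluation metrics from detection counts
#'
#' recall = TP/(TP+FN), precision = TP/(TP+FP), F = 2PR/(P+R),
#' sensitivity = recall, specificity = TN/(TN+FP) and
#' accuracy = (TP+TN)/(TP+FN+FP+TN), all as percentages in `[0, 100]` kept
#' at full precision; two-decimal rounding happens only at rendering
#' ([render_pct()], [print.metrics_report()]). A metric whose denominator
#' is zero is absent (`NA`), not 0.
#'
#' @param counts A [detection_counts()].
#' @return A list of class `metrics_report` with elements `precision`,
#'   `recall`, `f_score`, `sensitivity`, `specificity`, `accuracy`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  div <- function(num, den) if (!is.na(den) && den > 0) 100 * num / den else NA_real_
  p <- div(tp, tp + fp)
  r <- div(tp, tp + fn)
  f <- f_from_precision_recall(p, r)
  spec <- if (is.na(tn)) NA_real_ else div(tn, tn + fp)
  acc <- if (is.na(tn)) NA_real_ else div(tp + tn, tp + fn + fp + tn)
  structure(list(precision = p, recall = r, f_score = f,
                 sensitivity = r, specificity = spec, accuracy = acc,
                 counts = counts),
            class = "metrics_report")
}

#' F-score from a precision/recall pair
#'
#' The harmonic mean `2PR/(P+R)`, on the percentage scale. Useful both
#' inside [metrics_from_counts()] and to recompute an F-score from reported
#' precision and recall figures.
#'
#' @param precision,recall Percentages in `[0, 100]`.
#' @return The F-score percentage (`NA` when undefined).
#' @export
f_from_precision_recall <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    return(NA_real_)
  }
  2 * precision * recall / (precision + recall)
}

#' Accuracy from sensitivity, specificity and class sizes
#'
#' `(sens * n_pos + spec * n_neg) / (n_pos + n_neg)`, all percentages;
#' the weighted form of the accuracy identity, convenient to recompute an
#' accuracy from reported sensitivity/specificity figures and known
#' positive/negative passage counts.
#'
#' @param sensitivity,specificity Percentages in `[0, 100]`.
#' @param n_pos,n_neg Numbers of positive and negative instances.
#' @return The accuracy percentage.
#' @export
accuracy_from_sens_spec <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(n_pos + n_neg > 0)
  (sensitivity * n_pos + specificity * n_neg) / (n_pos + n_neg)
}

#' Render a percentage at two decimals (half-up)
#'
#' @param x Numeric vector of percentages.
#' @return Character vector like `"85.21"` (`"NA"` for absent metrics).
#' @export
render_pct <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.2f", floor(v * 100 + 0.5 + 1e-9) / 100)
  }, "")
}

#' @export
print.metrics_report <- function(x, ...) {
  nm <- c("precision", "recall", "f_score", "sensitivity", "specificity",
          "accuracy")
  vals <- unlist(x[nm])
  keep <- !is.na(vals)
  cat(paste(sprintf("%s=%s", nm[keep], render_pct(vals[keep])),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
print.detection_counts <- function(x, ...) {
  cat(sprintf("tp=%g fp=%g fn=%g tn=%s\n", x$tp, x$fp, x$fn,
              if (is.na(x$tn)) "-" else format(x$tn)))
  invisible(x)
}

#' Union of dictionary and CRF predictions
#'
#' Everything recognized by either member system is kept. Spans identical
#' in (document, passage, start, end) merge into one span carrying the
#' maximum member confidence; overlapping but non-identical spans are both
#' kept.
#'
#' @param dict_spans,crf_spans Span data frames over the same corpus.
#' @return A span data frame with `source = "ensemble"`.
#' @export
ensemble_union <- function(dict_spans, crf_spans) {
  cols <- SPAN_COLS
  both <- rbind(
    if (nrow(dict_spans)) dict_spans[, cols, drop = FALSE] else NULL,
    if (nrow(crf_spans)) crf_spans[, cols, drop = FALSE] else NULL
  )
  if (is.null(both) || nrow(both) == 0L) {
    out <- empty_spans()
    attr(out, "validated") <- TRUE
    return(out)
  }
  id <- span_ids(both)
  conf <- tapply(both$confidence, id, max)
  both <- both[!duplicated(id), , drop = FALSE]
  both$confidence <- as.numeric(conf[span_ids(both)])
  both$source <- "ensemble"
  both <- both[order(both$doc_id, both$passage, both$start, both$end), ,
               drop = FALSE]
  rownames(both) <- NULL
  attr(both, "validated") <- TRUE
  both
}

#' Classify one passage as chemical-related or not
#'
#' A passage is chemical-related exactly when at least one chemical mention
#' was recognized in it.
#'
#' @param spans_in_passage Spans filtered to one (document, passage).
#' @return `"chemical"` or `"non-chemical"`.
#' @export
classify_passage <- function(spans_in_passage) {
  if (nrow(spans_in_passage) > 0L) "chemical" else "non-chemical"
}

#' Classify every passage of a corpus
#'
#' Titles and abstracts are classified separately; passages with no span
#' are non-chemical.
#'
#' @param spans Predicted spans.
#' @param corpus The corpus (all its passages are labelled, including
#'   span-free ones).
#' @return Data frame with `doc_id`, `passage`, `label`.
#' @export
classify_passages <- function(spans, corpus) {
  keys <- expand.grid(passage = c("T", "A"), doc_id = corpus$records$doc_id,
                      stringsAsFactors = FALSE)[, c("doc_id", "passage")]
  has <- paste(keys$doc_id, keys$passage) %in%
    paste(spans$doc_id, spans$passage)
  keys$label <- ifelse(has, "chemical", "non-chemical")
  keys[order(keys$doc_id, keys$passage), , drop = FALSE]
}

#' Gold passage labels from gold mentions
#'
#' @param corpus A corpus with gold annotations.
#' @return Data frame with `doc_id`, `passage`, `label` (chemical iff the
#'   passage contains at least one gold mention).
#' @export
cpd_gold_labels <- function(corpus) {
  if (is.null(corpus$gold)) stop("corpus has no gold annotations")
  classify_passages(corpus$gold, corpus)
}

#' Mention-level evaluation (micro-averaged)
#'
#' A prediction is a true positive exactly when a gold span matches it on
#' (document, passage, start, end); each gold span matches at most one
#' prediction. Counts are pooled over all documents before computing
#' precision, recall and F (micro-averaging). Duplicate predictions are
#' collapsed before counting.
#'
#' @param pred_spans,gold_spans Span data frames over one corpus.
#' @return A list with `counts` ([detection_counts()], `tn` absent) and
#'   `metrics` ([metrics_from_counts()]).
#' @export
evaluate_mentions <- function(pred_spans, gold_spans) {
  pid <- span_ids(pred_spans)
  if (anyDuplicated(pid)) {
    message(sprintf("collapsing %d duplicate predictions",
                    sum(duplicated(pid))))
    pred_spans <- pred_spans[!duplicated(pid), , drop = FALSE]
    pid <- span_ids(pred_spans)
  }
  gid <- unique(span_ids(gold_spans))
  tp <- sum(pid %in% gid)
  counts <- detection_counts(tp = tp, fp = nrow(pred_spans) - tp,
                             fn = length(gid) - tp)
  list(counts = counts, metrics = metrics_from_counts(counts))
}

#' Passage-level (CPD) evaluation
#'
#' Confusion counts over per-passage labels, with chemical as the positive
#' class; sensitivity (= recall), specificity and accuracy follow from the
#' standard formulas.
#'
#' @param pred_labels,gold_labels Data frames with `doc_id`, `passage`,
#'   `label` covering the same passages (for example from
#'   [classify_passages()] and [cpd_gold_labels()]).
#' @return A list with `counts` and `metrics`.
#' @export
evaluate_cpd <- function(pred_labels, gold_labels) {
  pk <- paste(pred_labels$doc_id, pred_labels$passage)
  gk <- paste(gold_labels$doc_id, gold_labels$passage)
  miss <- c(setdiff(gk, pk), setdiff(pk, gk))
  if (length(miss)) {
    stop(sprintf("label sets cover different passages; missing: %s",
                 paste(utils::head(miss, 5L), collapse = ", ")))
  }
  pred <- pred_labels$label[match(gk, pk)] == "chemical"
  gold <- gold_labels$label == "chemical"
  counts <- detection_counts(
    tp = sum(pred & gold), fp = sum(pred & !gold),
    fn = sum(!pred & gold), tn = sum(!pred & !gold)
  )
  list(counts = counts, metrics = metrics_from_counts(counts))
}
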