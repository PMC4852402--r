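BIO_LABELS <- c("B", "I", "O")

#' Encode spans as BIO labels over a token sequence
#'
#' Spans are expected to be token-aligned; a span whose edges fall inside a
#' token is snapped outward to whole tokens with a warning. Overlapping
#' spans are applied in start order; a span whose tokens are already
#' labelled is skipped with a warning.
#'
#' @param spans Data frame with `start`/`end` columns (passage-local).
#' @param tokens Token data frame from [tokenize()].
#' @return Character vector of labels in `{B, I, O}`, one per token.
#' @export
bio_encode <- function(spans, tokens) {
  n <- nrow(tokens)
  labels <- rep("O", n)
  if (is.null(spans) || nrow(spans) == 0L || n == 0L) return(labels)
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    cover <- which(tokens$start < e & tokens$end > s)
    if (length(cover) == 0L) next
    i1 <- cover[1L]; i2 <- cover[length(cover)]
    if (tokens$start[i1] != s || tokens$end[i2] != e) {
      warning(sprintf(
        "span [%d,%d) is not token-aligned; snapped to [%d,%d)",
        s, e, tokens$start[i1], tokens$end[i2]))
    }
    if (any(labels[i1:i2] != "O")) {
      warning(sprintf("span [%d,%d) overlaps an already encoded span; skipped",
                      s, e))
      next
    }
    labels[i1] <- "B"
    if (i2 > i1) labels[(i1 + 1L):i2] <- "I"
  }
  labels
}

#' Decode BIO labels back into spans
#'
#' Emits one span per maximal `B/I` run. An `I` with no preceding `B` (an
#' invalid BIO sequence) is repaired by treating it as `B`.
#'
#' @param labels Character vector in `{B, I, O}`.
#' @param tokens Token data frame the labels refer to.
#' @param text Passage text used to slice surfaces.
#' @return Data frame with `start`, `end`, `surface` and `token_first`,
#'   `token_last` (1-based token indices).
#' @export
bio_decode <- function(labels, tokens, text) {
  n <- length(labels)
  stopifnot(n == nrow(tokens))
  starts <- integer(); ends <- integer()
  cur <- NA_integer_
  for (t in seq_len(n)) {
    if (labels[t] == "B" || (labels[t] == "I" && is.na(cur))) {
      if (!is.na(cur)) { starts <- c(starts, cur); ends <- c(ends, t - 1L) }
      cur <- t
    } else if (labels[t] == "O") {
      if (!is.na(cur)) { starts <- c(starts, cur); ends <- c(ends, t - 1L) }
      cur <- NA_integer_
    }
  }
  if (!is.na(cur)) { starts <- c(starts, cur); ends <- c(ends, n) }
  data.frame(
    start = tokens$start[starts], end = tokens$end[ends],
    surface = substr_many(text, tokens$start[starts], tokens$end[ends]),
    token_first = starts, token_last = ends,
    stringsAsFactors = FALSE
  )
}

#' Build labelled token sequences for the sequence tagger
#'
#' Each title and abstract is pre-processed ([preprocess_text()], which
#' preserves length so offsets stay valid in the original text), tokenized,
#' and featurized. When the corpus carries gold annotations, BIO labels are
#' attached.
#'
#' @param corpus A `chem_corpus`.
#' @param config A [feature_config()].
#' @param clusters Optional `cluster_model`.
#' @param labelled Attach BIO labels from `corpus$gold` (requires gold).
#' @return A list of sequence objects (`doc_id`, `passage`, `text` original
#'   passage text, `tokens`, `features`, and `labels` when labelled).
#' @export
make_crf_sequences <- function(corpus, config = feature_config(),
                               clusters = NULL, labelled = !is.null(corpus$gold)) {
  if (labelled && is.null(corpus$gold)) {
    stop("labelled sequences require gold annotations")
  }
  recs <- corpus$records
  out <- list()
  for (i in seq_len(nrow(recs))) {
    for (p in c("T", "A")) {
      orig <- if (p == "T") recs$title[i] else recs$abstract[i]
      if (!nzchar(orig)) next
      clean <- preprocess_text(orig)
      toks <- tokenize(clean)
      if (nrow(toks) == 0L) next
      seq <- list(
        doc_id = recs$doc_id[i], passage = p, text = orig, tokens = toks,
        features = token_features(toks, config, clusters = clusters)
      )
      if (labelled) {
        g <- corpus$gold[corpus$gold$doc_id == recs$doc_id[i] &
                           corpus$gold$passage == p, , drop = FALSE]
        seq$labels <- bio_encode(g, toks)
      }
      out[[length(out) + 1L]] <- seq
    }
  }
  out
}

feature_namespaces <- function(feats) {
  unique(stringi::stri_replace_first_regex(feats, "=.*$", ""))
}

pack_sequences <- function(sequences, feat_index, with_labels) {
  lapply(sequences, function(s) {
    feats <- lapply(s$features, function(f) {
      ids <- match(f, feat_index)
      as.integer(ids[!is.na(ids)] - 1L)
    })
    lab <- NULL
    if (with_labels) {
      lab <- as.integer(match(s$labels, BIO_LABELS) - 1L)
      if (anyNA(lab)) stop("labels must be B, I or O")
    }
    list(feats = feats, labels = lab)
  })
}

#' Train the linear-chain CRF mention tagger
#'
#' Maximum-likelihood training with L2 regularization; the negative
#' log-likelihood and its exact gradient (forward-backward) are optimized
#' with L-BFGS. Weights start at zero, so training is deterministic.
#'
#' @param sequences Labelled sequences from [make_crf_sequences()].
#' @param l2 L2 regularization strength.
#' @param max_iter Maximum L-BFGS iterations.
#' @param seed Integer recorded with the model (training itself is
#'   deterministic from a zero start).
#' @param min_feature_count Features seen fewer times than this are dropped.
#' @return An object of class `crf_model`.
#' @export
crf_train <- function(sequences, l2 = 1, max_iter = 150L, seed = 1L,
                      min_feature_count = 1L) {
  if (length(sequences) == 0L) stop("no training sequences")
  if (!all(vapply(sequences, function(s) !is.null(s$labels), TRUE))) {
    stop("all training sequences must carry labels")
  }
  if (!any(unlist(lapply(sequences, `[[`, "labels")) == "B")) {
    stop("training data contains no B label (no mentions)")
  }
  all_feats <- unlist(lapply(sequences, function(s) unlist(s$features)),
                      use.names = FALSE)
  if (length(all_feats) == 0L) {
    stop("all token feature maps are empty; nothing to train on")
  }
  if (min_feature_count > 1L) {
    tab <- table(all_feats)
    feat_index <- sort(names(tab)[tab >= min_feature_count])
  } else {
    feat_index <- sort(unique(all_feats))
  }
  nfeat <- length(feat_index)
  L <- length(BIO_LABELS)
  packed <- pack_sequences(sequences, feat_index, with_labels = TRUE)
  npar <- nfeat * L + L * L + 2L * L
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    key <- theta
    if (!is.null(cache$theta) && identical(cache$theta, key)) return(cache$val)
    val <- cpp_crf_nll_grad(packed, theta, nfeat, L, l2)
    cache$theta <- key
    cache$val <- val
    val
  }
  fit <- stats::optim(
    par = numeric(npar),
    fn = function(th) evaluate(th)$nll,
    gr = function(th) evaluate(th)$grad,
    method = "L-BFGS-B",
    control = list(maxit = as.integer(max_iter), factr = 1e8)
  )
  structure(list(
    weights = fit$par, feat_index = feat_index, labels = BIO_LABELS,
    l2 = l2, seed = as.integer(seed), nll = fit$value,
    convergence = fit$convergence
  ), class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf("<crf_model> %d features, labels %s, final nll %.2f\n",
              length(x$feat_index), paste(x$labels, collapse = "/"), x$nll))
  invisible(x)
}

#' Predict BIO labels and token marginals
#'
#' Viterbi decoding plus forward-backward posterior marginals of the
#' decoded labels. Prediction is deterministic given a model. Features
#' unseen at training time are ignored; if the input shares no feature
#' namespace with the model at all, the schemas are incompatible and an
#' error names the offending namespaces.
#'
#' @param model A `crf_model`.
#' @param sequences Sequences from [make_crf_sequences()] (labels ignored).
#' @return The sequences, each with `labels` (predicted) and `marginal`
#'   (per-token posterior of the predicted label, in `[0, 1]`).
#' @export
crf_predict <- function(model, sequences) {
  if (length(sequences) == 0L) return(sequences)
  in_ns <- feature_namespaces(unique(unlist(lapply(sequences, function(s) {
    unlist(s$features, use.names = FALSE)
  }))))
  model_ns <- feature_namespaces(model$feat_index)
  if (length(in_ns) && !length(intersect(in_ns, model_ns))) {
    stop(sprintf(
      "feature schema mismatch: input namespaces {%s} share nothing with model namespaces {%s}",
      paste(utils::head(in_ns, 5L), collapse = ", "),
      paste(utils::head(model_ns, 5L), collapse = ", ")
    ))
  }
  packed <- pack_sequences(sequences, model$feat_index, with_labels = FALSE)
  dec <- cpp_crf_decode(packed, model$weights, length(model$feat_index),
                        length(model$labels))
  for (i in seq_along(sequences)) {
    sequences[[i]]$labels <- model$labels[dec[[i]]$labels + 1L]
    sequences[[i]]$marginal <- dec[[i]]$marginal
  }
  sequences
}

#' Tag a corpus with a trained CRF model
#'
#' Builds sequences, predicts, decodes BIO runs to spans, and reports each
#' span with the minimum of its member-token marginals as confidence.
#'
#' @param corpus A `chem_corpus`.
#' @param model A `crf_model`.
#' @param config The [feature_config()] used at training time.
#' @param clusters The `cluster_model` used at training time (or `NULL`).
#' @return A validated span data frame with `source = "crf"`.
#' @export
tag_corpus_crf <- function(corpus, model, config = feature_config(),
                           clusters = NULL) {
  seqs <- make_crf_sequences(corpus, config, clusters = clusters,
                             labelled = FALSE)
  seqs <- crf_predict(model, seqs)
  out <- list()
  for (s in seqs) {
    d <- bio_decode(s$labels, s$tokens, s$text)
    if (nrow(d) == 0L) next
    conf <- vapply(seq_len(nrow(d)), function(k) {
      min(s$marginal[d$token_first[k]:d$token_last[k]])
    }, 0)
    sp <- mention_spans(s$doc_id, s$passage, d$start, d$end, d$surface,
                        source = "crf", confidence = conf)
    out[[length(out) + 1L]] <- sp
  }
  spans <- if (length(out)) do.call(rbind, out) else empty_spans()
  validate_spans(spans, corpus)
}
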