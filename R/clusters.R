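#' Train word-vector clusters
#'
#' Learns dense word embeddings from a token stream and partitions them into
#' `K` clusters with K-means; the cluster id of a word is then used as a
#' categorical feature by the sequence tagger. The embedding trainer is a
#' deterministic spectral one: a positive pointwise-mutual-information
#' co-occurrence matrix (symmetric window) factorized by truncated SVD.
#' Any trainer producing one dense vector per word satisfies the same
#' contract. Given identical inputs and seed the word-to-cluster mapping is
#' identical.
#'
#' @param token_stream Character vector of tokens in corpus order, or a
#'   list of such vectors (one per document; co-occurrence never crosses
#'   document boundaries). Tokens are lowercased.
#' @param dim Embedding dimensionality (capped at the vocabulary size).
#' @param K Number of clusters; must be at least 2 and at most the
#'   vocabulary size.
#' @param seed Integer seed driving the K-means initialization.
#' @param window Co-occurrence half-window in tokens.
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @return An object of class `cluster_model`: a named integer vector
#'   `clusters` mapping word to cluster id in `[0, K)`, the learned
#'   `embeddings` matrix (one row per vocabulary word), plus `K`, `dim` and
#'   `seed`.
#' @export
build_clusters <- function(token_stream, dim = 50L, K = 1000L, seed = 1L,
                           window = 2L, min_count = 1L) {
  if (is.character(token_stream)) token_stream <- list(token_stream)
  token_stream <- lapply(token_stream, function(x) {
    stringi::stri_trans_tolower(as.character(x))
  })
  all_tok <- unlist(token_stream, use.names = FALSE)
  if (length(all_tok) == 0L) stop("token stream is empty")
  tab <- table(all_tok)
  vocab <- sort(names(tab)[tab >= min_count])
  V <- length(vocab)
  if (K > V) stop(sprintf("K = %d exceeds vocabulary size %d", K, V))
  if (K < 2L) stop("K must be at least 2")
  co <- matrix(0, V, V, dimnames = list(vocab, vocab))
  for (doc in token_stream) {
    ids <- match(doc, vocab)
    n <- length(ids)
    for (d in seq_len(window)) {
      if (n <= d) next
      a <- ids[seq_len(n - d)]
      b <- ids[seq.int(d + 1L, n)]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      for (k in which(ok)) {
        co[a[k], b[k]] <- co[a[k], b[k]] + 1
        co[b[k], a[k]] <- co[b[k], a[k]] + 1
      }
    }
  }
  total <- sum(co)
  if (total == 0) stop("no co-occurrences in the token stream")
  rs <- rowSums(co)
  # positive PMI with a small floor to avoid log(0)
  expected <- outer(rs, rs) / total
  pmi <- log(pmax(co, 0) * total / pmax(expected * total, 1e-12))
  pmi[co == 0] <- 0
  pmi[pmi < 0] <- 0
  dim <- min(as.integer(dim), V)
  sv <- svd(pmi, nu = dim, nv = 0L)
  emb <- sv$u * rep(sqrt(pmax(sv$d[seq_len(dim)], 0)), each = V)
  rownames(emb) <- vocab
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  km <- stats::kmeans(emb, centers = K, nstart = 5L, iter.max = 100L)
  structure(list(
    clusters = stats::setNames(as.integer(km$cluster) - 1L, vocab),
    K = as.integer(K), dim = dim, seed = as.integer(seed),
    embeddings = emb
  ), class = "cluster_model")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d words in %d clusters (dim %d, seed %d)\n",
              length(x$clusters), x$K, x$dim, x$seed))
  invisible(x)
}

#' Cluster id of words
#'
#' @param model A `cluster_model`.
#' @param words Character vector (lowercased internally).
#' @return Integer vector of cluster ids in `[0, K)`, `NA` for unmapped
#'   words (rendered as `UNK` in features).
#' @export
clusters_lookup <- function(model, words) {
  unname(model$clusters[stringi::stri_trans_tolower(words)])
}

#' Write a cluster model to a text file
#'
#' Format: `word TAB cluster_id`, sorted by word.
#'
#' @param model A `cluster_model`.
#' @param path Output path.
#' @export
write_clusters <- function(model, path) {
  w <- sort(names(model$clusters))
  write_utf8_lines(paste(w, model$clusters[w], sep = "\t"), path)
}

#' Read a cluster model written by [write_clusters()]
#'
#' @param path Path to the file.
#' @return A `cluster_model` (with `dim` and `seed` unknown, set to `NA`).
#' @export
read_clusters <- function(path) {
  lines <- read_utf8_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- split_fields(lines, 2L, path, "clusters")
  m <- do.call(rbind, parts)
  ids <- stats::setNames(as.integer(m[, 2L]), m[, 1L])
  structure(list(clusters = ids, K = max(ids) + 1L, dim = NA_integer_,
                 seed = NA_integer_), class = "cluster_model")
}
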