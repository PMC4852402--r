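#' @useDynLib chemner, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim kmeans rpois runif
#' @importFrom utils head tail
NULL

SPAN_COLS <- c("doc_id", "passage", "start", "end", "surface", "source", "confidence")

#' Create an empty mention-span table
#'
#' Mention spans are stored as plain data frames with one row per mention.
#' Offsets are 0-based character (code point) positions into the passage text
#' (title or abstract, counted separately), with `end` exclusive, so that
#' `surface` always equals the passage text sliced `[start, end)`.
#'
#' @return A zero-row data frame with columns `doc_id`, `passage` (`"T"` or
#'   `"A"`), `start`, `end`, `surface`, `source` (`"dict"`, `"crf"`,
#'   `"ensemble"` or `"gold"`) and `confidence` (in `[0, 1]`).
#' @export
empty_spans <- function() {
  data.frame(
    doc_id = character(), passage = character(),
    start = integer(), end = integer(),
    surface = character(), source = character(),
    confidence = numeric(), stringsAsFactors = FALSE
  )
}

#' Construct a mention-span table
#'
#' @param doc_id,passage,start,end,surface Span fields (recycled as usual).
#' @param source Provenance of the spans: `"dict"`, `"crf"`, `"ensemble"` or
#'   `"gold"`.
#' @param confidence Numeric confidence in `[0, 1]`; dictionary matches
#'   default to 1.
#' @return A span data frame (see [empty_spans()] for the column contract).
#' @export
mention_spans <- function(doc_id, passage, start, end, surface,
                          source = "dict", confidence = 1) {
  if (length(doc_id) == 0L) return(empty_spans())
  data.frame(
    doc_id = as.character(doc_id), passage = as.character(passage),
    start = as.integer(start), end = as.integer(end),
    surface = as.character(surface), source = as.character(source),
    confidence = as.numeric(confidence), stringsAsFactors = FALSE
  )
}

#' Assemble a patent corpus
#'
#' A corpus holds an ordered table of patent records (one title and one
#' abstract each) and, optionally, gold-standard chemical mention annotations.
#'
#' @param records Data frame with character columns `doc_id`, `title`,
#'   `abstract`. Document ids must be non-empty and unique; titles and
#'   abstracts may be empty strings but not `NA`.
#' @param gold Optional span data frame of gold annotations (source is forced
#'   to `"gold"`); validated against `records`.
#' @return An object of class `chem_corpus`.
#' @export
chem_corpus <- function(records, gold = NULL) {
  stopifnot(is.data.frame(records))
  req <- c("doc_id", "title", "abstract")
  if (!all(req %in% names(records))) {
    stop("records must have columns doc_id, title, abstract")
  }
  records <- records[, req, drop = FALSE]
  for (cl in req) records[[cl]] <- as.character(records[[cl]])
  if (anyNA(records$doc_id) || any(!nzchar(records$doc_id))) {
    stop("doc_id must be non-empty")
  }
  if (anyDuplicated(records$doc_id)) {
    dup <- records$doc_id[duplicated(records$doc_id)][1L]
    stop(sprintf("duplicate doc_id: '%s'", dup))
  }
  if (anyNA(records$title) || anyNA(records$abstract)) {
    stop("title/abstract may be empty but not NA")
  }
  rownames(records) <- NULL
  corpus <- structure(list(records = records, gold = NULL),
                      class = "chem_corpus")
  if (!is.null(gold)) {
    gold$source <- "gold"
    gold <- validate_spans(gold, corpus)
    if (anyDuplicated(gold[, c("doc_id", "passage", "start", "end")])) {
      stop("gold spans contain duplicates")
    }
    corpus$gold <- gold
  }
  corpus
}

#' @export
print.chem_corpus <- function(x, ...) {
  cat(sprintf("<chem_corpus> %d records, %s gold spans\n",
              nrow(x$records),
              if (is.null(x$gold)) "no" else nrow(x$gold)))
  invisible(x)
}

#' Number of records in a corpus
#' @param x A `chem_corpus`.
#' @export
n_records <- function(x) nrow(x$records)

#' Retrieve the text of one passage
#'
#' @param corpus A `chem_corpus`.
#' @param doc_id Document identifier.
#' @param passage `"T"` for title, `"A"` for abstract.
#' @return The passage text (length-1 character).
#' @export
passage_text <- function(corpus, doc_id, passage) {
  i <- match(doc_id, corpus$records$doc_id)
  if (is.na(i)) stop(sprintf("unknown doc_id '%s'", doc_id))
  if (passage == "T") corpus$records$title[i]
  else if (passage == "A") corpus$records$abstract[i]
  else stop("passage must be 'T' or 'A'")
}

# 0-based, end-exclusive slice in code points
slice_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

#' Validate mention spans against a corpus
#'
#' Checks the span invariants: known document, passage in `{T, A}`,
#' `0 <= start < end <= nchar(passage)`, and `surface` equal to the passage
#' slice `[start, end)`.
#'
#' @param spans Span data frame.
#' @param corpus A `chem_corpus`.
#' @return The validated spans (invisibly coerced to canonical column types),
#'   with attribute `validated = TRUE`.
#' @export
validate_spans <- function(spans, corpus) {
  stopifnot(is.data.frame(spans))
  if (nrow(spans) == 0L) {
    out <- empty_spans()
    attr(out, "validated") <- TRUE
    return(out)
  }
  miss <- setdiff(SPAN_COLS, names(spans))
  if ("confidence" %in% miss) spans$confidence <- 1
  if ("source" %in% miss) spans$source <- "dict"
  miss <- setdiff(SPAN_COLS, names(spans))
  if (length(miss)) stop("spans missing columns: ", paste(miss, collapse = ", "))
  spans$start <- as.integer(spans$start)
  spans$end <- as.integer(spans$end)
  bad_doc <- !(spans$doc_id %in% corpus$records$doc_id)
  if (any(bad_doc)) {
    stop(sprintf("span references unknown doc_id '%s'",
                 spans$doc_id[bad_doc][1L]))
  }
  if (any(!spans$passage %in% c("T", "A"))) stop("passage must be 'T' or 'A'")
  i <- match(spans$doc_id, corpus$records$doc_id)
  text <- ifelse(spans$passage == "T",
                 corpus$records$title[i], corpus$records$abstract[i])
  len <- nchar(text)
  bad <- spans$start < 0L | spans$start >= spans$end | spans$end > len
  if (any(bad)) {
    k <- which(bad)[1L]
    stop(sprintf(
      "span %s %s [%d,%d) out of range (passage length %d)",
      spans$doc_id[k], spans$passage[k], spans$start[k], spans$end[k], len[k]
    ))
  }
  got <- substr(text, spans$start + 1L, spans$end)
  mism <- got != spans$surface
  if (any(mism)) {
    k <- which(mism)[1L]
    stop(sprintf(
      "surface mismatch for %s %s [%d,%d): annotation '%s' but passage has '%s'",
      spans$doc_id[k], spans$passage[k], spans$start[k], spans$end[k],
      spans$surface[k], got[k]
    ))
  }
  rownames(spans) <- NULL
  attr(spans, "validated") <- TRUE
  spans
}

split_fields <- function(lines, n_expected, path, what) {
  parts <- stringi::stri_split_fixed(lines, "\t")
  nf <- lengths(parts)
  bad <- which(nf != n_expected)
  if (length(bad)) {
    stop(sprintf(
      "%s: line %d of '%s' has %d tab-separated fields (expected %d)",
      what, bad[1L], path, nf[bad[1L]], n_expected
    ))
  }
  parts
}

read_utf8_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

write_utf8_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Read patent records
#'
#' Reads a UTF-8, tab-separated records file with one line per patent record:
#' `doc_id TAB title TAB abstract`. Embedded tab characters inside titles or
#' abstracts are not supported and make a line fail loudly (wrong field
#' count).
#'
#' @param path Path to the records file.
#' @return A `chem_corpus` with records only.
#' @export
read_records <- function(path) {
  lines <- read_utf8_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(chem_corpus(data.frame(doc_id = character(), title = character(),
                                  abstract = character(),
                                  stringsAsFactors = FALSE)))
  }
  parts <- split_fields(lines, 3L, path, "records")
  m <- do.call(rbind, parts)
  chem_corpus(data.frame(doc_id = m[, 1L], title = m[, 2L],
                         abstract = m[, 3L], stringsAsFactors = FALSE))
}

#' Write patent records
#'
#' @param corpus A `chem_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(corpus, path) {
  r <- corpus$records
  if (any(stringi::stri_detect_fixed(c(r$title, r$abstract), "\t"))) {
    stop("titles/abstracts must not contain TAB characters")
  }
  write_utf8_lines(paste(r$doc_id, r$title, r$abstract, sep = "\t"), path)
}

#' Read gold mention annotations
#'
#' Annotation lines are `doc_id TAB passage TAB start TAB end TAB surface`
#' with an optional sixth column carrying a mention class, which is preserved
#' in a `class` column but ignored by evaluation. Offsets are 0-based,
#' end-exclusive code point positions. Every span is validated against the
#' corpus text; a mismatching surface or out-of-range offset is an error that
#' names the offending line.
#'
#' @param path Path to the annotation file.
#' @param corpus The `chem_corpus` the annotations refer to.
#' @return A validated span data frame with `source = "gold"`.
#' @export
read_annotations <- function(path, corpus) {
  lines <- read_utf8_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(validate_spans(empty_spans(), corpus))
  parts <- stringi::stri_split_fixed(lines, "\t")
  nf <- lengths(parts)
  bad <- which(nf < 5L | nf > 6L)
  if (length(bad)) {
    stop(sprintf("annotations: line %d of '%s' has %d fields (expected 5 or 6)",
                 bad[1L], path, nf[bad[1L]]))
  }
  get <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else NA_character_, "")
  spans <- mention_spans(
    doc_id = get(1L), passage = get(2L),
    start = as.integer(get(3L)), end = as.integer(get(4L)),
    surface = get(5L), source = "gold", confidence = 1
  )
  cls <- get(6L)
  if (any(!is.na(cls))) spans$class <- cls
  out <- tryCatch(validate_spans(spans, corpus), error = function(e) e)
  if (inherits(out, "error")) {
    stop(sprintf("invalid annotation in '%s': %s", path, conditionMessage(out)))
  }
  out
}

#' Write annotations in the gold format
#'
#' @param spans Span data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(spans, path) {
  o <- order(spans$doc_id, spans$passage, spans$start, spans$end)
  spans <- spans[o, , drop = FALSE]
  lines <- paste(spans$doc_id, spans$passage, spans$start, spans$end,
                 spans$surface, sep = "\t")
  if (!is.null(spans$class) && any(!is.na(spans$class))) {
    lines <- paste(lines, ifelse(is.na(spans$class), "", spans$class), sep = "\t")
  }
  write_utf8_lines(lines, path)
}

#' Write predictions in the submission format
#'
#' One line per predicted span: `doc_id TAB passage:start:end TAB rank TAB
#' confidence`. Ranks run 1..n per document in decreasing confidence, with
#' ties broken deterministically by (passage, start, end), so repeated runs on
#' the same input are byte-identical.
#'
#' @param spans Span data frame that has passed [validate_spans()] (the
#'   `validated` attribute is required; unvalidated spans are refused).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(spans, path) {
  if (!isTRUE(attr(spans, "validated"))) {
    stop("write_predictions requires spans validated by validate_spans()")
  }
  if (nrow(spans) == 0L) return(write_utf8_lines(character(), path))
  o <- order(spans$doc_id, -spans$confidence, spans$passage,
             spans$start, spans$end)
  spans <- spans[o, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(spans)), spans$doc_id, FUN = seq_along)
  lines <- paste(spans$doc_id,
                 paste0(spans$passage, ":", spans$start, ":", spans$end),
                 rank, format_num(spans$confidence), sep = "\t")
  write_utf8_lines(lines, path)
}

format_num <- function(x) {
  vapply(x, function(v) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    s
  }, "")
}

#' Read predictions written by [write_predictions()]
#'
#' @param path Path to the prediction file.
#' @param corpus The corpus the predictions refer to (used to restore
#'   surfaces and validate offsets).
#' @param source Source label to assign to the read spans.
#' @return A validated span data frame.
#' @export
read_predictions <- function(path, corpus, source = "ensemble") {
  lines <- read_utf8_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(validate_spans(empty_spans(), corpus))
  parts <- split_fields(lines, 4L, path, "predictions")
  m <- do.call(rbind, parts)
  loc <- stringi::stri_split_fixed(m[, 2L], ":")
  if (any(lengths(loc) != 3L)) stop("malformed passage:start:end field")
  loc <- do.call(rbind, loc)
  i <- match(m[, 1L], corpus$records$doc_id)
  if (anyNA(i)) stop(sprintf("prediction references unknown doc_id '%s'",
                             m[is.na(i), 1L][1L]))
  text <- ifelse(loc[, 1L] == "T", corpus$records$title[i],
                 corpus$records$abstract[i])
  start <- as.integer(loc[, 2L]); end <- as.integer(loc[, 3L])
  spans <- mention_spans(
    doc_id = m[, 1L], passage = loc[, 1L], start = start, end = end,
    surface = substr(text, start + 1L, end),
    source = source, confidence = as.numeric(m[, 4L])
  )
  validate_spans(spans, corpus)
}
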