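# one-character ASCII equivalents for characters the tagger must survive;
# every replacement is exactly one character so offsets never move
GREEK_MAP <- c(
  "α" = "a", "β" = "b", "γ" = "g", "δ" = "d",
  "ε" = "e", "ζ" = "z", "η" = "e", "θ" = "t",
  "ι" = "i", "κ" = "k", "λ" = "l", "μ" = "m",
  "ν" = "n", "ξ" = "x", "ο" = "o", "π" = "p",
  "ρ" = "r", "ς" = "s", "σ" = "s", "τ" = "t",
  "υ" = "u", "φ" = "p", "χ" = "c", "ψ" = "p",
  "ω" = "o",
  "Α" = "A", "Β" = "B", "Γ" = "G", "Δ" = "D",
  "Ε" = "E", "Ζ" = "Z", "Η" = "E", "Θ" = "T",
  "Ι" = "I", "Κ" = "K", "Λ" = "L", "Μ" = "M",
  "Ν" = "N", "Ξ" = "X", "Ο" = "O", "Π" = "P",
  "Ρ" = "R", "Σ" = "S", "Τ" = "T", "Υ" = "U",
  "Φ" = "P", "Χ" = "C", "Ψ" = "P", "Ω" = "O",
  # typographic dashes, quotes, and common symbols
  "‐" = "-", "‑" = "-", "‒" = "-", "–" = "-",
  "—" = "-", "―" = "-", "−" = "-",
  "‘" = "'", "’" = "'", "‚" = "'", "′" = "'",
  "“" = "\"", "”" = "\"", "„" = "\"", "″" = "\"",
  "×" = "x", "·" = ".", "•" = ".", "°" = "o",
  " " = " ", "…" = ".", "µ" = "u"
)

#' Transliterate non-ASCII characters to one-character ASCII stand-ins
#'
#' Greek letters map to the first Latin letter of their name (so
#' `α`-pinene becomes `a-pinene`), typographic dashes and quotes to their
#' ASCII forms, and anything else non-ASCII falls back to a general
#' Latin-ASCII transliteration truncated to one character, or `?`. Every
#' replacement is exactly one character, so string length — and therefore
#' every mention offset — is preserved and the offset map is the identity.
#'
#' @param text Character vector.
#' @return Character vector of the same lengths, pure ASCII.
#' @export
transliterate <- function(text) {
  out <- stringi::stri_replace_all_fixed(
    text, names(GREEK_MAP), unname(GREEK_MAP), vectorize_all = FALSE
  )
  nonascii <- unique(unlist(
    stringi::stri_extract_all_regex(out, "[^\\x00-\\x7f]", omit_no_match = TRUE),
    use.names = FALSE
  ))
  if (length(nonascii)) {
    repl <- vapply(nonascii, function(ch) {
      t <- suppressWarnings(
        stringi::stri_trans_general(ch, "Any-Latin; Latin-ASCII")
      )
      t1 <- substr(t, 1L, 1L)
      if (nzchar(t1) && !stringi::stri_detect_regex(t1, "[^\\x20-\\x7e]")) t1 else "?"
    }, "")
    out <- stringi::stri_replace_all_fixed(out, nonascii, repl,
                                           vectorize_all = FALSE)
  }
  stopifnot(all(nchar(out) == nchar(text)))
  out
}

#' Replace a vertical bar enclosed by brackets
#'
#' A `|` immediately between `()`, `[]` or `{}` (as in `[|]`) is replaced by
#' a single space; everything else, including bars outside brackets, is left
#' untouched. Length-preserving.
#'
#' @param text Character vector.
#' @return Character vector with enclosed bars blanked.
#' @export
sanitize_bars <- function(text) {
  stringi::stri_replace_all_regex(
    text, "(?<=[\\(\\[\\{])\\|(?=[\\)\\]\\}])", " "
  )
}

#' Standard passage pre-processing for the statistical tagger
#'
#' Applies [sanitize_bars()] then [transliterate()]. Both steps preserve
#' string length, so spans predicted on the pre-processed text are valid in
#' the original passage coordinates.
#'
#' @param text Character vector of passages.
#' @return Pre-processed text of identical lengths.
#' @export
preprocess_text <- function(text) {
  transliterate(sanitize_bars(text))
}
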