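#' Tokenizer contracts
#'
#' A tokenizer is a deterministic mapping from a word to a non-empty list of
#' subword pieces, plus the special tokens framing the encoded sequence. Two
#' implementations ship with the package:
#'
#' * `word_tokenizer()` — every word is a single piece (the identity mapping);
#'   appropriate for the synthetic corpora whose tokens are already atomic.
#' * `subword_tokenizer()` — splits words on internal hyphens, keeping the
#'   hyphen as its own piece (so "UV-light" becomes "UV", "-", "light"), and
#'   optionally chunks residual pieces longer than `max_piece_chars`
#'   characters. Exercises the first-piece/last-piece label-placement rules
#'   without a learned vocabulary.
#'
#' Concatenating a word's pieces always recovers the word.
#'
#' @param max_piece_chars chunk length for long pieces (subword tokenizer).
#' @return object of class `mrc_tokenizer` with fields `pieces_of` (function),
#'   `cls`, `sep`, `name`.
#' @export
word_tokenizer <- function() {
  structure(list(pieces_of = function(word) word,
                 cls = "[CLS]", sep = "[SEP]", name = "word"),
            class = "mrc_tokenizer")
}

#' @rdname word_tokenizer
#' @export
subword_tokenizer <- function(max_piece_chars = 8L) {
  pieces_of <- function(word) {
    if (!nzchar(word)) stop("empty word")
    raw <- strsplit(word, "(?<=-)|(?=-)", perl = TRUE)[[1]]
    raw <- raw[nzchar(raw)]
    out <- character()
    for (p in raw) {
      while (nchar(p) > max_piece_chars) {
        out <- c(out, substr(p, 1L, max_piece_chars))
        p <- substr(p, max_piece_chars + 1L, nchar(p))
      }
      out <- c(out, p)
    }
    out
  }
  structure(list(pieces_of = pieces_of, cls = "[CLS]", sep = "[SEP]",
                 name = "subword"),
            class = "mrc_tokenizer")
}

tokenize_words <- function(tok, words) lapply(words, tok$pieces_of)

# query text -> pieces: whitespace word split, then per-word pieces
query_pieces <- function(tok, text) {
  words <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  unlist(tokenize_words(tok, words), use.names = FALSE)
}
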