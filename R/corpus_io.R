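#' Construct a labeled corpus
#'
#' A labeled corpus holds pre-tokenized sentences together with typed entity
#' spans in word-index space (0-based, end-inclusive). This is the central
#' container every other stage of the pipeline consumes: the CoNLL reader
#' produces one, the synthetic generator emits one, and the span model's
#' predictions are decoded back into one.
#'
#' @param sentences list of character vectors, one per sentence; every token
#'   must be a non-empty string without whitespace.
#' @param spans list (same length) of data.frames with integer columns
#'   `start`, `end` and character column `label`; may have zero rows.
#' @param labels character vector of declared entity-type names. Defaults to
#'   the union of labels present in `spans`.
#' @param sentence_ids optional character identifiers, default "s1", "s2", ...
#' @return an object of class `mrc_corpus`.
#' @export
mrc_corpus <- function(sentences, spans = NULL, labels = NULL,
                       sentence_ids = NULL) {
  stopifnot(is.list(sentences))
  n <- length(sentences)
  if (is.null(spans)) spans <- replicate(n, empty_spans(), simplify = FALSE)
  stopifnot(length(spans) == n)
  if (is.null(sentence_ids)) sentence_ids <- paste0("s", seq_len(n))
  spans <- lapply(spans, as_span_frame)
  for (i in seq_len(n)) {
    toks <- sentences[[i]]
    if (length(toks) == 0L || any(!nzchar(toks)))
      stop("sentence ", sentence_ids[i], ": tokens must be non-empty strings")
    sp <- spans[[i]]
    if (nrow(sp) > 0L) {
      bad <- sp$start < 0L | sp$end < sp$start | sp$end >= length(toks)
      if (any(bad))
        stop("sentence ", sentence_ids[i], ": span out of range (",
             paste(sprintf("(%d,%d,%s)", sp$start[bad], sp$end[bad],
                           sp$label[bad]), collapse = ", "), ")")
    }
  }
  seen <- unique(unlist(lapply(spans, function(s) s$label), use.names = FALSE))
  labels <- union(if (is.null(labels)) character() else labels, seen)
  structure(list(sentences = sentences, spans = spans,
                 labels = as.character(labels),
                 sentence_ids = as.character(sentence_ids)),
            class = "mrc_corpus")
}

empty_spans <- function() {
  data.frame(start = integer(), end = integer(), label = character(),
             stringsAsFactors = FALSE)
}

as_span_frame <- function(sp) {
  if (is.null(sp) || (is.data.frame(sp) && nrow(sp) == 0L)) return(empty_spans())
  sp <- as.data.frame(sp, stringsAsFactors = FALSE)
  stopifnot(all(c("start", "end", "label") %in% names(sp)))
  out <- data.frame(start = as.integer(sp$start), end = as.integer(sp$end),
                    label = as.character(sp$label), stringsAsFactors = FALSE)
  # canonical order makes span sets comparable across representations
  out[order(out$start, out$end, out$label), , drop = FALSE] |> reset_rows()
}

reset_rows <- function(df) { rownames(df) <- NULL; df }

#' @export
print.mrc_corpus <- function(x, ...) {
  st <- corpus_stats(x)
  cat(sprintf("<mrc_corpus> %d sentences, %d annotations, %d entity types (%s)\n",
              st$sentences, st$annotations, length(x$labels),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Number of sentences in a corpus
#' @param corpus an `mrc_corpus`.
#' @return integer count.
#' @export
n_sentences <- function(corpus) length(corpus$sentences)

#' Read a CoNLL-style two-column BIO file
#'
#' Parses "token tag" lines (any whitespace run as separator; the first field
#' is the token, the last is the tag) with blank-line sentence breaks, and
#' converts each tag sequence to entity spans. `-DOCSTART-` document markers
#' are skipped. Orphan `I-` tags are repaired as span starts under the default
#' lenient mode (with a warning); `strict = TRUE` raises instead.
#'
#' @param path file path, or a character vector of lines via `lines =`.
#' @param lines character vector of raw lines (alternative to `path`).
#' @param declared_labels optional label set to declare beyond those observed.
#' @param strict logical; orphan `I-` handling (see Details).
#' @return an `mrc_corpus`.
#' @export
read_conll <- function(path = NULL, lines = NULL, declared_labels = NULL,
                       strict = FALSE) {
  if (is.null(lines)) lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list(); tagseqs <- list()
  cur_tok <- character(); cur_tag <- character()
  flush <- function() {
    if (length(cur_tok) > 0L) {
      sentences[[length(sentences) + 1L]] <<- cur_tok
      tagseqs[[length(tagseqs) + 1L]] <<- cur_tag
      cur_tok <<- character(); cur_tag <<- character()
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush(); next }
    fields <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (startsWith(fields[[1]], "-DOCSTART-")) next
    if (length(fields) < 2L)
      stop("parse error at line ", i, ": expected 'token tag', got ",
           sQuote(ln))
    tag <- fields[[length(fields)]]
    if (!grepl("^(O|[BI]-.+)$", tag))
      stop("parse error at line ", i, ": unknown tag scheme prefix in ",
           sQuote(tag))
    cur_tok <- c(cur_tok, fields[[1]])
    cur_tag <- c(cur_tag, tag)
  }
  flush()
  spans <- lapply(tagseqs, bio_to_spans, strict = strict)
  mrc_corpus(sentences, spans, labels = declared_labels)
}

#' Write a corpus as CoNLL-style two-column BIO lines
#'
#' Only flat (non-overlapping, non-nested) span sets are representable in a
#' single BIO sequence; a sentence with nested or overlapping spans raises a
#' representation error naming the sentence.
#'
#' @param corpus an `mrc_corpus`.
#' @param path optional file path; when omitted the lines are returned.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_conll <- function(corpus, path = NULL) {
  out <- character()
  for (i in seq_len(n_sentences(corpus))) {
    tags <- tryCatch(
      spans_to_bio(corpus$spans[[i]], length(corpus$sentences[[i]])),
      error = function(e) stop("sentence ", corpus$sentence_ids[i], ": ",
                               conditionMessage(e), call. = FALSE))
    out <- c(out, paste(corpus$sentences[[i]], tags), "")
  }
  if (length(out) > 0L) out <- out[-length(out)]
  if (is.null(path)) return(out)
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Convert a BIO tag sequence to entity spans
#'
#' Maximal runs `B-X (I-X)*` become one span. An `I-X` without a preceding
#' `B-X`/`I-X` of the same label is repaired as a span start (lenient default)
#' or raises when `strict = TRUE`.
#'
#' @param tags character vector of tags in `{O, B-<label>, I-<label>}`.
#' @param strict logical; orphan `I-` handling.
#' @return data.frame of spans (`start`, `end`, `label`; 0-based inclusive).
#' @export
bio_to_spans <- function(tags, strict = FALSE) {
  starts <- integer(); ends <- integer(); labs <- character()
  open_lab <- NULL; open_start <- NA_integer_
  close <- function(i) {
    if (!is.null(open_lab)) {
      starts <<- c(starts, open_start); ends <<- c(ends, i)
      labs <<- c(labs, open_lab); open_lab <<- NULL
    }
  }
  for (i in seq_along(tags)) {
    tg <- tags[[i]]
    if (tg == "O") { close(i - 2L) ; next }
    pre <- substr(tg, 1, 1); lab <- substr(tg, 3, nchar(tg))
    if (pre == "B" || (pre == "I" && (is.null(open_lab) || open_lab != lab))) {
      if (pre == "I") {
        if (strict) stop("orphan I-", lab, " at position ", i)
        warning("orphan I-", lab, " at position ", i, "; repaired as B-", lab,
                call. = FALSE)
      }
      close(i - 2L)
      open_lab <- lab; open_start <- i - 1L
    }
    # I-X continuing an open X: nothing to do
  }
  close(length(tags) - 1L)
  as_span_frame(data.frame(start = starts, end = ends, label = labs,
                           stringsAsFactors = FALSE))
}

#' Convert entity spans to a BIO tag sequence
#'
#' Inverse of [bio_to_spans()] on flat span sets. Overlapping or nested spans
#' cannot share one BIO sequence and raise a representation error.
#'
#' @param spans data.frame with `start`, `end`, `label` (0-based inclusive).
#' @param length token count of the sentence.
#' @return character vector of tags, one per token.
#' @export
spans_to_bio <- function(spans, length) {
  spans <- as_span_frame(spans)
  tags <- rep("O", length)
  covered <- rep(FALSE, length)
  if (nrow(spans) > 0L) {
    for (k in seq_len(nrow(spans))) {
      idx <- (spans$start[k]:spans$end[k]) + 1L
      if (any(idx < 1L | idx > length))
        stop("span (", spans$start[k], ",", spans$end[k], ") out of range")
      if (any(covered[idx]))
        stop("overlapping or nested spans are not representable in BIO: span (",
             spans$start[k], ",", spans$end[k], ",", spans$label[k], ")")
      covered[idx] <- TRUE
      tags[idx] <- c(paste0("B-", spans$label[k]),
                     rep(paste0("I-", spans$label[k]), length(idx) - 1L))
    }
  }
  tags
}

#' Corpus summary statistics
#'
#' Counts sentences, annotations and per-label annotation totals, mirroring
#' the usual dataset-statistics table (annotations / sentences / entity types).
#'
#' @param corpus an `mrc_corpus`.
#' @return list with `sentences`, `annotations`, `entity_types`, `per_label`.
#' @export
corpus_stats <- function(corpus) {
  labs <- unlist(lapply(corpus$spans, function(s) s$label), use.names = FALSE)
  per <- table(factor(labs, levels = corpus$labels))
  list(sentences = n_sentences(corpus),
       annotations = length(labs),
       entity_types = length(corpus$labels),
       per_label = stats::setNames(as.integer(per), names(per)))
}

#' Format corpus statistics as tab-separated text
#' @param corpus an `mrc_corpus`.
#' @return character lines (header + one row).
#' @export
format_corpus_stats <- function(corpus) {
  st <- corpus_stats(corpus)
  c("Annotation\tSentences\tEntity types",
    sprintf("%d\t%d\t%d", st$annotations, st$sentences, st$entity_types))
}
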