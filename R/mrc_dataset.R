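#' Build (Context, Query, Answer) triples from a corpus and query set
#'
#' Every sentence is paired with every entity-type query, including pairs
#' with no entity of that type (the model must learn to return empty
#' answers). The answers of a triple are exactly the corpus annotations of
#' the query's type on that sentence, so the union of answers over triples
#' partitions the corpus annotations by type.
#'
#' @param corpus an `mrc_corpus`.
#' @param qs a `query_set` covering the corpus label set.
#' @return list of `mrc_triple` objects, sentence-major / label-minor order.
#' @export
build_triples <- function(corpus, qs) {
  chk <- validate_query_set(qs, corpus)
  if (!chk$pass)
    stop("query set does not match corpus labels; missing: ",
         paste(chk$missing, collapse = ", "), "; extra: ",
         paste(chk$extra, collapse = ", "))
  out <- vector("list", n_sentences(corpus) * length(corpus$labels))
  k <- 0L
  for (i in seq_len(n_sentences(corpus))) {
    sp <- corpus$spans[[i]]
    for (lab in corpus$labels) {
      k <- k + 1L
      out[[k]] <- structure(list(
        tokens = corpus$sentences[[i]],
        sentence_id = corpus$sentence_ids[[i]],
        sentence_index = i,
        query = qs$specs[[lab]],
        answers = reset_rows(sp[sp$label == lab, , drop = FALSE])),
        class = "mrc_triple")
    }
  }
  out
}

#' Encode a triple as [CLS] query [SEP] context [SEP] with start/end labels
#'
#' Lays the query and context pieces out as `[CLS] q1..qm [SEP] x-pieces
#' [SEP]`, builds binary start/end label vectors (start bit on the first
#' piece of an answer's start word, end bit on the last piece of its end
#' word), and a context mask that confines prediction to context pieces.
#' Contexts longer than `max_len` are split into overlapping windows with
#' stride `stride`; an answer is labeled in every window that contains it
#' wholly, and an answer contained in no window is dropped with a warning
#' (it is still counted against recall at evaluation time).
#'
#' @param triple an `mrc_triple`.
#' @param tok an `mrc_tokenizer`.
#' @param max_len maximum encoded length in pieces (default 512).
#' @param stride window stride in context pieces (default 128).
#' @return list of `encoded_example` objects (length 1 unless windowed).
#' @export
encode_example <- function(triple, tok, max_len = 512L, stride = 128L) {
  qp <- query_pieces(tok, triple$query$text)
  header <- c(tok$cls, qp, tok$sep)
  budget <- max_len - length(header) - 1L   # room for context + trailing SEP
  if (budget < 1L)
    stop("query alone exceeds max_len (", max_len, " pieces)")

  wp <- tokenize_words(tok, triple$tokens)          # pieces per word
  npieces <- vapply(wp, length, integer(1))
  ctx <- unlist(wp, use.names = FALSE)
  n_ctx <- length(ctx)
  # word k (1-based) occupies context-piece offsets first[k]..last[k] (1-based)
  last <- cumsum(npieces)
  first <- last - npieces + 1L

  if (n_ctx > budget && stride > budget)
    stop("stride (", stride, ") must not exceed the window capacity (",
         budget, ") or pieces would be skipped")
  win_starts <- integer(); s <- 1L
  repeat {
    win_starts <- c(win_starts, s)
    if (s + budget - 1L >= n_ctx) break
    s <- s + stride
  }

  ans <- triple$answers
  covered <- if (nrow(ans) > 0L) rep(FALSE, nrow(ans)) else logical()
  out <- list()
  for (w in seq_along(win_starts)) {
    lo <- win_starts[[w]]
    hi <- min(lo + budget - 1L, n_ctx)
    pieces <- c(header, ctx[lo:hi], tok$sep)
    n <- length(pieces)
    off <- length(header)                   # context piece j -> position off + (j - lo) + 1
    pos_of <- function(j) off + (j - lo) + 1L
    context_mask <- integer(n)
    context_mask[(off + 1L):(off + (hi - lo + 1L))] <- 1L

    # words wholly inside this window
    in_win <- which(first >= lo & last <= hi)
    word_map <- lapply(in_win, function(k) c(pos_of(first[k]), pos_of(last[k])))
    names(word_map) <- as.character(in_win - 1L)    # 0-based word index
    word_of_piece <- rep(NA_integer_, n)
    for (k in seq_len(length(npieces))) {
      js <- first[k]:last[k]
      js <- js[js >= lo & js <= hi]
      if (length(js) > 0L) word_of_piece[pos_of(js)] <- k - 1L
    }

    start_labels <- integer(n); end_labels <- integer(n)
    if (nrow(ans) > 0L) {
      for (a in seq_len(nrow(ans))) {
        ws <- ans$start[a] + 1L; we <- ans$end[a] + 1L
        if (first[ws] >= lo && last[we] <= hi) {
          start_labels[pos_of(first[ws])] <- 1L
          end_labels[pos_of(last[we])] <- 1L
          covered[a] <- TRUE
        }
      }
    }
    out[[w]] <- structure(list(
      pieces = pieces, start_labels = start_labels, end_labels = end_labels,
      context_mask = context_mask, word_map = word_map,
      word_of_piece = word_of_piece, n = n,
      sentence_id = triple$sentence_id, sentence_index = triple$sentence_index,
      entity_type = triple$query$entity_type, query_text = triple$query$text,
      window = w, n_windows = length(win_starts),
      gold_answers = ans), class = "encoded_example")
  }
  if (any(!covered))
    warning(sum(!covered), " answer span(s) cross window boundaries in sentence ",
            triple$sentence_id, " and were dropped from the labels",
            call. = FALSE)
  out
}

#' Encode a whole corpus
#'
#' Convenience driver: [build_triples()] then [encode_example()] over all
#' triples, flattening windows. Ordering is deterministic (sentence-major,
#' label-minor, window order).
#'
#' @inheritParams build_triples
#' @inheritParams encode_example
#' @return list of `encoded_example`s.
#' @export
encode_corpus <- function(corpus, qs, tok, max_len = 512L, stride = 128L) {
  triples <- build_triples(corpus, qs)
  unlist(lapply(triples, encode_example, tok = tok, max_len = max_len,
                stride = stride), recursive = FALSE)
}

#' Map predicted piece-space spans back to word space
#'
#' Inverse of the encoding: a predicted span's start piece is snapped to the
#' start of the word containing it and its end piece to the end of that
#' word's piece run, duplicates across overlapping windows are merged, and
#' spans from different queries on the same sentence are unioned (overlap
#' across types is permitted). Predictions at positions outside the context
#' mask are dropped with a warning.
#'
#' @param predictions list parallel to `examples`; each element a data.frame
#'   with piece positions `start`, `end` (1-based), and optionally `score`.
#' @param examples the `encoded_example`s the predictions refer to.
#' @param corpus the source `mrc_corpus` (supplies sentence count/ids).
#' @return list of span data.frames, one per corpus sentence.
#' @export
decode_to_corpus <- function(predictions, examples, corpus) {
  out <- replicate(n_sentences(corpus), empty_spans(), simplify = FALSE)
  for (e in seq_along(examples)) {
    ex <- examples[[e]]
    pr <- predictions[[e]]
    if (is.null(pr) || nrow(pr) == 0L) next
    for (r in seq_len(nrow(pr))) {
      ps <- pr$start[r]; pe <- pr$end[r]
      if (ps < 1L || pe > ex$n || ex$context_mask[ps] != 1L ||
          ex$context_mask[pe] != 1L ||
          is.na(ex$word_of_piece[ps]) || is.na(ex$word_of_piece[pe])) {
        warning("predicted position outside context in example ", e,
                "; dropped", call. = FALSE)
        next
      }
      ws <- ex$word_of_piece[ps]; we <- ex$word_of_piece[pe]
      i <- ex$sentence_index
      out[[i]] <- rbind(out[[i]],
                        data.frame(start = ws, end = we,
                                   label = ex$entity_type,
                                   stringsAsFactors = FALSE))
    }
  }
  lapply(out, function(df) as_span_frame(unique(df)))
}

#' Serialize / restore encoded examples as JSON lines
#'
#' One JSON object per line: pieces, labels, masks, word map and provenance
#' fields. The representation is plain text and round-trips exactly.
#'
#' @param examples list of `encoded_example`s.
#' @param path output (input) file path.
#' @return `read_encoded_dataset` returns the list of examples.
#' @export
write_encoded_dataset <- function(examples, path) {
  lines <- vapply(examples, function(ex) {
    jsonlite::toJSON(ex[c("pieces", "start_labels", "end_labels",
                          "context_mask", "word_map", "word_of_piece", "n",
                          "sentence_id", "sentence_index", "entity_type",
                          "query_text", "window", "n_windows")],
                     auto_unbox = FALSE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_encoded_dataset
#' @export
read_encoded_dataset <- function(path) {
  lapply(readLines(path, warn = FALSE), function(ln) {
    x <- jsonlite::parse_json(ln, simplifyVector = TRUE, simplifyMatrix = FALSE)
    x$word_map <- lapply(x$word_map, as.integer)
    x$word_of_piece <- as.integer(x$word_of_piece)
    x$gold_answers <- empty_spans()
    structure(x, class = "encoded_example")
  })
}
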