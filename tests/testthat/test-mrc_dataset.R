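two_label_corpus <- function() {
  mrc_corpus(list(c("Fish", "contains", "docosahexaenoic", "acids"),
                  c("pure", "TiO2", "films")),
             list(data.frame(start = 2L, end = 3L, label = "CHEM"),
                  data.frame(start = 1L, end = 1L, label = "MAT")),
             labels = c("CHEM", "MAT"))
}

two_label_queries <- function() {
  query_set(list(query_spec("CHEM", "guideline", "find chemical compounds"),
                 query_spec("MAT", "guideline", "find inorganic materials")))
}

test_that("build_triples produces |sentences| x |labels| and partitions gold", {
  cc <- two_label_corpus()
  tri <- build_triples(cc, two_label_queries())
  expect_length(tri, 4L)
  labs <- vapply(tri, function(t) t$query$entity_type, "")
  ids <- vapply(tri, function(t) t$sentence_id, "")
  expect_equal(labs, c("CHEM", "MAT", "CHEM", "MAT"))
  # answers restricted to the query type; negatives kept with empty answers
  expect_equal(tri[[1]]$answers$start, 2L)
  expect_equal(nrow(tri[[2]]$answers), 0L)
  expect_equal(tri[[4]]$answers$start, 1L)
  # union of answers over triples == corpus annotations
  total <- sum(vapply(tri, function(t) nrow(t$answers), 0L))
  expect_equal(total, corpus_stats(cc)$annotations)

  expect_length(build_triples(mrc_corpus(list(), list(), labels = "X"),
                              query_set(list(query_spec("X", "guideline",
                                                        "q")))), 0L)
})

test_that("encode_example places label bits on first/last pieces", {
  cc <- mrc_corpus(list(c("UV-light", "illumination")),
                   list(data.frame(start = 0L, end = 1L, label = "PRO")),
                   labels = "PRO")
  qs <- query_set(list(query_spec("PRO", "guideline", "find properties")))
  tok <- subword_tokenizer(max_piece_chars = 16L)
  ex <- encode_example(build_triples(cc, qs)[[1]], tok)[[1]]
  # layout: [CLS] find properties [SEP] UV - light illumination [SEP]
  expect_identical(ex$pieces,
                   c("[CLS]", "find", "properties", "[SEP]",
                     "UV", "-", "light", "illumination", "[SEP]"))
  expect_equal(which(ex$start_labels == 1L), 5L)   # first piece of "UV-light"
  expect_equal(which(ex$end_labels == 1L), 8L)     # last piece of word 1
  expect_equal(which(ex$context_mask == 1L), 5:8)
  expect_equal(ex$word_map[["0"]], c(5L, 7L))
  expect_equal(ex$word_map[["1"]], c(8L, 8L))

  # empty answers -> all-zero labels
  neg <- build_triples(mrc_corpus(list(c("plain", "words")),
                                  labels = "PRO"), qs)[[1]]
  ex0 <- encode_example(neg, tok)[[1]]
  expect_true(all(ex0$start_labels == 0L) && all(ex0$end_labels == 0L))

  # query alone exceeding max_len is an error
  expect_error(encode_example(build_triples(cc, qs)[[1]], tok, max_len = 4L),
               "max_len")
})

test_that("long contexts split into covering windows and gold survives", {
  n_words <- 600L
  toks <- sprintf("w%03d", seq_len(n_words))
  sp <- data.frame(start = c(10L, 590L), end = c(12L, 592L), label = "MAT")
  cc <- mrc_corpus(list(toks), list(sp), labels = "MAT")
  qs <- query_set(list(query_spec("MAT", "guideline", "find materials")))
  tok <- word_tokenizer()
  exs <- encode_example(build_triples(cc, qs)[[1]], tok, max_len = 512L,
                        stride = 128L)
  expect_gte(length(exs), 2L)
  # context masks jointly cover all 600 pieces
  covered <- logical(n_words)
  for (ex in exs) {
    w <- ex$word_of_piece[ex$context_mask == 1L]
    covered[w + 1L] <- TRUE
  }
  expect_true(all(covered))
  # decode of gold bits reproduces both gold spans despite windowing
  pred <- lapply(exs, function(ex)
    match_spans(which(ex$start_labels == 1L), which(ex$end_labels == 1L),
                ex$entity_type))
  dec <- decode_to_corpus(pred, exs, cc)
  expect_true(span_df_equal(dec[[1]], sp))
})

test_that("boundary-crossing answers are dropped with a warning", {
  toks <- sprintf("w%03d", 1:20)
  sp <- data.frame(start = 9L, end = 12L, label = "MAT")
  cc <- mrc_corpus(list(toks), list(sp), labels = "MAT")
  qs <- query_set(list(query_spec("MAT", "guideline", "q")))
  # budget = 14 - 3 header - 1 = 10 context pieces; stride 10 -> windows
  # [1..10], [11..20]: the span (words 9..12) is whole in neither
  expect_warning(
    exs <- encode_example(build_triples(cc, qs)[[1]],
                          word_tokenizer(), max_len = 14L, stride = 10L),
    "dropped")
  expect_true(all(vapply(exs, function(e) sum(e$start_labels), 0L) == 0L))
})

test_that("decode snaps mid-word pieces outward and de-duplicates", {
  cc <- mrc_corpus(list(c("UV-light", "on", "Si-wafers")), labels = "MAT")
  qs <- query_set(list(query_spec("MAT", "guideline", "q")))
  ex <- encode_example(build_triples(cc, qs)[[1]], subword_tokenizer())[[1]]
  # pieces: [CLS] q [SEP] UV - light on Si - wafers [SEP]
  mid <- ex$word_map[["0"]][1] + 1L   # the "-" piece inside word 0
  pred <- list(data.frame(start = mid, end = mid))
  dec <- decode_to_corpus(pred, list(ex), cc)
  expect_equal(dec[[1]]$start, 0L)
  expect_equal(dec[[1]]$end, 0L)
  # duplicates across examples merge
  p2 <- data.frame(start = rep(ex$word_map[["0"]][1], 2),
                   end = rep(ex$word_map[["0"]][2], 2))
  dec2 <- decode_to_corpus(list(p2), list(ex), cc)
  expect_equal(nrow(dec2[[1]]), 1L)
  # out-of-context prediction dropped with warning
  expect_warning(dec3 <- decode_to_corpus(list(data.frame(start = 1L,
                                                          end = 1L)),
                                          list(ex), cc), "dropped")
  expect_equal(nrow(dec3[[1]]), 0L)
})

test_that("encode/decode of gold is the identity on random one-window corpora", {
  set.seed(99)
  for (rep in 1:15) {
    cc <- random_flat_corpus(n_sentences = 4L)
    qs <- query_set(lapply(cc$labels, function(l)
      query_spec(l, "guideline", paste("find", l))))
    exs <- encode_corpus(cc, qs, word_tokenizer())
    pred <- lapply(exs, function(ex)
      match_spans(which(ex$start_labels == 1L), which(ex$end_labels == 1L),
                  ex$entity_type))
    dec <- decode_to_corpus(pred, exs, cc)
    for (i in seq_len(n_sentences(cc)))
      expect_true(span_df_equal(dec[[i]], cc$spans[[i]]))
  }
})

test_that("nested same-start spans survive the triple representation", {
  nf <- generate_nested_case()
  qs <- query_set(list(query_spec("MAT", "guideline", "find materials"),
                       query_spec("DSC", "guideline", "find descriptions")))
  tri <- build_triples(nf, qs)
  answers <- do.call(rbind, lapply(tri, `[[`, "answers"))
  expect_true(span_df_equal(answers, nf$spans[[1]]))
  expect_error(spans_to_bio(nf$spans[[1]], 11L), "not representable")
})

test_that("encoded datasets round-trip through JSON lines", {
  cc <- two_label_corpus()
  exs <- encode_corpus(cc, two_label_queries(), word_tokenizer())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_encoded_dataset(exs, path)
  back <- read_encoded_dataset(path)
  expect_length(back, length(exs))
  for (k in seq_along(exs)) {
    expect_identical(back[[k]]$pieces, exs[[k]]$pieces)
    expect_equal(back[[k]]$start_labels, exs[[k]]$start_labels)
    expect_equal(back[[k]]$end_labels, exs[[k]]$end_labels)
    expect_equal(back[[k]]$context_mask, exs[[k]]$context_mask)
    expect_equal(unname(unlist(back[[k]]$word_map)),
                 unname(unlist(exs[[k]]$word_map)))
  }
})
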