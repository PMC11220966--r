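# plain independent softmax for expected values
soft2 <- function(x) { e <- exp(x - max(x)); e / sum(e) }

test_that("predict_start is the row-softmax of L Q_start", {
  p <- head_params(2L, mode = "base", init = "zero")
  p$Q_start <- diag(2)
  K <- predict_start(matrix(c(1, 0), 1, 2), p)
  expect_equal(K[1, ], soft2(c(1, 0)), tolerance = 1e-12)
  expect_equal(unname(K[1, 1]), 0.7311, tolerance = 1e-4)

  # zero weights -> uniform rows
  pz <- head_params(5L, mode = "base", init = "zero")
  L <- matrix(rnorm(20), 4, 5)
  expect_true(all(abs(predict_start(L, pz) - 0.5) < 1e-12))

  # empty context
  expect_equal(nrow(predict_start(matrix(0, 0, 5), pz)), 0L)
  expect_error(predict_start(matrix(0, 2, 3), pz), "shape")
})

test_that("conditioned head with zeroed conditioning rows equals base head", {
  set.seed(7)
  d <- 6L
  L <- matrix(rnorm(5 * d), 5, d)
  base <- head_params(d, mode = "base")
  cond <- head_params(d, mode = "conditioned", init = "zero")
  cond$Q_end[seq_len(d), ] <- base$Q_end
  cond$Q_end[d + 1:2, ] <- 0
  K_start <- predict_start(L, base)
  expect_equal(predict_end(L, K_start, params = cond),
               predict_end(L, params = base),
               tolerance = 1e-12)
  expect_error(predict_end(L, params = cond), "K_start")
})

test_that("conditioned end head matches a hand-computed softmax", {
  # d=2, L row (0,1), start probs (0.7311, 0.2689), hand-set Q_end
  p <- head_params(2L, mode = "conditioned", init = "zero")
  p$Q_end <- matrix(c(1, 0, 0.5, -0.5,
                      0, 1, -0.5, 0.5), nrow = 4)
  L <- matrix(c(0, 1), 1, 2)
  Ks <- matrix(soft2(c(1, 0)), 1, 2)
  expected <- soft2(as.numeric(c(0, 1, Ks) %*% p$Q_end))
  got <- predict_end(L, Ks, params = p)
  expect_equal(as.numeric(got), expected, tolerance = 1e-12)
})

test_that("score matrices are row-stochastic on random inputs", {
  set.seed(31)
  for (rep in 1:20) {
    d <- sample(2:10, 1)
    L <- matrix(rnorm(8 * d, sd = 3), 8, d)
    hp <- head_params(d, mode = "conditioned")
    Ks <- predict_start(L, hp)
    Ke <- predict_end(L, Ks, params = hp)
    expect_true(all(abs(rowSums(Ks) - 1) < 1e-6))
    expect_true(all(abs(rowSums(Ke) - 1) < 1e-6))
    expect_true(all(Ks >= 0 & Ks <= 1))
  }
})

test_that("extract_index_set matches a brute-force argmax oracle", {
  expect_equal(extract_index_set(
    matrix(c(0.3, 0.6, 0.1, 0.7, 0.4, 0.9), 3, 2), rep(1L, 3)),
    c(1L, 3L))
  expect_length(extract_index_set(matrix(c(0.9, 0.1), 1, 2), 1L), 0L)
  # exact ties resolve to class 0
  expect_length(extract_index_set(matrix(0.5, 4, 2), rep(1L, 4)), 0L)

  set.seed(77)
  for (rep in 1:50) {
    n <- sample(1:30, 1)
    p1 <- runif(n)
    K <- cbind(1 - p1, p1)
    mask <- sample(0:1, n, replace = TRUE)
    oracle <- sort(which(vapply(seq_len(n), function(i)
      mask[i] == 1L && which.max(K[i, ]) == 2L, logical(1))))
    expect_equal(extract_index_set(K, mask), oracle)
  }
})

test_that("match_spans pairs each end with its nearest preceding start", {
  m <- match_spans(c(2L, 8L), c(4L, 9L), "MAT")
  expect_equal(m$start, c(2L, 8L))
  expect_equal(m$end, c(4L, 9L))
  # nested pair sharing a start
  m2 <- match_spans(2L, c(3L, 4L), "MAT")
  expect_equal(m2$start, c(2L, 2L))
  expect_equal(m2$end, c(3L, 4L))
  # start with no end is dropped
  expect_equal(nrow(match_spans(5L, integer(), "MAT")), 0L)
  # end before every start is dropped
  expect_equal(nrow(match_spans(5L, 3L, "MAT")), 0L)
  # scores are products of endpoint class-1 probabilities
  Ks <- cbind(1:9 * 0, 1:9 / 10); Ke <- Ks
  m3 <- match_spans(c(2L), c(4L), "MAT", Ks, Ke)
  expect_equal(m3$score, 0.2 * 0.4)
  expect_true(all(m3$start <= m3$end))
})

test_that("oracle-encoder forward reproduces gold and masks the query", {
  set.seed(12)
  cc <- random_flat_corpus(n_sentences = 6L)
  qs <- query_set(lapply(cc$labels, function(l)
    query_spec(l, "guideline", paste("find every", l, "mention"))))
  exs <- encode_corpus(cc, qs, word_tokenizer())
  enc <- oracle_encoder()
  for (mode in c("conditioned", "base")) {
    hp <- oracle_heads(mode)
    pred <- lapply(exs, function(ex) {
      fw <- forward(ex, enc, hp)
      # nothing emitted at query or special-token positions
      expect_true(all(ex$context_mask[fw$spans$start] == 1L))
      expect_true(all(ex$context_mask[fw$spans$end] == 1L))
      fw$spans
    })
    dec <- decode_to_corpus(pred, exs, cc)
    for (i in seq_len(n_sentences(cc)))
      expect_true(span_df_equal(dec[[i]], cc$spans[[i]]))
  }
  # empty-answer example yields no spans
  neg <- exs[[which(vapply(exs, function(e) sum(e$start_labels), 0L) == 0L)[1]]]
  expect_equal(nrow(forward(neg, enc, oracle_heads())$spans), 0L)
})

test_that("checkpoints round-trip model state exactly", {
  cc <- generate_corpus(synth_config(n_sentences = 12L, seed = 2L))
  qs <- synth_query_set(cc$labels)
  exs <- encode_corpus(cc, qs, word_tokenizer())
  vocab <- build_vocab(exs)
  enc <- tiny_encoder(vocab, d = 8L, seed = 4L)
  state <- train_model(exs, enc, train_config(epochs = 1L, seed = 9L))
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(state, path)
  back <- read_checkpoint(path)
  expect_identical(back$vocab, state$vocab)
  expect_equal(back$head$Q_start, state$head$Q_start, tolerance = 0)
  expect_equal(back$encoder_params$E, state$encoder_params$E, tolerance = 0)
  expect_equal(back$encoder_params$b, state$encoder_params$b, tolerance = 0)
  # restored state predicts identically
  p1 <- predict_corpus(cc, qs, state)
  state2 <- state; state2$head <- back$head
  state2$encoder_params <- back$encoder_params; state2$vocab <- back$vocab
  p2 <- predict_corpus(cc, qs, state2)
  for (i in seq_along(p1)) expect_true(span_df_equal(p1[[i]], p2[[i]]))
})
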