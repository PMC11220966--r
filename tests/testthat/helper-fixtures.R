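# Shared fixtures and independent oracles. Oracles here are deliberately
# naive re-implementations, kept independent of the package internals they
# check.

# random flat (non-overlapping) span set over a sentence of `len` tokens
random_flat_spans <- function(len, labels, max_spans = 3L) {
  free <- rep(TRUE, len)
  out <- data.frame(start = integer(), end = integer(), label = character(),
                    stringsAsFactors = FALSE)
  for (k in seq_len(sample.int(max_spans + 1L, 1L) - 1L)) {
    l <- sample.int(min(3L, len), 1L)
    s <- sample.int(len - l + 1L, 1L)
    if (all(free[s:(s + l - 1L)])) {
      free[s:(s + l - 1L)] <- FALSE
      out <- rbind(out, data.frame(start = s - 1L, end = s + l - 2L,
                                   label = sample(labels, 1L),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

random_flat_corpus <- function(n_sentences = 5L,
                               labels = c("MAT", "PRO"),
                               max_len = 12L) {
  sentences <- list(); spans <- list()
  for (i in seq_len(n_sentences)) {
    len <- sample(3:max_len, 1L)
    sentences[[i]] <- sprintf("tok%02d", sample.int(30L, len, replace = TRUE))
    spans[[i]] <- random_flat_spans(len, labels)
  }
  mrc_corpus(sentences, spans, labels = labels)
}

# brute-force run-length BIO scanner (independent of bio_to_spans)
scan_bio_runs <- function(tags) {
  out <- data.frame(start = integer(), end = integer(), label = character(),
                    stringsAsFactors = FALSE)
  i <- 1L
  while (i <= length(tags)) {
    if (tags[i] == "O") { i <- i + 1L; next }
    lab <- sub("^[BI]-", "", tags[i])
    j <- i
    while (j < length(tags) && tags[j + 1L] == paste0("I-", lab)) j <- j + 1L
    out <- rbind(out, data.frame(start = i - 1L, end = j - 1L, label = lab,
                                 stringsAsFactors = FALSE))
    i <- j + 1L
  }
  out
}

# independent exact-match scorer via multiset key intersection
oracle_counts <- function(pred, gold) {
  keys <- function(lst) unlist(lapply(seq_along(lst), function(i) {
    df <- lst[[i]]
    if (is.null(df) || nrow(df) == 0L) return(character())
    paste(i, df$start, df$end, df$label, sep = ":")
  }), use.names = FALSE)
  pk <- keys(pred); gk <- keys(gold)
  tp <- 0L
  gpool <- gk
  for (k in pk) {
    hit <- match(k, gpool)
    if (!is.na(hit)) { tp <- tp + 1L; gpool <- gpool[-hit] }
  }
  list(TP = tp, FP = length(pk) - tp, FN = length(gk) - tp)
}

span_df_equal <- function(a, b) {
  key <- function(df) sort(paste(df$start, df$end, df$label, sep = "|"))
  identical(key(a), key(b))
}

# a small experiment config for fast end-to-end runs
quick_experiment <- function(n_sentences = 60L, epochs = 4L, runs = 1L,
                             seed = 42L, synth_seed = 21L, ...) {
  experiment_config(
    train_config = train_config(epochs = epochs, runs = runs, seed = seed),
    synth = synth_config(n_sentences = n_sentences, seed = synth_seed),
    ...)
}
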