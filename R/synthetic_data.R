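#' Synthetic-corpus configuration
#'
#' The generator emulates a tagged NER corpus with lexically separable
#' entity types: every entity type has its own token vocabulary, disjoint
#' from the background vocabulary and from every other type, so a capable
#' model can in principle reach perfect F1 (a token-lexicon oracle attains
#' it by construction). Defaults give 500 sentences of 6-12 tokens, four
#' entity types, about 1.5 entities per sentence of 1-3 words, no nesting.
#'
#' @param n_sentences number of sentences.
#' @param sentence_length integer range `c(min, max)` in tokens.
#' @param entity_types character vector of type names.
#' @param vocab_per_type tokens in each type vocabulary.
#' @param background_vocab tokens in the background vocabulary.
#' @param entity_density expected entities per sentence (Poisson, capped by
#'   available room).
#' @param entity_length integer range `c(min, max)` in words.
#' @param nesting_prob probability that an entity of length >= 2 receives a
#'   nested inner entity of a different type (sharing its start word).
#' @param seed RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_sentences = 500L, sentence_length = c(6L, 12L),
                         entity_types = c("MAT", "PRO", "SMT", "DSC"),
                         vocab_per_type = 12L, background_vocab = 60L,
                         entity_density = 1.5, entity_length = c(1L, 3L),
                         nesting_prob = 0, seed = 13L) {
  stopifnot(n_sentences >= 0, all(sentence_length > 0),
            sentence_length[1] <= sentence_length[2],
            length(entity_types) > 0, vocab_per_type > 0,
            background_vocab > 0, entity_density >= 0,
            all(entity_length > 0), entity_length[1] <= entity_length[2],
            nesting_prob >= 0, nesting_prob <= 1)
  structure(list(n_sentences = as.integer(n_sentences),
                 sentence_length = as.integer(sentence_length),
                 entity_types = entity_types,
                 vocab_per_type = as.integer(vocab_per_type),
                 background_vocab = as.integer(background_vocab),
                 entity_density = entity_density,
                 entity_length = as.integer(entity_length),
                 nesting_prob = nesting_prob, seed = as.integer(seed)),
            class = "synth_config")
}

synth_vocabularies <- function(cfg) {
  type_vocab <- lapply(cfg$entity_types, function(ty)
    sprintf("%s_w%02d", tolower(ty), seq_len(cfg$vocab_per_type)))
  names(type_vocab) <- cfg$entity_types
  bg <- sprintf("bg_w%02d", seq_len(cfg$background_vocab))
  all_ent <- unlist(type_vocab, use.names = FALSE)
  if (length(intersect(all_ent, bg)) > 0L ||
      anyDuplicated(all_ent) > 0L)
    stop("vocabularies must be pairwise disjoint")
  list(types = type_vocab, background = bg)
}

#' Generate a labeled corpus
#'
#' Deterministic under `cfg$seed`. Background tokens are drawn from the
#' background vocabulary; each entity replaces a run of tokens with draws
#' from its type vocabulary. Entities never overlap each other except for
#' deliberately nested inner spans (enabled via `nesting_prob`), which are
#' annotation-level: an inner sub-span of an entity, sharing its start word
#' and labeled with a different type.
#'
#' @param cfg a [synth_config()].
#' @return an `mrc_corpus`.
#' @export
generate_corpus <- function(cfg = synth_config()) {
  voc <- synth_vocabularies(cfg)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  sentences <- vector("list", cfg$n_sentences)
  spans <- vector("list", cfg$n_sentences)
  ntypes <- length(cfg$entity_types)
  for (i in seq_len(cfg$n_sentences)) {
    len <- sample(cfg$sentence_length[1]:cfg$sentence_length[2], 1L)
    toks <- sample(voc$background, len, replace = TRUE)
    free <- rep(TRUE, len)
    k <- stats::rpois(1, cfg$entity_density)
    sp <- empty_spans()
    tries <- 0L
    while (k > 0L && tries < 50L) {
      tries <- tries + 1L
      el <- sample(cfg$entity_length[1]:cfg$entity_length[2], 1L)
      if (el > len) next
      s0 <- sample(seq_len(len - el + 1L), 1L)
      idx <- s0:(s0 + el - 1L)
      # a background-token buffer separates entities: two adjacent same-type
      # entities would be indistinguishable from one longer entity (and the
      # lexicon oracle would merge them), so adjacency is never generated
      buf <- max(1L, s0 - 1L):min(len, s0 + el)
      if (!all(free[buf])) next
      ty <- cfg$entity_types[[sample.int(ntypes, 1L)]]
      toks[idx] <- sample(voc$types[[ty]], el, replace = TRUE)
      free[idx] <- FALSE
      sp <- rbind(sp, data.frame(start = s0 - 1L, end = s0 + el - 2L,
                                 label = ty, stringsAsFactors = FALSE))
      # optional nested inner span: shares the start word, different label
      if (el >= 2L && cfg$nesting_prob > 0 &&
          stats::runif(1) < cfg$nesting_prob) {
        il <- sample.int(el - 1L, 1L)
        ity <- sample(setdiff(cfg$entity_types, ty), 1L)
        sp <- rbind(sp, data.frame(start = s0 - 1L,
                                   end = s0 + il - 2L,
                                   label = ity, stringsAsFactors = FALSE))
      }
      k <- k - 1L
    }
    sentences[[i]] <- toks
    spans[[i]] <- sp
  }
  mrc_corpus(sentences, spans, labels = cfg$entity_types)
}

#' Fixed nested-entity fixture
#'
#' A single sentence whose gold annotation contains an outer span and an
#' inner span sharing the start word ("BWT-Pt" nested inside "BWT-Pt
#' catalysts"), with distinct labels — the shape a single BIO sequence
#' cannot represent but the (Context, Query, Answer) representation holds
#' without loss.
#'
#' @return an `mrc_corpus` with one sentence and two nested gold spans.
#' @export
generate_nested_case <- function() {
  toks <- c("The", "prepared", "BWT-Pt", "catalysts", "were", "used", "for",
            "aerobic", "oxidation", "of", "alcohols")
  sp <- data.frame(start = c(2L, 2L), end = c(2L, 3L),
                   label = c("MAT", "DSC"), stringsAsFactors = FALSE)
  mrc_corpus(list(toks), list(sp), labels = c("MAT", "DSC"),
             sentence_ids = "nested_fixture")
}

#' Token-lexicon oracle annotator
#'
#' Labels every maximal run of type-vocabulary tokens with its type. On flat
#' corpora produced by [generate_corpus()] this attains F1 = 1 by
#' construction (vocabulary disjointness) — the ceiling a trained model is
#' measured against.
#'
#' @param corpus an `mrc_corpus`.
#' @param cfg the [synth_config()] that generated it.
#' @return list of span data.frames, one per sentence.
#' @export
lexicon_oracle <- function(corpus, cfg) {
  voc <- synth_vocabularies(cfg)
  lapply(corpus$sentences, function(toks) {
    ty_of <- rep(NA_character_, length(toks))
    for (ty in names(voc$types))
      ty_of[toks %in% voc$types[[ty]]] <- ty
    sp <- empty_spans()
    i <- 1L
    while (i <= length(toks)) {
      if (!is.na(ty_of[i])) {
        j <- i
        while (j < length(toks) && !is.na(ty_of[j + 1L]) &&
               ty_of[j + 1L] == ty_of[i]) j <- j + 1L
        sp <- rbind(sp, data.frame(start = i - 1L, end = j - 1L,
                                   label = ty_of[i],
                                   stringsAsFactors = FALSE))
        i <- j + 1L
      } else i <- i + 1L
    }
    sp
  })
}

#' Query sets for synthetic corpora
#'
#' Deterministic per-type lexicon (keywords, template, definition, synonyms,
#' guideline text) for the synthetic entity types, so every construction
#' strategy can be exercised without external resources.
#'
#' @param entity_types type names.
#' @return named list: per-type lexicon lists for [build_query()].
#' @export
synth_query_lexicon <- function(entity_types) {
  lex <- lapply(entity_types, function(ty) {
    low <- tolower(ty)
    list(keywords = paste0(low, " entity"),
         template = "Which <kw> is mentioned in the text?",
         wikipedia = paste0("A ", low, " entity is a token drawn from the ",
                            low, " vocabulary"),
         synonyms = c(paste0(low, " mention"), paste0(low, " term")),
         guideline = paste0("Look up any word of the ", low,
                            " vocabulary in the sentence"))
  })
  names(lex) <- entity_types
  lex
}

#' Build a synthetic query set under one strategy
#'
#' @param entity_types type names.
#' @param strategy one of the six construction strategies.
#' @return a `query_set`.
#' @export
synth_query_set <- function(entity_types, strategy = "guideline") {
  lex <- synth_query_lexicon(entity_types)
  query_set(lapply(entity_types, function(ty)
    build_query(ty, strategy, lex[[ty]])),
    name = paste0("synth_", strategy))
}

#' Write / read a structured-text span file (for nested corpora)
#'
#' One JSON object per line: `sentence_id`, `tokens`, `spans`. Unlike BIO,
#' this representation holds nested and overlapping spans.
#'
#' @param corpus an `mrc_corpus`.
#' @param path file path.
#' @return `read_span_file` returns an `mrc_corpus`.
#' @export
write_span_file <- function(corpus, path) {
  lines <- vapply(seq_len(n_sentences(corpus)), function(i)
    as.character(jsonlite::toJSON(list(
      sentence_id = corpus$sentence_ids[[i]],
      tokens = corpus$sentences[[i]],
      spans = corpus$spans[[i]]), auto_unbox = FALSE, dataframe = "columns")),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_span_file
#' @export
read_span_file <- function(path) {
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::parse_json,
                 simplifyVector = TRUE)
  mrc_corpus(sentences = lapply(recs, function(r) as.character(r$tokens)),
             spans = lapply(recs, function(r) {
               s <- r$spans
               if (length(s) == 0L || length(s$start) == 0L) empty_spans()
               else data.frame(start = as.integer(s$start),
                               end = as.integer(s$end),
                               label = as.character(s$label),
                               stringsAsFactors = FALSE)
             }),
             sentence_ids = vapply(recs, function(r)
               as.character(r$sentence_id), character(1)))
}
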