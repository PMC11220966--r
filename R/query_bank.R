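QUERY_STRATEGIES <- c("keywords", "template", "wikipedia", "synonyms",
                      "keywords_synonyms", "guideline")

#' Construct a query specification
#'
#' A query spec pairs an entity type with the natural-language query sentence
#' Q_y used to retrieve spans of that type, plus the construction strategy it
#' came from.
#'
#' @param entity_type label name.
#' @param strategy one of `"keywords"`, `"template"`, `"wikipedia"`,
#'   `"synonyms"`, `"keywords_synonyms"`, `"guideline"`.
#' @param text the query sentence; must be non-empty.
#' @return object of class `query_spec`.
#' @export
query_spec <- function(entity_type, strategy, text) {
  strategy <- match.arg(strategy, QUERY_STRATEGIES)
  if (!nzchar(text)) stop("query text for ", entity_type, " must be non-empty")
  structure(list(entity_type = as.character(entity_type),
                 strategy = strategy, text = as.character(text)),
            class = "query_spec")
}

#' Construct a query set
#'
#' One query spec per entity type, order-preserving.
#'
#' @param specs list of `query_spec` objects.
#' @param name identifier for the set.
#' @return object of class `query_set` (named list of specs).
#' @export
query_set <- function(specs, name = "query_set") {
  labs <- vapply(specs, function(s) s$entity_type, character(1))
  dup <- labs[duplicated(labs)]
  if (length(dup) > 0L)
    stop("duplicate query for label(s): ", paste(unique(dup), collapse = ", "))
  names(specs) <- labs
  structure(list(specs = specs, name = name), class = "query_set")
}

#' @export
print.query_set <- function(x, ...) {
  cat(sprintf("<query_set '%s'> %d entity types\n", x$name, length(x$specs)))
  for (s in x$specs)
    cat(sprintf("  %-6s [%s] %s\n", s$entity_type, s$strategy, s$text))
  invisible(x)
}

#' Load a query set from a JSON config
#'
#' The config is a JSON object `{"name": ..., "queries": {label: {"strategy":
#' ..., "text": ...}, ...}}`. When `labels` is supplied the set is checked for
#' completeness against it.
#'
#' @param path file path, or raw JSON text via `text =`.
#' @param text JSON string (alternative to `path`).
#' @param labels optional label set the config must cover exactly once each.
#' @return a `query_set`.
#' @export
load_query_set <- function(path = NULL, text = NULL, labels = NULL) {
  cfg <- if (is.null(text)) jsonlite::read_json(path) else
    jsonlite::parse_json(text)
  qmap <- cfg$queries
  if (is.null(qmap)) stop("config has no 'queries' field")
  if (anyDuplicated(names(qmap)))
    stop("duplicate label in query config: ",
         paste(unique(names(qmap)[duplicated(names(qmap))]), collapse = ", "))
  specs <- lapply(names(qmap), function(lab)
    query_spec(lab, qmap[[lab]]$strategy %||% "guideline", qmap[[lab]]$text))
  qs <- query_set(specs, name = cfg$name %||% "query_set")
  if (!is.null(labels)) {
    missing <- setdiff(labels, names(qs$specs))
    if (length(missing) > 0L)
      stop("query set incomplete; missing label(s): ",
           paste(missing, collapse = ", "))
  }
  qs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build one query under a named construction strategy
#'
#' Deterministic text assembly from locally supplied lexicon resources; no
#' network retrieval. Strategies: `keywords` uses the keyword phrase itself;
#' `template` fills a `<kw>` slot in a template; `wikipedia` uses a provided
#' definition sentence; `synonyms` joins provided synonyms; `keywords_synonyms`
#' joins the keyword with its synonyms; `guideline` returns the
#' annotation-guideline text verbatim.
#'
#' @param entity_type label name.
#' @param strategy strategy name (see above).
#' @param lexicon list with per-strategy raw material: `keywords` (character),
#'   `template` (string containing `<kw>`), `wikipedia` (string), `synonyms`
#'   (character), `guideline` (string).
#' @return a `query_spec`.
#' @export
build_query <- function(entity_type, strategy, lexicon) {
  strategy <- match.arg(strategy, QUERY_STRATEGIES)
  need <- function(field) {
    v <- lexicon[[field]]
    if (is.null(v) || length(v) == 0L || all(!nzchar(v)))
      stop("lexicon entry '", field, "' required for strategy '", strategy,
           "' is empty")
    v
  }
  text <- switch(strategy,
    keywords = paste(need("keywords"), collapse = ", "),
    template = {
      tpl <- need("template")
      kw <- paste(need("keywords"), collapse = ", ")
      if (!grepl("<kw>", tpl, fixed = TRUE))
        stop("template must contain a '<kw>' slot")
      gsub("<kw>", kw, tpl, fixed = TRUE)
    },
    wikipedia = need("wikipedia"),
    synonyms = paste(need("synonyms"), collapse = ", "),
    keywords_synonyms = paste(c(need("keywords"), need("synonyms")),
                              collapse = ", "),
    guideline = need("guideline"))
  query_spec(entity_type, strategy, text)
}

#' Validate a query set against a corpus
#'
#' Report-only check that the query set and the corpus label set are in
#' bijection.
#'
#' @param qs a `query_set`.
#' @param corpus an `mrc_corpus`.
#' @return list with `pass`, `missing` (labels lacking queries), `extra`
#'   (queries for absent labels).
#' @export
validate_query_set <- function(qs, corpus) {
  have <- names(qs$specs)
  want <- corpus$labels
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  list(pass = length(missing) == 0L && length(extra) == 0L,
       missing = missing, extra = extra)
}

#' Default query sets shipped with the package
#'
#' `"matscholar_guideline"` covers the seven Matscholar entity types with
#' annotation-guideline queries; `"chem_guideline"` is a single-label set for
#' chemical-NER-shaped corpora (one CHEM type).
#'
#' @param which set name.
#' @return a `query_set`.
#' @export
default_query_set <- function(which = c("matscholar_guideline",
                                        "chem_guideline")) {
  which <- match.arg(which)
  path <- system.file("extdata", "queries", paste0(which, ".json"),
                      package = "mrcner", mustWork = TRUE)
  load_query_set(path)
}
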