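Package: mrcner
Title: Query-Based Machine Reading Comprehension for Named Entity Recognition
Version: 0.1.0
Authors@R:
    person("mrcner", "developers", email = "mrcner@example.org", role = c("aut", "cre"))
Description: Reformulates token-tagged named-entity-recognition corpora from
    materials-science and chemical text as (Context, Query, Answer) triples
    and extracts entity spans with paired start/end binary classifiers over an
    encoder representation. Supports nested entities, six query-construction
    strategies, class-imbalance-aware losses (focal, cross-entropy, label
    smoothing), entity-level exact-match evaluation, a seeded synthetic-corpus
    generator, and a command-line driver for reproducible ablation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
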