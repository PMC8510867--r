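Package: relra
Title: Literature-Based Recommendation of Biomedical Entities over a
    Relation Graph
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for turning collections of scientific abstracts into
    implicit-feedback recommendation datasets and for recommending biomedical
    entities to authors.  Provides dictionary-based entity recognition and
    linking against ontology lexicons (DeCS/DO/GO/HPO/ChEBI-shaped), a
    builder that derives <user,item,rating> triples in which users are
    authors, items are recognized entities and ratings count the articles an
    author wrote mentioning an entity, the RelRA content-based recommender
    that scores an unrated item by the fraction of a user's liked items it is
    related to in an entity relation graph, a random baseline, and a top-k
    evaluation protocol (Precision, Recall, MRR) with per-user train/test
    splitting.  A synthetic corpus generator with planted author-topic
    structure makes the whole pipeline testable offline, and readers/writers
    cover PubAnnotation JSON and tab-separated document, lexicon, relation
    and ratings tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
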