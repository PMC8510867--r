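#' Specification for a synthetic literature corpus
#'
#' Describes a corpus with planted author-topic structure: every author has a
#' preferred topic, every entity belongs to one topic, documents mostly
#' mention entities from their primary author's topic, and relations are
#' denser within topics than between them.  The generator stands in for a
#' real abstract collection so the whole annotation-to-recommendation
#' pipeline can be exercised offline.
#'
#' @param n_authors,n_docs,n_topics,entities_per_topic Positive integers.
#' @param authors_per_doc,entities_per_doc Integer ranges `c(min, max)`:
#'   authors per document and entity mentions per document.
#' @param topic_affinity Probability that a document's entity draw (and each
#'   co-author) comes from the primary author's preferred topic rather than
#'   uniformly from the whole pool.
#' @param intra_topic_edge_prob,inter_topic_edge_prob Probability of a
#'   relation edge between two entities of the same / of different topics.
#'   Planted-structure runs need `intra_topic_edge_prob >=
#'   inter_topic_edge_prob`.
#' @param languages ISO 639-1 codes cycled over the documents.
#' @param seed Integer seed driving all randomness in [generate_corpus()].
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_authors = 25, n_docs = 120, n_topics = 5,
                           entities_per_topic = 25,
                           authors_per_doc = c(1, 2),
                           entities_per_doc = c(6, 10),
                           topic_affinity = 0.9,
                           intra_topic_edge_prob = 0.35,
                           inter_topic_edge_prob = 0.02,
                           languages = c("en", "pt"),
                           seed = 1L) {
  n_authors <- assert_count(n_authors, "n_authors")
  n_docs <- assert_count(n_docs, "n_docs")
  n_topics <- assert_count(n_topics, "n_topics")
  entities_per_topic <- assert_count(entities_per_topic, "entities_per_topic")
  for (rng_name in c("authors_per_doc", "entities_per_doc")) {
    rng <- get(rng_name)
    if (length(rng) != 2L || any(rng < 1L) || rng[1L] > rng[2L] ||
        any(rng != as.integer(rng))) {
      abort(paste0("`", rng_name, "` must be an integer range c(min, max) ",
                   "with 1 <= min <= max."))
    }
  }
  assert_fraction(topic_affinity, "topic_affinity", open = FALSE)
  assert_fraction(intra_topic_edge_prob, "intra_topic_edge_prob",
                  open = FALSE)
  assert_fraction(inter_topic_edge_prob, "inter_topic_edge_prob",
                  open = FALSE)
  if (intra_topic_edge_prob < inter_topic_edge_prob) {
    warn(paste0(
      "intra_topic_edge_prob < inter_topic_edge_prob: the corpus will not ",
      "carry planted topic structure."
    ))
  }
  if (entities_per_doc[2L] > n_topics * entities_per_topic) {
    abort("`entities_per_doc` exceeds the number of available entities.")
  }
  if (!all(stringi::stri_detect_regex(languages, "^[a-z]{2}$"))) {
    abort("`languages` must be 2-letter lowercase ISO 639-1 codes.")
  }
  structure(
    list(
      n_authors = n_authors, n_docs = n_docs, n_topics = n_topics,
      entities_per_topic = entities_per_topic,
      authors_per_doc = as.integer(authors_per_doc),
      entities_per_doc = as.integer(entities_per_doc),
      topic_affinity = topic_affinity,
      intra_topic_edge_prob = intra_topic_edge_prob,
      inter_topic_edge_prob = inter_topic_edge_prob,
      languages = languages,
      seed = assert_count(seed, "seed", min = 0L)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic annotated corpus with planted structure
#'
#' Emits every input the pipeline consumes — documents, a lexicon, gold
#' entity annotations, a relation list — together with the ground truth that
#' produced them.  Abstracts are synthetic token streams: planted surface
#' terms separated by filler tokens that never collide with lexicon entries,
#' so a dictionary matcher recovers exactly the planted spans.  Lexicon
#' terms include single-token, multi-word and diacritic-bearing forms to
#' exercise the matcher's edge cases.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_corpus` with elements `documents`,
#'   `lexicon`, `annotations`, `relations` (edge tibble) and `ground_truth`
#'   (author topics, entity topics, planted occurrences, true edges).  All
#'   randomness is driven by `spec$seed`; the same spec yields an identical
#'   corpus.
#' @seealso [write_corpus()], [annotate_documents()], [build_ratings()]
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be created with synthetic_spec().")
  }
  withr::with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  n_entities <- spec$n_topics * spec$entities_per_topic
  entity_topic <- rep(seq_len(spec$n_topics), each = spec$entities_per_topic)
  onts <- c("DOID", "CHEBI", "GO", "HP")
  entity_id <- sprintf("%s_%06d",
                       onts[(seq_len(n_entities) - 1L) %% length(onts) + 1L],
                       7000L + seq_len(n_entities))
  uid <- sprintf("ent%04dx", seq_len(n_entities))
  form <- (seq_len(n_entities) - 1L) %% 3L
  term <- ifelse(form == 0L, uid,
                 ifelse(form == 1L, paste("síndrome", uid),
                        paste(uid, "aguda")))
  lexicon <- tibble(term = term, entity_id = entity_id)

  authors <- sprintf("author_%03d", seq_len(spec$n_authors))
  author_topic <- rep_len(seq_len(spec$n_topics), spec$n_authors)

  fillers <- sprintf("zz%02d", 1:24)
  doc_ids <- sprintf("doc%04d", seq_len(spec$n_docs))
  documents <- vector("list", spec$n_docs)
  planted <- vector("list", spec$n_docs)

  for (d in seq_len(spec$n_docs)) {
    primary <- sample.int(spec$n_authors, 1L)
    topic <- author_topic[[primary]]
    n_auth <- sample(seq(spec$authors_per_doc[1L], spec$authors_per_doc[2L]),
                     1L)
    doc_authors <- primary
    while (length(doc_authors) < n_auth) {
      pool <- if (stats::runif(1L) < spec$topic_affinity) {
        setdiff(which(author_topic == topic), doc_authors)
      } else {
        setdiff(seq_len(spec$n_authors), doc_authors)
      }
      if (length(pool) == 0L) {
        pool <- setdiff(seq_len(spec$n_authors), doc_authors)
      }
      if (length(pool) == 0L) break
      doc_authors <- c(doc_authors, pool[sample.int(length(pool), 1L)])
    }

    n_ent <- sample(seq(spec$entities_per_doc[1L], spec$entities_per_doc[2L]),
                    1L)
    from_topic <- stats::runif(n_ent) < spec$topic_affinity
    ent_draw <- integer(n_ent)
    topic_pool <- which(entity_topic == topic)
    for (j in seq_len(n_ent)) {
      pool <- if (from_topic[j]) topic_pool else seq_len(n_entities)
      ent_draw[j] <- pool[sample.int(length(pool), 1L)]
    }

    # Token stream: filler, then [term filler] per planted occurrence.
    # Planted terms are always flanked by filler tokens or string edges, so
    # boundary-aware matching recovers exactly these spans.
    pieces <- character(2L * n_ent + 1L)
    pieces[seq(1L, 2L * n_ent + 1L, by = 2L)] <-
      fillers[sample.int(length(fillers), n_ent + 1L, replace = TRUE)]
    pieces[seq(2L, 2L * n_ent, by = 2L)] <- term[ent_draw]
    abstract <- paste(pieces, collapse = " ")

    piece_len <- stringi::stri_length(pieces)
    piece_begin <- cumsum(c(0L, head(piece_len, -1L) + 1L)) # +1 per space
    occ_idx <- seq(2L, 2L * n_ent, by = 2L)
    planted[[d]] <- tibble(
      doc_id = doc_ids[[d]],
      entity_id = entity_id[ent_draw],
      begin = piece_begin[occ_idx],
      end = piece_begin[occ_idx] + piece_len[occ_idx],
      surface = term[ent_draw]
    )
    documents[[d]] <- tibble(
      doc_id = doc_ids[[d]],
      title = paste("Synthetic abstract", d),
      abstract = abstract,
      language = spec$languages[[(d - 1L) %% length(spec$languages) + 1L]],
      authors = list(authors[radix_sort(doc_authors)]),
      source = "synthetic"
    )
  }
  documents <- bind_rows(documents)
  planted <- bind_rows(planted)
  annotations <- mutate(planted, ontology = curie_ontology(.data$entity_id))

  pair_idx <- utils::combn(n_entities, 2L)
  same_topic <- entity_topic[pair_idx[1L, ]] == entity_topic[pair_idx[2L, ]]
  p_edge <- ifelse(same_topic, spec$intra_topic_edge_prob,
                   spec$inter_topic_edge_prob)
  has_edge <- stats::runif(ncol(pair_idx)) < p_edge
  edges <- canonicalise_pairs(entity_id[pair_idx[1L, has_edge]],
                              entity_id[pair_idx[2L, has_edge]])
  edges$label <- "related_to"
  edges <- edges[radix_order(edges$entity_a, edges$entity_b), , drop = FALSE]

  structure(
    list(
      documents = documents,
      lexicon = lexicon,
      annotations = annotations[
        radix_order(annotations$doc_id, annotations$begin), , drop = FALSE],
      relations = edges,
      ground_truth = list(
        author_topics = tibble(user_id = authors, topic = author_topic),
        entity_topics = tibble(entity_id = entity_id, topic = entity_topic),
        planted = planted,
        edges = edges[c("entity_a", "entity_b")]
      )
    ),
    class = "synthetic_corpus"
  )
}

#' Write a synthetic corpus to disk
#'
#' Emits the document, lexicon and relation tables as TSV, one PubAnnotation
#' JSON per document (gold annotations) under `annotations/`, and the ground
#' truth as JSON.
#'
#' @param corpus A `synthetic_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!inherits(corpus, "synthetic_corpus")) {
    abort("`corpus` must come from generate_corpus().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_documents(corpus$documents, file.path(dir, "documents.tsv"))
  readr::write_tsv(corpus$lexicon, file.path(dir, "lexicon.tsv"),
                   progress = FALSE)
  readr::write_tsv(corpus$relations, file.path(dir, "relations.tsv"),
                   progress = FALSE)
  ann_dir <- file.path(dir, "annotations")
  dir.create(ann_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus$documents))) {
    doc <- corpus$documents[i, , drop = FALSE]
    anns <- filter(corpus$annotations, .data$doc_id == doc$doc_id)
    write_pubannotation(doc, anns,
                        file.path(ann_dir, paste0(doc$doc_id, ".json")))
  }
  gt <- corpus$ground_truth
  jsonlite::write_json(
    list(
      author_topics = gt$author_topics,
      entity_topics = gt$entity_topics,
      planted = gt$planted,
      edges = gt$edges
    ),
    file.path(dir, "ground_truth.json"),
    dataframe = "columns", digits = NA
  )
  invisible(dir)
}

#' Packaged worked example of relation-based recommendation
#'
#' A small golden fixture reconstructing the recommender's canonical worked
#' example: one researcher who liked six COVID-19-related entities, and
#' three candidate entities — severe acute respiratory syndrome
#' (`DOID_2945`), related to two of the liked entities; propyzamide
#' (`CHEBI_34935`), related to three; and inflammatory response
#' (`GO_0006954`), related to none.  Their RelRA scores are therefore
#' exactly 2/6, 3/6 and 0, and only the first two are worth recommending.
#' The liked set's identifiers are a plausible reconstruction (the published
#' example names only the candidates).
#'
#' @return A list with `ratings` (one user, six items), `graph` (relation
#'   graph), `relations` (its edge tibble), `candidates` (the three
#'   candidate CURIEs) and `liked` (the six liked CURIEs).
#' @export
relra_example_fixture <- function() {
  liked <- c(
    "DOID_0080600", # COVID-19
    "DOID_934",     # viral infectious disease
    "GO_0019079",   # viral genome replication
    "HP_0001945",   # fever
    "HP_0002098",   # respiratory distress
    "CHEBI_15379"   # dioxygen
  )
  candidates <- c("DOID_2945", "CHEBI_34935", "GO_0006954")
  relations <- tibble(
    entity_a = c(
      "DOID_2945", "DOID_2945",                  # SARS ~ 2 liked
      "CHEBI_34935", "CHEBI_34935", "CHEBI_34935" # propyzamide ~ 3 liked
    ),
    entity_b = c(
      "HP_0001945", "DOID_934",
      "GO_0019079", "HP_0002098", "CHEBI_15379"
    ),
    label = "related_to"
  )
  ratings <- tibble(
    user_id = "researcher_001",
    item_id = liked,
    rating = 1L
  )
  list(
    ratings = ratings,
    graph = as_relation_graph(relations),
    relations = relations,
    candidates = candidates,
    liked = liked
  )
}
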