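# Independent brute-force oracles and random-instance generators shared by
# the unit, property and acceptance tests.  These deliberately avoid the
# package's own code paths: the matcher oracle scans position by position,
# the ratings oracle loops over (document, author, entity), the RelRA oracle
# loops over (candidate, liked) pairs against the raw relation table.

# Character pool where whole-string and per-character case/diacritic folding
# coincide (no length-changing folds such as the German sharp s).
ORACLE_CHARS <- c(letters, LETTERS, 0:9, "é", "í", "ó",
                  "ç", "ã", "É", "Í")

rand_word <- function(min_len = 2, max_len = 6) {
  paste(sample(ORACLE_CHARS, sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

rand_term <- function() {
  n_words <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
  words <- replicate(n_words, rand_word())
  term <- paste(words, collapse = " ")
  if (stats::runif(1) < 0.15) term <- paste0(term, "-", rand_word(1, 3))
  term
}

rand_lexicon <- function(n_terms = 10) {
  terms <- unique(replicate(n_terms, rand_term()))
  tibble::tibble(
    term = terms,
    entity_id = sprintf("DOID_%04d", seq_along(terms))
  )
}

# Random text interleaving lexicon terms, random words, punctuation and
# occasional unseparated concatenations (to exercise the boundary rule).
rand_text <- function(lexicon, n_tokens = 30) {
  toks <- character(n_tokens)
  for (i in seq_len(n_tokens)) {
    r <- stats::runif(1)
    toks[i] <- if (r < 0.35) {
      sample(lexicon$term, 1)
    } else if (r < 0.85) {
      rand_word()
    } else {
      sample(c(".", ",", "(", ")", ";"), 1)
    }
  }
  glue <- sample(c(" ", " ", " ", ""), n_tokens - 1, replace = TRUE)
  paste0(paste0(toks[-n_tokens], glue, collapse = ""), toks[n_tokens])
}

# Naive leftmost-longest scanner with the word-boundary rule: at each
# position try term lengths longest-first; on a hit, emit and jump past it.
oracle_match_spans <- function(terms, text, fold_case = TRUE,
                               fold_diacritics = FALSE) {
  norm <- function(x) {
    if (fold_case) x <- stringi::stri_trans_tolower(x)
    if (fold_diacritics) x <- stringi::stri_trans_general(x, "Latin-ASCII")
    x
  }
  tnorm <- norm(text)
  terms_n <- unique(norm(terms))
  n <- stringi::stri_length(tnorm)
  chars <- stringi::stri_sub(tnorm, seq_len(n), seq_len(n))
  alnum <- stringi::stri_detect_regex(chars, "[\\p{L}\\p{N}]")
  lens <- sort(unique(stringi::stri_length(terms_n)), decreasing = TRUE)
  begins <- integer(); ends <- integer()
  i <- 1L
  while (i <= n) {
    hit_end <- 0L
    for (L in lens) {
      j <- i + L - 1L
      if (j > n) next
      if (!stringi::stri_sub(tnorm, i, j) %in% terms_n) next
      if (i > 1L && alnum[i - 1L]) next
      if (j < n && alnum[j + 1L]) next
      hit_end <- j
      break
    }
    if (hit_end == 0L) {
      i <- i + 1L
    } else {
      begins <- c(begins, i - 1L)
      ends <- c(ends, hit_end)
      i <- hit_end + 1L
    }
  }
  tibble::tibble(begin = begins, end = ends)
}

# Brute-force rating counts over the (document, author, entity) incidence.
oracle_ratings <- function(docs, anns) {
  rows <- list()
  for (d in seq_len(nrow(docs))) {
    ents <- sort(unique(anns$entity_id[anns$doc_id == docs$doc_id[[d]]]))
    for (a in docs$authors[[d]]) {
      for (e in ents) {
        rows[[length(rows) + 1L]] <- tibble::tibble(user_id = a, item_id = e)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(user_id = character(), item_id = character(),
                          rating = integer()))
  }
  out <- dplyr::count(dplyr::bind_rows(rows), user_id, item_id,
                      name = "rating")
  out$rating <- as.integer(out$rating)
  out[order(out$user_id, out$item_id, method = "radix"), ]
}

# Brute-force RelRA score from the raw relation pair table.
oracle_relra <- function(liked, candidate, rel_tbl) {
  hits <- 0L
  for (l in liked) {
    related <- any(
      (rel_tbl$entity_a == candidate & rel_tbl$entity_b == l) |
        (rel_tbl$entity_b == candidate & rel_tbl$entity_a == l)
    )
    if (related) hits <- hits + 1L
  }
  hits / length(liked)
}

# Random corpus of documents + annotations (no text needed; ratings only
# depend on the (doc, author, entity) incidence).
rand_incidence_corpus <- function(n_docs = 20, n_authors = 8, n_entities = 12,
                                  max_authors = 3, max_mentions = 6) {
  authors <- sprintf("auth%02d", seq_len(n_authors))
  entities <- sprintf("GO_%07d", seq_len(n_entities))
  docs <- tibble::tibble(
    doc_id = sprintf("d%03d", seq_len(n_docs)),
    title = "t",
    abstract = "a",
    language = "en",
    authors = lapply(seq_len(n_docs), function(i) {
      sample(authors, sample(0:max_authors, 1))
    }),
    source = "test"
  )
  anns <- dplyr::bind_rows(lapply(seq_len(n_docs), function(i) {
    n_m <- sample(1:max_mentions, 1)
    ents <- sample(entities, n_m, replace = TRUE)
    tibble::tibble(
      doc_id = docs$doc_id[[i]],
      begin = 0L, end = 1L, surface = "a",
      entity_id = ents, ontology = "GO"
    )
  }))
  list(docs = docs, anns = anns)
}

rand_ratings <- function(n_users = 10, n_items = 15, min_per_user = 2,
                         max_per_user = 8, max_rating = 5) {
  users <- sprintf("u%03d", seq_len(n_users))
  items <- sprintf("CHEBI_%05d", seq_len(n_items))
  dplyr::bind_rows(lapply(users, function(u) {
    its <- sample(items, sample(min_per_user:max_per_user, 1))
    tibble::tibble(user_id = u, item_id = its,
                   rating = sample.int(max_rating, length(its),
                                       replace = TRUE))
  }))
}

# Random valid PubAnnotation inputs: a text, non-overlapping annotations and
# relations among the annotated entities.
rand_pubannotation <- function(doc_id = "pa001") {
  words <- replicate(sample(10:25, 1), rand_word(3, 7))
  text <- paste(words, collapse = " ")
  n <- stringi::stri_length(text)
  starts <- cumsum(c(1L, stringi::stri_length(words) + 1L))
  starts <- starts[-length(starts)]
  pick <- sort(sample(seq_along(words), sample(2:6, 1)))
  anns <- tibble::tibble(
    doc_id = doc_id,
    begin = starts[pick] - 1L,
    end = starts[pick] - 1L + stringi::stri_length(words[pick]),
    surface = words[pick],
    entity_id = sprintf("HP_%07d", sample(1:9999, length(pick))),
    ontology = "HP"
  )
  rels <- NULL
  if (nrow(anns) >= 2) {
    pairs <- t(utils::combn(sort(unique(anns$entity_id)), 2))
    keep <- sample(nrow(pairs), min(nrow(pairs), sample(1:3, 1)))
    rels <- tibble::tibble(
      entity_a = pairs[keep, 1], entity_b = pairs[keep, 2],
      label = "related_to"
    )
  }
  doc <- tibble::tibble(
    doc_id = doc_id, title = "", abstract = text, language = "en",
    authors = list(character()), source = "test"
  )
  list(doc = doc, anns = anns, rels = rels)
}

# Common wrapper: corpus -> ratings -> evaluation comparison for one seed.
planted_eval <- function(seed, k = 5, min_items = 20) {
  spec <- synthetic_spec(seed = seed)
  corpus <- generate_corpus(spec)
  ratings <- build_ratings(corpus$documents, corpus$annotations)
  graph <- as_relation_graph(corpus$relations)
  evaluate(ratings, graph, algorithms = c("relra", "random"), k = k,
           min_items = min_items, train_frac = 0.8, seed = seed)
}
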