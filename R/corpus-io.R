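#' Read a document table
#'
#' Documents are the toolkit's ingestion format for abstract collections: one
#' row per article with an identifier, title, abstract text, an ISO 639-1
#' language code and the ordered author list.  Authors are serialized in a
#' single column separated by `authors_sep`.
#'
#' @param path Path to a UTF-8 tab-separated file with columns `doc_id`,
#'   `title`, `abstract`, `language`, `authors` and optionally `source`.
#' @param authors_sep Single character separating author names inside the
#'   `authors` column.
#'
#' @return A tibble with one row per document; `authors` is a list-column of
#'   character vectors (possibly empty).
#'
#' @details Duplicate `doc_id` values are an error (each record must be one
#'   article); an empty `authors` field yields an empty author list with a
#'   warning, since such a document contributes no ratings downstream.
#'
#' @seealso [write_documents()], [annotate_documents()], [build_ratings()]
#' @export
read_documents <- function(path, authors_sep = "|") {
  assert_string(path, "path")
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  require_columns(df, c("doc_id", "title", "abstract", "language", "authors"),
                  paste0("Document table '", path, "'"))
  if (!"source" %in% names(df)) df$source <- NA_character_
  line_no <- seq_len(nrow(df)) + 1L # header occupies line 1

  for (col in c("doc_id", "language")) {
    bad <- which(is.na(df[[col]]) | !nzchar(df[[col]]))
    if (length(bad) > 0L) {
      abort(paste0(
        "Missing `", col, "` in '", path, "' at line(s) ",
        paste(line_no[bad], collapse = ", "), "."
      ))
    }
  }
  bad_lang <- which(!stringi::stri_detect_regex(df$language, "^[a-z]{2}$"))
  if (length(bad_lang) > 0L) {
    abort(paste0(
      "`language` must be a 2-letter lowercase ISO 639-1 code in '", path,
      "' at line(s) ", paste(line_no[bad_lang], collapse = ", "), "."
    ))
  }
  dup <- df$doc_id[duplicated(df$doc_id)]
  if (length(dup) > 0L) {
    dup_lines <- line_no[df$doc_id %in% dup]
    abort(paste0(
      "Duplicate doc_id(s) ", paste(unique(dup), collapse = ", "),
      " in '", path, "' at line(s) ", paste(dup_lines, collapse = ", "), "."
    ))
  }

  authors_raw <- ifelse(is.na(df$authors), "", df$authors)
  authors <- stringi::stri_split_fixed(authors_raw, authors_sep)
  authors <- purrr::map(authors, function(a) {
    a <- stringi::stri_trim_both(a)
    a[nzchar(a)]
  })
  n_empty <- sum(lengths(authors) == 0L)
  if (n_empty > 0L) {
    warn(paste0(
      n_empty, " document(s) in '", path,
      "' have an empty author list and will contribute no ratings."
    ))
  }
  tibble(
    doc_id = df$doc_id,
    title = ifelse(is.na(df$title), "", df$title),
    abstract = ifelse(is.na(df$abstract), "", df$abstract),
    language = df$language,
    authors = authors,
    source = df$source
  )
}

#' Write a document table
#'
#' @param docs Document tibble as returned by [read_documents()] or
#'   [generate_corpus()].
#' @param path Output path (tab-separated, UTF-8).
#' @inheritParams read_documents
#' @return `path`, invisibly.
#' @export
write_documents <- function(docs, path, authors_sep = "|") {
  require_columns(docs, c("doc_id", "title", "abstract", "language", "authors"),
                  "`docs`")
  out <- tibble(
    doc_id = docs$doc_id,
    title = docs$title,
    abstract = docs$abstract,
    language = docs$language,
    authors = purrr::map_chr(docs$authors,
                             ~ paste(.x, collapse = authors_sep)),
    source = if ("source" %in% names(docs)) docs$source else NA_character_
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Load a lexicon table
#'
#' A lexicon maps ontology surface terms to entity identifiers (CURIEs such
#' as `DOID_2945` or `CHEBI_34935`).  A term may map to several identifiers
#' (e.g. a DeCS term carrying both a DeCS and a MeSH code).
#'
#' @param path Path to a tab-separated file whose first two columns are
#'   `term` and `entity_id`.
#' @return A tibble with columns `term` and `entity_id`, one row per
#'   term-to-identifier mapping, with the source row count in attribute
#'   `n_source_rows`.  Terms are stripped of surrounding whitespace; rows with
#'   empty terms are dropped with a warning.
#' @seealso [build_matcher()]
#' @export
load_lexicon <- function(path) {
  assert_string(path, "path")
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(df) < 2L) {
    abort(paste0("Lexicon '", path, "' must have at least 2 columns ",
                 "(term, entity_id); found ", ncol(df), "."))
  }
  require_columns(df, c("term", "entity_id"), paste0("Lexicon '", path, "'"))
  n_source <- nrow(df)
  term <- stringi::stri_trim_both(ifelse(is.na(df$term), "", df$term))
  keep <- nzchar(term) & !is.na(df$entity_id) & nzchar(df$entity_id)
  if (sum(!keep) > 0L) {
    warn(paste0("Dropped ", sum(!keep), " lexicon row(s) with an empty term ",
                "or identifier from '", path, "'."))
  }
  if (n_source == 0L) {
    warn(paste0("Lexicon '", path, "' is empty."))
  }
  out <- distinct(tibble(term = term[keep], entity_id = df$entity_id[keep]))
  attr(out, "n_source_rows") <- n_source
  out
}

#' Build an entity relation graph from a pair table
#'
#' The relation graph is RelRA's knowledge source: an undirected simple graph
#' over entity identifiers.  Pairs are canonicalised (lexicographically
#' ordered), duplicates in either orientation are collapsed, and self-pairs
#' are dropped with a warning — an item trivially related to itself would
#' distort recommendation scores.
#'
#' @param edges Data frame with columns `entity_a`, `entity_b` and optionally
#'   `label` and `provenance_doc`.  Labels are preserved on the edges (first
#'   label per pair) but ignored by scoring.
#' @return An undirected simple [igraph::igraph] object.
#' @seealso [load_relations()], [relation_edges()], [relra_score()]
#' @export
as_relation_graph <- function(edges) {
  require_columns(edges, c("entity_a", "entity_b"), "`edges`")
  edges <- as_tibble(edges)
  if (nrow(edges) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  pairs <- canonicalise_pairs(edges$entity_a, edges$entity_b)
  pairs$label <- if ("label" %in% names(edges)) edges$label else NA_character_
  self <- pairs$entity_a == pairs$entity_b
  if (any(self)) {
    warn(paste0("Dropped ", sum(self), " self-relation(s)."))
    pairs <- pairs[!self, , drop = FALSE]
  }
  pairs <- pairs |>
    group_by(.data$entity_a, .data$entity_b) |>
    summarise(label = .data$label[1L], .groups = "drop") |>
    arrange(.data$entity_a, .data$entity_b)
  igraph::graph_from_data_frame(pairs, directed = FALSE)
}

#' Load an entity relation table as a graph
#'
#' @param path Path to a tab-separated file with columns `entity_a`,
#'   `entity_b` and optionally `label`, `provenance_doc` — the shape produced
#'   by an external relation-extraction step.  An empty file yields an empty
#'   graph.
#' @inherit as_relation_graph return
#' @export
load_relations <- function(path) {
  assert_string(path, "path")
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(df) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  require_columns(df, c("entity_a", "entity_b"),
                  paste0("Relation table '", path, "'"))
  as_relation_graph(df)
}

#' Edge table of a relation graph
#'
#' @param graph Relation graph as returned by [as_relation_graph()].
#' @return Tibble with columns `entity_a`, `entity_b` (canonical order) and
#'   `label`, sorted for deterministic output.
#' @export
relation_edges <- function(graph) {
  if (igraph::ecount(graph) == 0L) {
    return(tibble(entity_a = character(), entity_b = character(),
                  label = character()))
  }
  el <- igraph::as_edgelist(graph)
  out <- canonicalise_pairs(el[, 1L], el[, 2L])
  lab <- igraph::edge_attr(graph, "label")
  out$label <- if (is.null(lab)) NA_character_ else lab
  out[radix_order(out$entity_a, out$entity_b), , drop = FALSE]
}

#' Read and validate a ratings table
#'
#' Ratings are implicit feedback: `rating` is the number of articles
#' `user_id` (an author) wrote that mention `item_id` (an entity CURIE).
#'
#' @param path Path to a tab-separated file with columns `user_id`,
#'   `item_id`, `rating`.
#' @return Tibble of validated rating triples, sorted by `(user_id, item_id)`.
#' @seealso [write_ratings()], [build_ratings()]
#' @export
read_ratings <- function(path) {
  assert_string(path, "path")
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      user_id = readr::col_character(),
      item_id = readr::col_character(),
      rating = readr::col_double()
    ),
    progress = FALSE
  )
  require_columns(df, c("user_id", "item_id", "rating"),
                  paste0("Ratings table '", path, "'"))
  validate_ratings(as_tibble(df), context = paste0("'", path, "'"))
}

#' Write a ratings table
#'
#' Rows are ordered by `(user_id, item_id)` in C-locale byte order so the
#' output is byte-identical across runs and machines for the same dataset.
#'
#' @param ratings Ratings tibble (`user_id`, `item_id`, `rating`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings, context = "`ratings`")
  out <- ratings[radix_order(ratings$user_id, ratings$item_id), , drop = FALSE]
  out$rating <- as.integer(out$rating)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Shared validation for rating triples: integer ratings >= 1, (user, item)
# unique.  Returns the triples with `rating` as integer.
validate_ratings <- function(ratings, context = "`ratings`") {
  require_columns(ratings, c("user_id", "item_id", "rating"), context)
  ratings <- as_tibble(ratings)[c("user_id", "item_id", "rating")]
  bad <- which(is.na(ratings$rating) | ratings$rating < 1 |
                 ratings$rating != as.integer(ratings$rating))
  if (length(bad) > 0L) {
    abort(paste0(
      "Ratings must be integers >= 1; offending row(s) in ", context, ": ",
      paste(head(bad, 10L), collapse = ", "), "."
    ))
  }
  key <- paste(ratings$user_id, ratings$item_id, sep = "\r")
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup) > 0L) {
    abort(paste0(
      "Duplicate (user_id, item_id) pair(s) in ", context, " at row(s): ",
      paste(head(dup, 10L), collapse = ", "), "."
    ))
  }
  ratings$rating <- as.integer(ratings$rating)
  ratings
}

#' Read a PubAnnotation JSON document
#'
#' Parses the PubAnnotation interchange dialect: a JSON object with `text`,
#' optional `denotations` (identifier, character span, ontology object) and
#' optional `relations` between denotations.
#'
#' @param path Path to a PubAnnotation JSON file.
#' @return A list with elements:
#'   \describe{
#'     \item{document}{One-row document tibble; `doc_id` comes from
#'       `sourceid` when present, else the file stem; the text is stored as
#'       the abstract.}
#'     \item{annotations}{Tibble of entity annotations (`doc_id`, `begin`,
#'       `end`, `surface`, `entity_id`, `ontology`), offsets 0-based
#'       half-open in Unicode code points, sorted by span.}
#'     \item{relations}{Tibble of canonicalised entity pairs (`entity_a`,
#'       `entity_b`, `label`, `provenance_doc`); self-pairs (two denotations
#'       of the same entity) are dropped with a warning.}
#'   }
#' @details Spans are validated against `text` (`0 <= begin < end <=`
#'   text length); a violating denotation or a relation referencing an
#'   unknown denotation id is an error naming the offender.
#' @seealso [write_pubannotation()]
#' @export
read_pubannotation <- function(path) {
  assert_string(path, "path")
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort(paste0("Malformed JSON in '", path, "': ", conditionMessage(e)))
    }
  )
  if (is.null(obj$text) || !is.character(obj$text[[1L]])) {
    abort(paste0("PubAnnotation file '", path, "' has no `text` field."))
  }
  text <- obj$text[[1L]]
  n <- stringi::stri_length(text)
  doc_id <- as.character(
    obj$sourceid %||% sub("\\.json$", "", basename(path))
  )

  dens <- obj$denotations %||% list()
  den_tbl <- purrr::map_dfr(dens, function(d) {
    id <- as.character(d$id %||% "<missing id>")
    begin <- d$span$begin
    end <- d$span$end
    if (is.null(begin) || is.null(end)) {
      abort(paste0("Denotation '", id, "' in '", path, "' has no span."))
    }
    begin <- as.integer(begin); end <- as.integer(end)
    if (begin < 0L || begin >= end || end > n) {
      abort(paste0(
        "Denotation '", id, "' in '", path, "' has an invalid span [",
        begin, ", ", end, ") for a text of length ", n, "."
      ))
    }
    tibble(den_id = id, begin = begin, end = end,
           entity_id = as.character(d$obj %||% ""))
  })
  if (nrow(den_tbl) > 0L) {
    den_tbl$surface <- stringi::stri_sub(text, den_tbl$begin + 1L,
                                         den_tbl$end)
    den_tbl <- den_tbl[radix_order(den_tbl$begin, den_tbl$end,
                                   den_tbl$entity_id), , drop = FALSE]
  }

  rels <- obj$relations %||% list()
  rel_tbl <- purrr::map_dfr(rels, function(r) {
    for (side in c("subj", "obj")) {
      ref <- as.character(r[[side]] %||% "")
      if (!ref %in% den_tbl$den_id) {
        abort(paste0(
          "Relation in '", path, "' references unknown denotation id '",
          ref, "'."
        ))
      }
    }
    tibble(
      entity_a = den_tbl$entity_id[match(as.character(r$subj),
                                         den_tbl$den_id)],
      entity_b = den_tbl$entity_id[match(as.character(r$obj),
                                         den_tbl$den_id)],
      label = as.character(r$pred %||% NA_character_)
    )
  })
  if (nrow(rel_tbl) > 0L) {
    canon <- canonicalise_pairs(rel_tbl$entity_a, rel_tbl$entity_b)
    canon$label <- rel_tbl$label
    self <- canon$entity_a == canon$entity_b
    if (any(self)) {
      warn(paste0("Dropped ", sum(self), " self-relation(s) in '", path,
                  "'."))
      canon <- canon[!self, , drop = FALSE]
    }
    rel_tbl <- canon |>
      distinct(.data$entity_a, .data$entity_b, .keep_all = TRUE) |>
      mutate(provenance_doc = doc_id)
  } else {
    rel_tbl <- tibble(entity_a = character(), entity_b = character(),
                      label = character(), provenance_doc = character())
  }

  annotations <- if (nrow(den_tbl) == 0L) {
    empty_annotations()
  } else {
    tibble(
      doc_id = doc_id,
      begin = den_tbl$begin,
      end = den_tbl$end,
      surface = den_tbl$surface,
      entity_id = den_tbl$entity_id,
      ontology = curie_ontology(den_tbl$entity_id)
    )
  }

  list(
    document = tibble(
      doc_id = doc_id,
      title = "",
      abstract = text,
      language = NA_character_,
      authors = list(character()),
      source = "pubannotation"
    ),
    annotations = annotations,
    relations = rel_tbl
  )
}

#' Write a PubAnnotation JSON document
#'
#' Emits a PubAnnotation-conformant JSON object for one annotated document.
#' Denotation ids are `"T1"`, `"T2"`, ... in span order; relation ids `"R1"`,
#' ....  Relations reference the first denotation of each member entity.
#'
#' @param doc One-row document tibble (the abstract is the annotated text).
#' @param annotations Annotation tibble for this document (`begin`, `end`,
#'   `surface`, `entity_id`).
#' @param path Output path.
#' @param relations Optional tibble of entity pairs (`entity_a`, `entity_b`,
#'   optional `label`) among the annotated entities.
#' @return `path`, invisibly.
#' @export
write_pubannotation <- function(doc, annotations, path, relations = NULL) {
  require_columns(doc, c("doc_id", "abstract"), "`doc`")
  if (nrow(doc) != 1L) abort("`doc` must be a single document row.")
  text <- doc$abstract[[1L]]
  n <- stringi::stri_length(text)

  annotations <- as_tibble(annotations)
  if (nrow(annotations) > 0L) {
    require_columns(annotations, c("begin", "end", "surface", "entity_id"),
                    "`annotations`")
    bad <- which(annotations$begin < 0L | annotations$begin >= annotations$end |
                   annotations$end > n |
                   stringi::stri_sub(text, annotations$begin + 1L,
                                     annotations$end) != annotations$surface)
    if (length(bad) > 0L) {
      b <- bad[[1L]]
      abort(paste0(
        "Annotation ", b, " (entity ", annotations$entity_id[b],
        ", span [", annotations$begin[b], ", ", annotations$end[b],
        ")) violates its span invariant against the document text."
      ))
    }
    annotations <- annotations[
      radix_order(annotations$begin, annotations$end, annotations$entity_id), ,
      drop = FALSE
    ]
  }

  den_ids <- paste0("T", seq_len(nrow(annotations)))
  denotations <- purrr::pmap(
    list(den_ids, annotations$begin, annotations$end, annotations$entity_id),
    function(id, b, e, obj) {
      list(id = id, span = list(begin = b, end = e), obj = obj)
    }
  )

  rel_objs <- list()
  if (!is.null(relations) && nrow(relations) > 0L) {
    require_columns(relations, c("entity_a", "entity_b"), "`relations`")
    first_den <- den_ids[match(c(relations$entity_a, relations$entity_b),
                               annotations$entity_id)]
    if (anyNA(first_den)) {
      missing_ent <- unique(c(relations$entity_a,
                              relations$entity_b)[is.na(first_den)])
      abort(paste0(
        "Relation references entity id(s) with no annotation in this ",
        "document: ", paste(missing_ent, collapse = ", "), "."
      ))
    }
    m <- nrow(relations)
    labels <- if ("label" %in% names(relations)) relations$label else
      rep(NA_character_, m)
    rel_objs <- purrr::map(seq_len(m), function(i) {
      list(
        id = paste0("R", i),
        subj = first_den[i],
        obj = first_den[m + i],
        pred = if (is.na(labels[i])) "related_to" else labels[i]
      )
    })
  }

  payload <- list(
    sourceid = doc$doc_id[[1L]],
    text = text,
    denotations = denotations,
    relations = rel_objs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# Zero-row annotation tibble with the canonical column set.
empty_annotations <- function() {
  tibble(
    doc_id = character(), begin = integer(), end = integer(),
    surface = character(), entity_id = character(), ontology = character()
  )
}
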