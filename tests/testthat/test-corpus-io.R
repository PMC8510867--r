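test_that("PubAnnotation reading validates spans and resolves relations", {
  path <- withr::local_tempfile(fileext = ".json")

  writeLines('{"text": "abc", "denotations": [
    {"id": "T1", "span": {"begin": 0, "end": 3}, "obj": "CHEBI_1"}]}', path)
  pa <- read_pubannotation(path)
  expect_equal(nrow(pa$annotations), 1L)
  expect_equal(pa$annotations$surface, "abc")
  expect_equal(pa$annotations$entity_id, "CHEBI_1")
  expect_equal(pa$annotations$ontology, "CHEBI")
  expect_equal(pa$document$abstract, "abc")

  writeLines('{"text": "ab", "denotations": [
    {"id": "T9", "span": {"begin": 0, "end": 5}, "obj": "X_1"}]}', path)
  expect_error(read_pubannotation(path), "T9")

  writeLines('{"text": "ab", "denotations": [
    {"id": "T1", "span": {"begin": 1, "end": 1}, "obj": "X_1"}]}', path)
  expect_error(read_pubannotation(path), "invalid span")

  writeLines('{"text": "ab", "denotations": [
    {"id": "T1", "span": {"begin": 0, "end": 1}, "obj": "X_1"}],
    "relations": [{"id": "R1", "subj": "T1", "obj": "T7", "pred": "p"}]}',
    path)
  expect_error(read_pubannotation(path), "unknown denotation id 'T7'")

  writeLines("{not json", path)
  expect_error(read_pubannotation(path), "Malformed JSON")
})

test_that("PubAnnotation writing orders denotations by span and round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- tibble::tibble(doc_id = "d1", title = "", abstract = "aa bb cc",
                        language = "en", authors = list("A"), source = "t")
  anns <- tibble::tibble(
    doc_id = "d1",
    begin = c(6L, 0L), end = c(8L, 2L),
    surface = c("cc", "aa"), entity_id = c("GO_2", "GO_1"),
    ontology = "GO"
  )
  rels <- tibble::tibble(entity_a = "GO_1", entity_b = "GO_2", label = "rel")
  write_pubannotation(doc, anns, path, relations = rels)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(sapply(raw$denotations, `[[`, "id"), c("T1", "T2"))
  expect_equal(sapply(raw$denotations, function(d) d$span$begin), c(0, 6))
  expect_equal(raw$relations[[1]][c("subj", "obj")],
               list(subj = "T1", obj = "T2"))

  back <- read_pubannotation(path)
  expect_equal(back$annotations$begin, c(0L, 6L))
  expect_equal(back$annotations$entity_id, c("GO_1", "GO_2"))
  expect_equal(back$relations$entity_a, "GO_1")

  # zero annotations -> text plus empty denotation list
  write_pubannotation(doc, anns[0, ], path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(raw$text, "aa bb cc")
  expect_length(raw$denotations, 0L)

  # invariant violation refuses to write
  bad <- anns
  bad$surface[1] <- "zz"
  expect_error(write_pubannotation(doc, bad, path), "span invariant")
})

test_that("PubAnnotation write->read is the identity on random valid files", {
  withr::local_seed(421)
  path <- withr::local_tempfile(fileext = ".json")
  for (i in 1:50) {
    inst <- rand_pubannotation(sprintf("pa%03d", i))
    suppressWarnings(
      write_pubannotation(inst$doc, inst$anns, path, relations = inst$rels)
    )
    back <- read_pubannotation(path)
    expect_equal(back$document$abstract, inst$doc$abstract)
    expect_equal(
      back$annotations[c("begin", "end", "surface", "entity_id")],
      inst$anns[c("begin", "end", "surface", "entity_id")]
    )
    if (!is.null(inst$rels)) {
      expect_equal(
        back$relations[order(back$relations$entity_a,
                             back$relations$entity_b), ][
                               c("entity_a", "entity_b")],
        inst$rels[order(inst$rels$entity_a, inst$rels$entity_b), ][
          c("entity_a", "entity_b")],
        ignore_attr = TRUE
      )
    }
  }
})

test_that("document tables round-trip and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "doc_id\ttitle\tabstract\tlanguage\tauthors",
    "d1\tT1\tsome text\ten\tAna Silva|Li Wei",
    "d2\tT2\toutro texto\tpt\tAna Silva",
    "d3\tT3\tmore text\ten\t"
  ), path)
  expect_warning(docs <- read_documents(path), "empty author list")
  expect_equal(nrow(docs), 3L)
  expect_equal(docs$authors[[1]], c("Ana Silva", "Li Wei"))
  expect_equal(docs$authors[[3]], character())

  writeLines(c(
    "doc_id\ttitle\tabstract\tlanguage\tauthors",
    "d1\tT\tx\ten\tA",
    "d1\tT\ty\tpt\tB",
    "d2\tT\tz\ten\tC",
    "d1\tT\tw\tes\tD"
  ), path)
  expect_error(read_documents(path), "2, 3, 5")

  writeLines(c(
    "doc_id\ttitle\tabstract\tlanguage\tauthors",
    "d1\tT\tx\tENG\tA"
  ), path)
  expect_error(read_documents(path), "ISO 639-1")

  # write -> read round trip
  docs <- tibble::tibble(
    doc_id = c("a", "b"), title = c("t1", "t2"),
    abstract = c("x y", "z"), language = c("en", "es"),
    authors = list(c("P Q", "R S"), "T U"), source = "synthetic"
  )
  write_documents(docs, path)
  back <- read_documents(path)
  expect_equal(back$authors, docs$authors)
  expect_equal(back$abstract, docs$abstract)
})

test_that("lexicon loading keeps multi-mappings and drops empty terms", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "term\tentity_id",
    "covid-19\tD000086382",
    "covid-19\tMESH_D000086382",
    "  fever \tHP_0001945",
    "\tHP_0000001"
  ), path)
  expect_warning(lex <- load_lexicon(path), "Dropped 1")
  expect_equal(nrow(lex), 3L)
  expect_equal(sort(lex$entity_id[lex$term == "covid-19"]),
               c("D000086382", "MESH_D000086382"))
  expect_equal(lex$term[lex$entity_id == "HP_0001945"], "fever")

  writeLines("term\tentity_id", path)
  expect_warning(lex <- load_lexicon(path), "empty")
  expect_equal(nrow(lex), 0L)

  writeLines(c("term", "x"), path)
  expect_error(load_lexicon(path), "at least 2 columns")

  # recount: mapping rows survive verbatim after dedup
  n <- 500
  tbl <- tibble::tibble(
    term = sprintf("term %03d", sample(seq_len(200), n, replace = TRUE)),
    entity_id = sprintf("GO_%04d", sample(seq_len(300), n, replace = TRUE))
  )
  readr::write_tsv(tbl, path)
  lex <- load_lexicon(path)
  expect_equal(nrow(lex), nrow(dplyr::distinct(tbl)))
  expect_equal(length(unique(lex$term)), length(unique(tbl$term)))
})

test_that("relation loading canonicalises pairs and is order-insensitive", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "entity_a\tentity_b",
    "A\tB",
    "B\tA",
    "A\tA"
  ), path)
  expect_warning(g <- load_relations(path), "self-relation")
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(sort(igraph::V(g)$name), c("A", "B"))

  writeLines(c("entity_a\tentity_b", "A\tB", "B\tC", "C\tD"), path)
  g <- load_relations(path)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(igraph::degree(g)[["B"]], 2)

  writeLines("entity_a\tentity_b", path)
  expect_equal(igraph::ecount(load_relations(path)), 0L)

  # 500 random pairs: edge count equals the distinct canonical pair count,
  # and permuting rows yields an identical graph
  withr::local_seed(77)
  ents <- sprintf("E%02d", 1:20)
  pairs <- tibble::tibble(
    entity_a = sample(ents, 500, replace = TRUE),
    entity_b = sample(ents, 500, replace = TRUE)
  )
  expected <- unique(apply(pairs, 1, function(r) {
    if (r[1] == r[2]) NA_character_ else paste(sort(r), collapse = "|")
  }))
  expected <- expected[!is.na(expected)]
  g1 <- suppressWarnings(as_relation_graph(pairs))
  expect_equal(igraph::ecount(g1), length(expected))
  g2 <- suppressWarnings(as_relation_graph(pairs[sample(nrow(pairs)), ]))
  expect_equal(relation_edges(g1)[c("entity_a", "entity_b")],
               relation_edges(g2)[c("entity_a", "entity_b")])
})

test_that("ratings tables validate, round-trip and write deterministically", {
  path <- withr::local_tempfile(fileext = ".tsv")
  one <- tibble::tibble(user_id = "u1", item_id = "DOID_2945", rating = 3L)
  write_ratings(one, path)
  expect_equal(read_ratings(path), one)

  dup <- tibble::tibble(user_id = c("u1", "u1"), item_id = c("i", "i"),
                        rating = c(1L, 2L))
  expect_error(write_ratings(dup, path), "Duplicate")

  bad <- tibble::tibble(user_id = "u", item_id = "i", rating = 0L)
  expect_error(write_ratings(bad, path), ">= 1")
  bad$rating <- 1.5
  expect_error(write_ratings(bad, path), ">= 1")

  withr::local_seed(99)
  big <- dplyr::distinct(tibble::tibble(
    user_id = sprintf("u%04d", sample(200, 10000, replace = TRUE)),
    item_id = sprintf("i%04d", sample(400, 10000, replace = TRUE))
  ))
  big$rating <- sample.int(9, nrow(big), replace = TRUE)
  write_ratings(big, path)
  back <- read_ratings(path)
  expect_equal(
    back,
    big[order(big$user_id, big$item_id, method = "radix"), ],
    ignore_attr = TRUE
  )
  # byte-identical rewrite from a permuted copy of the same dataset
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_ratings(big[sample(nrow(big)), ], path2)
  expect_identical(readLines(path), readLines(path2))
})
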