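test_that("per-user split follows the ceiling rule and reconstructs input", {
  mk <- function(user, n) tibble::tibble(
    user_id = user, item_id = sprintf("i%03d", seq_len(n)), rating = 1L
  )
  ds <- dplyr::bind_rows(mk("u20", 20), mk("u21", 21))
  sp <- split_dataset(ds, train_frac = 0.8, seed = 1)
  n_train <- table(sp$train$user_id)
  n_test <- table(sp$test$user_id)
  expect_equal(as.integer(n_train[c("u20", "u21")]), c(16L, 17L))
  expect_equal(as.integer(n_test[c("u20", "u21")]), c(4L, 4L))

  expect_error(split_dataset(mk("solo", 1)), "filter")

  # random dataset: per-user disjoint partition whose union is the input
  withr::local_seed(55)
  ds <- rand_ratings(n_users = 15, n_items = 30, min_per_user = 2,
                     max_per_user = 10)
  sp <- split_dataset(ds, train_frac = 0.8, seed = 7)
  joint <- dplyr::bind_rows(sp$train, sp$test)
  key <- function(x) sort(paste(x$user_id, x$item_id))
  expect_equal(key(joint), key(ds))
  expect_equal(nrow(dplyr::distinct(joint, user_id, item_id)), nrow(ds))
  expect_true(all(unique(ds$user_id) %in% sp$train$user_id))
  # deterministic for a fixed seed, different for another
  sp2 <- split_dataset(ds, train_frac = 0.8, seed = 7)
  expect_identical(sp, sp2)
})

test_that("top-k metrics match their set-based definitions", {
  rec <- sprintf("i%d", 1:5)
  expect_equal(precision_at_k(rec, c("i2", "i4"), 5), 0.4)
  expect_equal(precision_at_k(character(), "i1", 5), 0)
  expect_equal(recall_at_k(rec, c("i1", "i2", "i3", "i4"), 5), 1)
  expect_equal(recall_at_k(rec, c("x", "y"), 5), 0)
  expect_error(recall_at_k(rec, character(), 5), "skipped")
  expect_equal(mrr_at_k(rec, "i1", 5), 1)
  expect_equal(mrr_at_k(rec, "i3", 5), 1 / 3)
  expect_equal(mrr_at_k(rec, "i9", 5), 0)
  expect_error(precision_at_k(c("a", "a"), "a", 5), "duplicate")
  expect_error(precision_at_k(rec, "i1", 0), "k")

  # random instances vs brute-force intersection counting; the shared
  # intersection ties precision*k to recall*|relevant|
  withr::local_seed(12)
  pool <- sprintf("e%02d", 1:30)
  for (i in 1:25) {
    rec <- sample(pool, sample(3:12, 1))
    rel <- sample(pool, sample(1:8, 1))
    k <- sample(1:8, 1)
    inter <- length(intersect(head(rec, k), rel))
    expect_equal(precision_at_k(rec, rel, k), inter / k)
    expect_equal(recall_at_k(rec, rel, k), inter / length(rel))
    expect_equal(precision_at_k(rec, rel, k) * k, inter)
    expect_equal(recall_at_k(rec, rel, k) * length(rel), inter)
    first <- which(head(rec, k) %in% rel)
    expect_equal(mrr_at_k(rec, rel, k),
                 if (length(first)) 1 / first[1] else 0)
  }
})

test_that("evaluate applies the protocol and honours custom algorithms", {
  withr::local_seed(42)
  ds <- rand_ratings(n_users = 12, n_items = 40, min_per_user = 8,
                     max_per_user = 20)
  min_items <- 8
  seed <- 3
  # reconstruct the split evaluate() uses internally (same seed, same data)
  sp <- split_dataset(filter_min_ratings(ds, min_items), 0.8, seed)
  test_items <- split(sp$test$item_id, sp$test$user_id)

  oracle_alg <- function(user, train_items, candidates, k) {
    mine <- intersect(candidates, test_items[[user]])
    c(mine, setdiff(candidates, mine))
  }
  adversarial_alg <- function(user, train_items, candidates, k) {
    setdiff(candidates, test_items[[user]])
  }
  g <- as_relation_graph(tibble::tibble(entity_a = character(),
                                        entity_b = character()))
  rep <- evaluate(
    ds, g,
    algorithms = list(oracle = oracle_alg, adversarial = adversarial_alg),
    k = 5, min_items = min_items, train_frac = 0.8, seed = seed
  )
  m <- rep$metrics
  expect_equal(m$mrr[m$algorithm == "oracle"], 1)
  expected_recall <- mean(vapply(
    test_items[unique(sp$test$user_id)],
    function(t) min(1, 5 / length(unique(t))), numeric(1)
  ))
  expect_equal(m$recall[m$algorithm == "oracle"], expected_recall)
  expect_equal(m$precision[m$algorithm == "adversarial"], 0)
  expect_equal(m$recall[m$algorithm == "adversarial"], 0)
  expect_equal(m$mrr[m$algorithm == "adversarial"], 0)

  expect_error(evaluate(ds, g, min_items = 10000), "nothing to evaluate")
})

test_that("evaluation reports are reproducible and well-formed", {
  withr::local_seed(9)
  ds <- rand_ratings(n_users = 10, n_items = 25, min_per_user = 5,
                     max_per_user = 12)
  g <- as_relation_graph(tibble::tibble(
    entity_a = sprintf("CHEBI_%05d", sample(25, 30, replace = TRUE)),
    entity_b = sprintf("CHEBI_%05d", sample(25, 30, replace = TRUE))
  ) |> dplyr::filter(entity_a != entity_b))
  r1 <- evaluate(ds, g, k = 5, min_items = 5, seed = 11)
  r2 <- evaluate(ds, g, k = 5, min_items = 5, seed = 11)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$per_user, r2$per_user)
  expect_true(all(dplyr::select(r1$metrics, -algorithm) >= 0 &
                    dplyr::select(r1$metrics, -algorithm) <= 1))

  td <- tidy(r1)
  expect_equal(sort(unique(td$metric)), c("mrr", "precision", "recall"))
  expect_true(all(td$value >= 0 & td$value <= 1))
  gl <- glance(r1)
  expect_equal(gl$k, 5L)
  expect_lte(gl$n_users_evaluated, dplyr::n_distinct(ds$user_id))
  p <- ggplot2::autoplot(r1)
  expect_s3_class(p, "ggplot")
})

test_that("per-user k-fold evaluation covers each item exactly once as test", {
  withr::local_seed(21)
  ds <- rand_ratings(n_users = 8, n_items = 30, min_per_user = 6,
                     max_per_user = 12)
  g <- as_relation_graph(tibble::tibble(entity_a = character(),
                                        entity_b = character()))
  rep <- evaluate(ds, g, algorithms = "random", k = 3, min_items = 6,
                  seed = 2, folds = 3)
  expect_equal(max(rep$per_user$fold), 3L)
  expect_true(is.na(rep$train_frac))
  expect_identical(
    rep$metrics,
    evaluate(ds, g, algorithms = "random", k = 3, min_items = 6,
             seed = 2, folds = 3)$metrics
  )
})
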