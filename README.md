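# relra

Recommending biomedical entities to researchers from the literature they
already wrote.

Keeping up with a fast-moving research topic (COVID-19 being the canonical
case) means tracking which diseases, chemicals, phenotypes and processes are
becoming relevant to one's own work. `relra` turns a collection of abstracts
into an implicit-feedback recommendation problem and solves it with a
content-based recommender driven by relations between entities:

1. **Entity annotation** — a dictionary matcher recognizes ontology terms
   (DeCS/DO/GO/HPO/ChEBI-shaped lexicons) in abstracts and links them to
   their identifiers.  No training data required, and it works for any
   language the lexicon covers.
2. **Dataset construction** — from the annotated corpus, a standard
   `<user, item, rating>` dataset is built: *users* are the article authors,
   *items* are the recognized entities, and the *rating* is the number of
   articles an author wrote mentioning an entity.
3. **RelRA recommendation** — given an entity relation graph (as produced by
   an external relation-extraction step), the RelRA score of an unrated
   candidate item *c* for a user with liked-item set *L* is

   ```
   score(c) = |{ l ∈ L : {c, l} ∈ E }| / |L|
   ```

   i.e. the fraction of the user's liked items the candidate is related to.
   Candidates are ranked by score; a random sampler serves as baseline.
4. **Evaluation** — the usual top@k protocol: keep users with ≥ 20 rated
   items, split each user's items 80/20 into train/test, recommend the top 5
   from the unseen candidate pool, and report macro-averaged Precision@5,
   Recall@5 and MRR.

A synthetic corpus generator with planted author-topic structure emulates all
the inputs (documents, lexicons, gold annotations, relation lists), so the
entire pipeline is testable offline.  I/O covers PubAnnotation JSON and
tab-separated document/lexicon/relation/ratings tables.

## Worked example

The packaged fixture reproduces the recommender's canonical example: a
researcher who liked six COVID-19-related entities, and three candidates —
severe acute respiratory syndrome (`DOID_2945`), related to two of the liked
entities; propyzamide (`CHEBI_34935`), related to three; inflammatory
response (`GO_0006954`), related to none.

```r
library(relra)

fx <- relra_example_fixture()
recommend(fx$ratings, "researcher_001", fx$graph,
          candidates = fx$candidates, k = 3)
#> # A tibble: 3 × 4
#>   user_id         rank item_id     score
#>   <chr>          <int> <chr>       <dbl>
#> 1 researcher_001     1 CHEBI_34935 0.5
#> 2 researcher_001     2 DOID_2945   0.333
#> 3 researcher_001     3 GO_0006954  0
```

The scores are exactly 3/6, 2/6 and 0: propyzamide is related to three of
the six liked entities, SARS to two, inflammatory response to none.  With
`min_score` above zero the unrelated candidate is dropped, leaving the two
entities actually worth recommending.

On a synthetic corpus with planted topic structure, the full pipeline runs:

```r
corpus  <- generate_corpus(synthetic_spec(seed = 7))
ratings <- build_ratings(corpus$documents, corpus$annotations)
dataset_stats(ratings)
#> # A tibble: 1 × 3
#>   n_users n_items n_ratings
#>     <int>   <int>     <int>
#> 1      25     125       667

graph  <- as_relation_graph(corpus$relations)
report <- evaluate(ratings, graph, k = 5, min_items = 20,
                   train_frac = 0.8, seed = 7)
report
#> <relra_eval>  top@5 evaluation
#>   users evaluated: 23 (skipped: 0); min items/user: 20
#>   split: per-user holdout, train fraction 0.8, seed 7
#>   random   precision@5 0.0522  recall@5 0.0504  MRR 0.0862
#>   relra    precision@5 0.6174  recall@5 0.5866  MRR 0.7464
```

Because the corpus plants relations preferentially inside each author's
preferred topic, the relation-aware recommender retrieves held-out items far
more often than chance.  `tidy(report)`, `glance(report)` and
`autoplot(report)` give the long-format metrics, the protocol record and a
comparison bar chart.

## Command line

The same stages are available as subcommands (wrapper script in
`inst/cli/relra`):

```sh
relra simulate        --out corpus --seed 7
relra annotate        --lexicon corpus/lexicon.tsv --docs corpus/documents.tsv --out anns
relra build-dataset   --docs corpus/documents.tsv --annotations anns --out ratings.tsv
relra recommend       --ratings ratings.tsv --relations corpus/relations.tsv --user author_001 --k 5
relra evaluate        --ratings ratings.tsv --relations corpus/relations.tsv --out eval --seed 7
```

Every run writes a `run_manifest.json` with the toolkit version, parameters
and input checksums; identical manifests yield identical outputs.

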