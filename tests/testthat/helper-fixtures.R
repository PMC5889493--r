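# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; nothing is read from outside the package.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, .fixture_env)
}

# Tiny study with full-width (200-dim) embeddings: the default 416 layout
# at unit-test scale.
fix_tiny_study <- function() {
  memo("tiny", function() {
    st <- suppressWarnings(simulate_study(study_config("tiny"), seed = 101))
    st$featurizer <- build_featurizer(
      st$frequency_table, easy_words = st$easy_words,
      embedding_wiki = st$embedding_wiki, embedding_ehr = st$embedding_ehr)
    st$features <- featurize_corpus(st$featurizer, st$docs)
    st
  })
}

# Vocabulary-driven study (difficulty planted purely in word identity),
# used by the baseline-separation and ablation acceptance criteria.
fix_vocab_study <- function() {
  memo("vocab", function() {
    suppressWarnings(simulate_study(study_config("vocabulary"), seed = 5))
  })
}

# A deterministic toy document set with known feature vectors.
toy_features <- function(scores) {
  X <- matrix(scores, ncol = 1,
              dimnames = list(sprintf("d%02d", seq_along(scores)), "f"))
  attr(X, "layout_version") <- "toy1"
  X
}

# Ratings table helper for hand-built cases: one rater, sequential pairs.
toy_ratings <- function(rater, docs, ratings) {
  stopifnot(length(docs) %% 2 == 0)
  data.frame(rater_id = rater,
             pair_id = rep(sprintf("%s_p%02d", rater,
                                   seq_len(length(docs) / 2)), each = 2),
             doc_id = docs, rating = as.integer(ratings),
             stringsAsFactors = FALSE)
}
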