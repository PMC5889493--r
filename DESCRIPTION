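Package: readrank
Title: Ranking-Based Readability Assessment for Clinical and Health Text
Version: 0.1.0
Authors@R:
    person("readrank", "developers", email = "readrank@example.org",
           role = c("aut", "cre"))
Description: Assesses the readability of medical documents (electronic
    health record notes, consumer health articles) as a ranking problem
    rather than a grade-level prediction. Documents are featurized with
    readability-formula statistics, corpus word-frequency bins, length
    features and source-specific skip-gram word embeddings; a linear
    max-margin pairwise ranker is trained from per-rater difficulty
    ratings reduced to feature difference vectors. Includes the Kendall
    coefficient of concordance evaluation protocol with per-rater
    averaging and Wilcoxon signed-rank comparison, rater-behavior quality
    control (conformity, eccentric raters, controversial documents), a
    feature-ablation harness, and a synthetic study generator emulating a
    crowdsourced side-by-side annotation design so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
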