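# Kendall W, the per-rater concordance protocol, Wilcoxon comparison,
# stratified splitting, ablation harness structure

test_that("kendall_w: limits, errors, list input", {
  expect_equal(kendall_w(rbind(1:5, 1:5, 1:5)), 1)
  expect_equal(kendall_w(rbind(1:5, 5:1)), 0)
  expect_error(kendall_w(rbind(1:3)), class = "readrank_bad_rankings")
  expect_error(kendall_w(matrix(1, 2, 1)), class = "readrank_bad_rankings")
  # named-list input with item-set checking
  l <- list(a = c(x = 1, y = 2, z = 3), b = c(z = 3, x = 1, y = 2))
  expect_equal(kendall_w(l), 1)
  expect_error(kendall_w(list(c(x = 1, y = 2), c(x = 1, q = 2))),
               class = "readrank_bad_rankings")
})

test_that("kendall_w matches the brute-force oracle on an exhaustive small sweep", {
  # all weak orders of 3 items, all ordered pairs (m = 2), ties included
  wo <- weak_orders(3)
  for (a in wo) {
    for (b in wo) {
      x <- rbind(a, b)
      if (length(unique(a)) < 2 && length(unique(b)) < 2) next
      expect_equal(kendall_w(x), brute_kendall_w(x), tolerance = 1e-12)
    }
  }
  # random tied cases at n = 4..5, m = 3..4
  set.seed(7)
  for (i in 1:100) {
    m <- sample(3:4, 1)
    n <- sample(4:5, 1)
    x <- matrix(sample(1:4, m * n, replace = TRUE), m, n)
    if (all(apply(x, 1, function(r) length(unique(r))) < 2)) next
    expect_equal(kendall_w(x), brute_kendall_w(x), tolerance = 1e-12)
  }
})

test_that("W = (rho_spearman + 1) / 2 for two untied rankings", {
  set.seed(8)
  for (i in 1:40) {
    n <- sample(3:9, 1)
    a <- sample(n)
    b <- sample(n)
    expect_equal(kendall_w(rbind(a, b)),
                 (cor(a, b, method = "spearman") + 1) / 2, tolerance = 1e-12)
  }
})

test_that("per-rater concordance protocol: limits and exclusions", {
  # system scores identical to the ratings -> W = 1 per rater
  r <- rbind(toy_ratings("u1", sprintf("d%02d", 1:4), c(1, 4, 6, 9)),
             toy_ratings("u2", sprintf("d%02d", 3:6), c(2, 3, 8, 5)))
  sys <- c(d01 = 1, d02 = 4, d03 = 6, d04 = 9, d05 = 80, d06 = 50)
  rep <- system_vs_rater_concordance(sys, read_ratings(r))
  expect_equal(unname(rep$per_rater_w["u1"]), 1)
  expect_equal(rep$mean_w, mean(rep$per_rater_w))
  expect_equal(rep$n_raters, 2L)

  # rater with all-equal ratings is excluded with a warning
  r3 <- rbind(r, toy_ratings("u3", c("d01", "d02"), c(5, 5)))
  expect_warning(rep3 <- system_vs_rater_concordance(sys, read_ratings(r3)),
                 class = "readrank_excluded_raters")
  expect_equal(rep3$n_raters, 2L)
  expect_equal(rep3$excluded_raters, "u3")

  expect_error(
    suppressWarnings(system_vs_rater_concordance(
      sys, read_ratings(toy_ratings("u9", c("d01", "d02"), c(3, 3))))),
    class = "readrank_bad_rankings")
})

test_that("fkgl baseline shares the protocol and hits 1 when raters follow fkgl", {
  txts <- list(
    easy = "cat sat. dog ran. sun up.",
    mid = "patient reports feeling better today overall.",
    hard = paste("comprehensive pathophysiological deterioration necessitating",
                 "multidisciplinary rehabilitation evaluation immediately"))
  docs <- Map(function(id, t) tokenize(document(id, t)), names(txts), txts)
  grades <- vapply(docs, fkgl, 1.0)
  ord <- names(sort(grades))
  r <- read_ratings(
    toy_ratings("u1", c(ord[1], ord[2], ord[1], ord[3]), c(2, 5, 2, 9)))
  rep <- fkgl_baseline_concordance(r, docs)
  expect_equal(rep$mean_w, 1)
  expect_error(fkgl_baseline_concordance(r, docs["easy"]),
               class = "readrank_missing_features")
})

test_that("wilcoxon comparison semantics", {
  w <- c(a = .5, b = .6, c = .7)
  expect_equal(wilcoxon_compare(w, w)$p_value, 1)
  expect_false(wilcoxon_compare(w, w)$significant)

  base <- runif(20, .3, .6)
  names(base) <- sprintf("r%02d", 1:20)
  up <- base + 0.2
  res <- wilcoxon_compare(up, base, alpha = 0.05)
  expect_true(res$significant)
  expect_lt(res$p_value, 0.001) # n=20 all-positive differences
  expect_false(wilcoxon_compare(up, base, alpha = 1e-9)$significant)
})

test_that("stratified split: proportions, determinism, per-stratum rounding", {
  ids <- sprintf("d%03d", 1:100)
  sp <- stratified_split(ids, seed = 4)
  expect_equal(as.integer(table(sp$partition)[c("train", "dev", "test")]),
               c(60L, 20L, 20L))
  expect_setequal(sp$doc_id, ids)
  sp2 <- stratified_split(ids, seed = 4)
  expect_identical(sp, sp2)

  # 10 docs per stratum x 3 strata -> 6/2/2 within each
  strata <- rep(c("cancer", "diabetes", "hypertension"), each = 10)
  ids30 <- sprintf("d%03d", 1:30)
  sp3 <- stratified_split(ids30, stratum_key = strata, seed = 9)
  tab <- table(sp3$stratum, sp3$partition)
  expect_true(all(tab[, "train"] == 6 & tab[, "dev"] == 2 & tab[, "test"] == 2))

  expect_warning(stratified_split(sprintf("d%d", 1:2), seed = 1),
                 class = "readrank_small_stratum")
  expect_error(stratified_split(ids, proportions = c(train = .5, dev = .2,
                                                     test = .2)),
               class = "readrank_bad_config")
})

test_that("split unit is the document: ratings follow their document", {
  st <- fix_tiny_study()
  tr <- split_ratings(st$ratings, st$split, "train")
  te <- split_ratings(st$ratings, st$split, "test")
  expect_length(intersect(tr$doc_id, te$doc_id), 0)
  train_ids <- st$split$doc_id[st$split$partition == "train"]
  expect_true(all(tr$doc_id %in% train_ids))
})

test_that("ablation harness structure: dropped blocks shrink the layout", {
  st <- fix_tiny_study()
  fz_full <- st$featurizer
  fz_noemb <- build_featurizer(st$frequency_table, easy_words = st$easy_words,
                               embedding_wiki = st$embedding_wiki,
                               embedding_ehr = st$embedding_ehr,
                               drop = "embedding")
  expect_equal(sum(fz_noemb$blocks), 16L)
  feats <- featurize_corpus(fz_noemb, st$docs)
  expect_equal(ncol(feats), 16L)
  expect_false(identical(fz_noemb$layout_version, fz_full$layout_version))
  expect_error(build_featurizer(st$frequency_table,
                                drop = c("formula", "frequency", "length",
                                         "embedding")),
               class = "readrank_bad_config")
  # retrained model has exactly the reduced number of weights
  tr <- split_ratings(st$ratings, st$split, "train")
  m <- suppressWarnings(fit_ranker(feats, tr, C = 1))
  expect_length(m$weights, 16L)
})
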