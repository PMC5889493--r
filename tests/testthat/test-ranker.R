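# pairwise example generation, the max-margin solver, scoring, ranking,
# and C tuning

test_that("pairwise examples: only same-rater, unequal-rating pairs", {
  X <- toy_features(c(1, 2, 3))
  r <- data.frame(rater_id = "u1", pair_id = rep(c("p1", "p2"), c(2, 2)),
                  doc_id = c("d01", "d02", "d03", "d01"),
                  rating = c(2L, 5L, 5L, 2L))
  # ratings: A=2, B=5, C=5 -> exactly A-B and A-C, none for B-C
  ex <- generate_pairwise_examples(r, X)
  expect_equal(nrow(ex$diff), 2L)
  expect_true(all(ex$rater_id == "u1"))

  # all-equal ratings -> zero examples
  r2 <- r
  r2$rating <- 4L
  expect_equal(nrow(generate_pairwise_examples(r2, X)$diff), 0L)

  # n documents, all-distinct ratings -> n(n-1)/2 examples
  n <- 6
  Xn <- toy_features(seq_len(n))
  rn <- toy_ratings("u9", rownames(Xn), seq_len(n))
  expect_equal(nrow(generate_pairwise_examples(rn, Xn)$diff), n * (n - 1) / 2)

  # two raters never mix
  r_two <- rbind(rn, toy_ratings("u8", rownames(Xn), rev(seq_len(n))))
  ex2 <- generate_pairwise_examples(r_two, Xn)
  expect_equal(nrow(ex2$diff), n * (n - 1))
  expect_setequal(unique(ex2$rater_id), c("u9", "u8"))

  expect_error(generate_pairwise_examples(
    data.frame(rater_id = "u", pair_id = "p", doc_id = "nope", rating = 3L), X),
    "nope", class = "readrank_missing_features")
})

test_that("difference vectors are oriented harder minus easier", {
  X <- toy_features(c(10, 20))
  r <- toy_ratings("u1", c("d01", "d02"), c(9, 2)) # d01 harder
  ex <- generate_pairwise_examples(r, X)
  expect_equal(as.numeric(ex$diff), 10 - 20)
})

test_that("1-D separable toy: positive weight, zero discordant at large C", {
  X <- matrix(c(2, 1, 0.5, 3), ncol = 1)
  attr(X, "layout_version") <- "toy1"
  m <- train_ranker(X, C = 100)
  expect_gt(m$weights, 0)
  expect_equal(m$diagnostics$n_discordant_on_train, 0L)
  # analytic solution: margin constraint w * min(diff) >= 1 -> w = 1/0.5 = 2
  expect_equal(m$weights, 2, tolerance = 1e-3)
})

test_that("training matches the brute-force grid oracle on toy sets", {
  set.seed(31)
  for (trial in 1:6) {
    d <- sample(1:3, 1)
    n <- sample(4:10, 1)
    X <- matrix(round(rnorm(n * d), 2), n, d)
    # plant a direction so examples are mostly (not perfectly) consistent
    w_true <- rnorm(d)
    X <- X + 0.8 * matrix(rep(w_true, each = n), n, d)
    C <- sample(c(0.3, 1, 3), 1)
    fit <- train_ranker(X, C = C, tol = 1e-6, max_epochs = 50000)
    oracle <- grid_svm_oracle(X, C)
    f_fit <- svm_objective(fit$weights, X, C)
    # the exact solver should never lose to the grid search, and should
    # be within its resolution
    expect_lte(f_fit, oracle$objective + 1e-6)
    expect_lt(abs(f_fit - oracle$objective), 0.01 * max(1, oracle$objective))
    # same discordant count and same induced ordering on a probe set
    probe <- matrix(rnorm(8 * d), 8, d)
    expect_equal(order(probe %*% fit$weights), order(probe %*% oracle$w))
    expect_equal(sum(X %*% fit$weights <= 0), sum(X %*% oracle$w <= 0))
  }
})

test_that("mirrored two-class encoding is equivalent to single orientation", {
  set.seed(12)
  X <- matrix(rnorm(18), 6, 3) + 1
  single <- readrank:::.svm_dcd
  fit1 <- single(X, rep(1, 6), 2, 50000L, 1e-8, 1L)
  Xm <- rbind(X, -X)
  fit2 <- single(Xm, c(rep(1, 6), rep(-1, 6)), 1, 50000L, 1e-8, 1L) # C halves
  expect_equal(as.numeric(fit1$weights), as.numeric(fit2$weights),
               tolerance = 1e-4)
})

test_that("antisymmetry: reversing all orientations negates the solution", {
  set.seed(13)
  X <- matrix(rnorm(24), 8, 3) + 0.7
  f1 <- train_ranker(X, C = 1, tol = 1e-8, max_epochs = 50000)
  f2 <- train_ranker(-X, C = 1, tol = 1e-8, max_epochs = 50000)
  expect_equal(f1$weights, -f2$weights, tolerance = 1e-4)
})

test_that("scale property: rescaled features preserve the induced ranking", {
  set.seed(14)
  X <- matrix(rnorm(30), 10, 3) + 0.5
  probe <- matrix(rnorm(15), 5, 3)
  rownames(probe) <- letters[1:5]
  f1 <- train_ranker(X, C = 1, tol = 1e-8, max_epochs = 50000)
  f2 <- train_ranker(3 * X, C = 1, tol = 1e-8, max_epochs = 50000)
  expect_equal(order(probe %*% f1$weights), order(probe %*% f2$weights))
})

test_that("duplication leaves the induced ranking unchanged", {
  set.seed(15)
  X <- matrix(rnorm(24), 8, 3) + 0.6
  probe <- matrix(rnorm(15), 5, 3)
  f1 <- train_ranker(X, C = 1, tol = 1e-8, max_epochs = 50000)
  f2 <- train_ranker(rbind(X, X), C = 0.5, tol = 1e-8, max_epochs = 50000)
  expect_equal(order(probe %*% f1$weights), order(probe %*% f2$weights))
})

test_that("score is a linear functional with layout checking", {
  m <- readrank:::new_rank_model(weights = c(1, -2), c_tradeoff = 1,
                                 layout_version = "toy2",
                                 diagnostics = list())
  expect_equal(score(m, c(3, 1)), 1)
  x1 <- c(3, 1); x2 <- c(1, 1)
  expect_equal(score(m, x1) - score(m, x2), score(m, x1 - x2))
  z <- m; z$weights <- c(0, 0)
  expect_equal(score(z, matrix(rnorm(10), 5, 2)), rep(0, 5),
               ignore_attr = TRUE)
  expect_error(score(m, c(1, 2, 3)), class = "readrank_layout_mismatch")
  Xwrong <- matrix(1, 2, 2)
  attr(Xwrong, "layout_version") <- "other"
  expect_error(score(m, Xwrong), class = "readrank_layout_mismatch")
})

test_that("rank_documents: descending, deterministic tie-break, stable", {
  m <- readrank:::new_rank_model(weights = 1, c_tradeoff = 1,
                                 layout_version = "toy1",
                                 diagnostics = list())
  X <- toy_features(c(3.2, 1.1, 3.2))
  rk <- rank_documents(m, X)
  expect_equal(rk$doc_id, c("d01", "d03", "d02")) # tie d01/d03 -> lexicographic
  expect_equal(rk$rank, 1:3)
  Xp <- X[c(3, 1, 2), , drop = FALSE]
  attr(Xp, "layout_version") <- "toy1"
  expect_equal(rank_documents(m, Xp)$doc_id, rk$doc_id)

  Xsame <- toy_features(c(1, 1, 1, 1))
  expect_equal(rank_documents(m, Xsame)$doc_id, rownames(Xsame))
})

test_that("degenerate training inputs are hard errors", {
  Z <- matrix(0, 4, 2)
  expect_error(train_ranker(Z, C = 1), class = "readrank_degenerate_examples")
  expect_error(train_ranker(matrix(1, 0, 2), C = 1),
               class = "readrank_no_examples")
  expect_error(train_ranker(matrix(1, 2, 2), C = -1),
               class = "readrank_bad_config")
})

test_that("tune_c: tie to smallest C, trivial grid, empty dev error", {
  X <- toy_features(seq(1, 8))
  r_tr <- toy_ratings("u1", rownames(X), c(1, 2, 3, 4, 5, 6, 7, 8))
  r_dv <- toy_ratings("u2", rownames(X), c(1, 2, 3, 4, 5, 6, 7, 8))
  ex <- generate_pairwise_examples(r_tr, X)
  one <- tune_c(ex, r_dv, X, c_grid = 0.5)
  expect_equal(one$best_c, 0.5)
  # perfectly separable 1-D world: every C ranks perfectly -> smallest wins
  tuned <- tune_c(ex, r_dv, X, c_grid = c(10, 0.1, 1))
  expect_equal(tuned$best_c, 0.1)
  expect_true(all(tuned$dev_w == tuned$dev_w[1]))
  expect_error(tune_c(ex, r_dv[0, ], X, c_grid = 1),
               class = "readrank_bad_config")
  expect_error(tune_c(ex, r_dv, X, c_grid = numeric(0)),
               class = "readrank_bad_config")
})

test_that("fit_ranker stores standardization and scores new documents", {
  st <- fix_tiny_study()
  tr <- split_ratings(st$ratings, st$split, "train")
  m <- suppressWarnings(fit_ranker(st$features, tr, C = 1))
  expect_length(m$center, ncol(st$features))
  expect_length(m$scale, ncol(st$features))
  s <- score(m, st$features)
  expect_length(s, nrow(st$features))
  expect_false(anyNA(s))
})
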