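# tokenization, syllables, readability formulas, frequency bins, lengths

test_that("tokenizer handles clinical text, lists, and degenerate input", {
  d <- tokenize(document("d", "BP 140/90. Continue lisinopril."))
  expect_identical(d$tokens, c("BP", "140/90", "Continue", "lisinopril"))
  expect_equal(nrow(d$sentences), 2L)
  expect_identical(d$sentences[, "start"], c(1L, 3L))

  expect_error(tokenize(document("e", "")),
               class = "readrank_degenerate_document")
  expect_error(tokenize(document("e", "  \n\t ")),
               class = "readrank_degenerate_document")

  # newline-separated list items become one sentence per line
  lst <- tokenize(document("l", "aspirin 81 mg\nmetformin 500 mg\nlisinopril"))
  expect_equal(nrow(lst$sentences), 3L)
  # spans partition the token list
  spans <- lst$sentences
  expect_equal(unname(spans[1, "start"]), 1L)
  expect_equal(unname(spans[nrow(spans), "end"]), length(lst$tokens))
  expect_true(all(spans[-1, "start"] == head(spans[, "end"], -1) + 1L))

  # punct-only mode keeps the list on one line
  lst2 <- tokenize(document("l", "one two\nthree four"), sentence_split = "punct")
  expect_equal(nrow(lst2$sentences), 1L)
})

test_that("syllable counting: dictionary, heuristic, floor of one", {
  expect_equal(count_syllables("a"), 1L)
  expect_equal(count_syllables("HTN"), 1L)      # vowel-free -> floor 1
  expect_equal(count_syllables("readability"), 5L)
  expect_equal(count_syllables("make"), 1L)     # silent e
  expect_equal(count_syllables("little"), 2L)   # -le keeps its syllable
  expect_equal(count_syllables("three"), 1L)
  expect_equal(count_syllables("hypertension"), 4L)
  expect_equal(count_syllables("different"), 3L) # exception table
})

test_that("formula features match hand arithmetic and the >3 syllable rule", {
  stats <- list(n_tokens = 20L, n_sentences = 2L, n_syllables = 30L,
                n_polysyllabic = 0L, n_difficult = 5L)
  f <- formula_features(stats)
  expect_equal(unname(f[c(1, 2, 4)]), c(10, 1.5, 25))

  # a word with exactly 3 syllables is NOT polysyllabic
  d <- tokenize(document("p", "banana banana banana."))  # 3 syllables each
  s <- surface_stats(d, easy_words_from_vector("banana"))
  expect_equal(s$n_polysyllabic, 0L)
  d2 <- tokenize(document("p", "universities banana."))
  s2 <- surface_stats(d2, easy_words_from_vector("x"))
  expect_equal(s2$n_polysyllabic, 1L) # universities (5) yes, banana (3) no

  # all monosyllabic -> proportion 0
  d3 <- tokenize(document("p", "cat dog fish."))
  expect_equal(formula_features(surface_stats(d3))[["polysyllabic_prop"]], 0)

  # numerals count as easy
  d4 <- tokenize(document("n", "120/80 7 zzz."))
  s4 <- surface_stats(d4, easy_words_from_vector("the"))
  expect_equal(s4$n_difficult, 1L)
})

test_that("fkgl matches the standard coefficients and is deterministic", {
  # 10 words, 1 sentence, 15 syllables -> 0.39*10 + 11.8*1.5 - 15.59 = 6.01
  d <- tokenize(document("f", "momo momo momo momo momo one two three four five."))
  # momo = 2 syllables x5 = 10, one two three four five = 5 -> 15 syllables
  expect_equal(sum(readrank:::count_syllables_vec(d$tokens)), 15L)
  expect_equal(fkgl(d), 0.39 * 10 + 11.8 * 1.5 - 15.59, tolerance = 1e-12)
  expect_identical(fkgl(d), fkgl(d))
})

test_that("frequency table builds decile bins; 1000 distinct types -> 100 per bin", {
  counts <- seq_len(1000) + 0 # distinct frequencies 1..1000
  names(counts) <- sprintf("w%04d", 1:1000)
  tab <- build_frequency_table(counts)
  bins <- readrank:::freq_bin_index(log(as.numeric(counts)), tab)
  expect_equal(as.integer(table(bins)), rep(100L, 10))

  expect_error(build_frequency_table(counts[1:9]),
               class = "readrank_too_few_types")
})

test_that("frequency-bin features: proportions, OOV rule, hand count", {
  counts <- seq_len(1000) + 0
  names(counts) <- sprintf("w%04d", 1:1000)
  tab <- build_frequency_table(counts)

  # tokens all in the top decile
  d <- tokenize(document("d", "w1000 w0999 w0995."))
  f <- frequency_bin_features(d, tab)
  expect_equal(unname(f[10]), 1)
  expect_equal(sum(f), 1)

  # out-of-vocabulary token lands in the lowest-frequency bin
  d2 <- tokenize(document("d", "neverseen w1000."))
  f2 <- frequency_bin_features(d2, tab)
  expect_equal(unname(f2[c(1, 10)]), c(0.5, 0.5))

  # brute-force hand count on a small table
  d3 <- tokenize(document("d", "w0001 w0050 w0150 w0500 w0850 w1000."))
  f3 <- frequency_bin_features(d3, tab)
  expected_bins <- ceiling(c(1, 50, 150, 500, 850, 1000) / 100)
  brute <- tabulate(expected_bins, 10) / 6
  expect_equal(unname(f3), brute)
})

test_that("length features and admission errors", {
  d <- tokenize(document("d", paste0(paste(rep("tok", 20), collapse = " "), ".\n",
                                     "more line here")))
  lf <- length_features(d)
  expect_equal(unname(lf), c(23, 2))
  dd <- tokenize(document("d2", paste(rep(d$text, 2), collapse = "\n")))
  expect_equal(unname(length_features(dd)), 2 * unname(lf))
})

test_that("full feature vector: length 416, no NaN, freq block sums to 1", {
  st <- fix_tiny_study()
  expect_equal(ncol(st$features), 416L)
  expect_false(anyNA(st$features))
  expect_true(all(is.finite(st$features)))
  freq_cols <- grep("^freq_bins", colnames(st$features))
  expect_equal(length(freq_cols), 10L)
  expect_equal(unname(rowSums(st$features[, freq_cols])),
               rep(1, nrow(st$features)), tolerance = 1e-12)
})

test_that("formula and fkgl are invariant to token order within sentences", {
  txt1 <- "alpha beta gamma delta. epsilon zeta eta theta."
  txt2 <- "delta gamma beta alpha. theta eta zeta epsilon."
  d1 <- tokenize(document("a", txt1))
  d2 <- tokenize(document("b", txt2))
  expect_equal(fkgl(d1), fkgl(d2))
  expect_equal(unname(formula_features(surface_stats(d1))),
               unname(formula_features(surface_stats(d2))))
})

test_that("bin occupancy conservation over the table's own corpus", {
  st <- fix_tiny_study()
  tab <- st$frequency_table
  # token-weighted sum of per-document bin proportions == corpus-level
  # occupancy of the bins
  occ <- rep(0, 10)
  total <- 0
  for (d in st$docs) {
    n <- length(d$tokens)
    occ <- occ + n * frequency_bin_features(d, tab)
    total <- total + n
  }
  low <- tolower(unlist(lapply(st$docs, `[[`, "tokens")))
  cnt <- tab$counts[low]
  cnt[is.na(cnt)] <- 0
  bins <- ifelse(cnt == 0, 1L,
                 readrank:::freq_bin_index(log(as.numeric(cnt)), tab))
  expect_equal(unname(occ / total), unname(tabulate(bins, 10) / total))
})
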