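# Synthetic study generator.
#
# No annotated corpus of this kind is publicly available, so the package
# ships a generator that emulates the whole study design: a two-source
# (wikipedia/ehr), three-topic corpus of pseudo-word documents with a
# *planted* latent difficulty, and simulated crowd raters who score
# side-by-side document pairs on the 1-10 scale. Difficulty is planted
# through jargon density (rare, long pseudo-jargon plus abbreviations),
# sentence length, and abbreviation rate; raters apply a noisy affine map
# of the latent difficulty (eccentric raters a reversed one). Pairs
# respect the study's matching constraints: within 50 tokens of length
# and within 0.5 FKGL grade, with a 5 wiki-wiki / 5 ehr-ehr / 10 mixed
# composition per 20-pair rater.
#
# The "vocabulary" preset plants difficulty purely in *which* words are
# used: both lexicons share the same word-length and frequency profiles
# and sentence length is held constant, so surface formulas carry no
# signal and only distributional (embedding) features can recover the
# planted order.

#' Build a synthetic study configuration
#'
#' @param preset `"tiny"` (fast unit-test scale), `"default"`,
#'   `"vocabulary"` (difficulty planted only in word identity),
#'   `"recovery"` (strictly monotone raters: no per-rater offset and a
#'   rating slope auto-scaled so the affine map never saturates the 1-10
#'   scale — the parameter-recovery world), or `"paper_scale"` (90
#'   raters, 900 pairs, ~930 documents).
#' @param ... overrides for any configuration field (see Details).
#' @return a `readrank_study_config` list.
#' @details Fields: `n_per_cell` documents per source x topic cell;
#'   lexicon sizes; `jargon_density_range`, `sentence_len_range` (per-doc
#'   mean words/sentence), `abbrev_rate` per source; `target_tokens_range`;
#'   `n_raters`, `pairs_per_rater`, `composition` (wiki/ehr/mixed pair
#'   counts), `noise_sd` (rater noise in latent-SD units),
#'   `eccentric_fraction`, `rater_offset_sd`, `rating_slope` (`NA` =
#'   auto-span the affine map over 1-10 without clipping), `rating_model`
#'   (`"affine"`: clipped affine map of latent + noise; `"quantile"`: the
#'   rater spreads ratings over the deciles of their own document
#'   sample), `vocabulary_driven`, `seed`.
#' @export
study_config <- function(preset = c("default", "tiny", "vocabulary",
                                    "recovery", "paper_scale"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    topics = c("cancer", "diabetes", "hypertension"),
    n_per_cell = 25L,
    easy_lexicon_size = 150L,
    hard_lexicon_size = 300L,
    n_abbrev = 40L,
    jargon_density_range = c(0.05, 0.5),
    sentence_len_range = c(6, 18),
    target_tokens_range = c(170L, 240L),
    abbrev_rate = list(wikipedia = c(0, 0.02), ehr = c(0.04, 0.12)),
    n_raters = 20L,
    pairs_per_rater = 20L,
    composition = c(wiki = 5L, ehr = 5L, mixed = 10L),
    noise_sd = 0.5,
    eccentric_fraction = 0,
    rater_offset_sd = 0.5,
    rating_slope = 2.0,
    rating_model = "affine",
    vocabulary_driven = FALSE,
    seed = 1L
  )
  if (preset == "tiny") {
    cfg$n_per_cell <- 8L
    cfg$easy_lexicon_size <- 40L
    cfg$hard_lexicon_size <- 60L
    cfg$n_abbrev <- 12L
    cfg$n_raters <- 6L
    cfg$pairs_per_rater <- 8L
    cfg$composition <- c(wiki = 2L, ehr = 2L, mixed = 4L)
  } else if (preset == "vocabulary") {
    cfg$vocabulary_driven <- TRUE
    cfg$easy_lexicon_size <- 200L
    cfg$hard_lexicon_size <- 200L
    cfg$n_abbrev <- 0L
    cfg$jargon_density_range <- c(0.05, 0.95)
    cfg$sentence_len_range <- c(12, 12)
    cfg$abbrev_rate <- list(wikipedia = c(0, 0), ehr = c(0, 0))
  } else if (preset == "recovery") {
    cfg$rater_offset_sd <- 0
    cfg$rating_model <- "quantile" # strictly monotone up to decile rounding
    cfg$noise_sd <- 0
    cfg$n_raters <- 90L # the emulated study's rater count
  } else if (preset == "paper_scale") {
    cfg$n_per_cell <- 155L
    cfg$n_raters <- 90L
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    rr_error("readrank_bad_config", sprintf("unknown config field '%s'", bad[1]))
  cfg[names(over)] <- over
  if (sum(cfg$composition) != cfg$pairs_per_rater)
    rr_error("readrank_bad_config",
             "pair composition must sum to pairs_per_rater")
  if (any(c(cfg$n_per_cell, cfg$n_raters, cfg$pairs_per_rater) < 1L))
    rr_error("readrank_bad_config", "counts must be positive")
  if (cfg$easy_lexicon_size < 10L || cfg$hard_lexicon_size < 10L)
    rr_error("readrank_bad_config", "lexicon sizes must be >= 10")
  structure(cfg, class = "readrank_study_config")
}

# Pseudo-word sampling from syllable templates.
rr_pseudo_words <- function(n, syllable_range, long_syllables = FALSE) {
  onsets <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
              "v", "z", "br", "cl", "dr", "gl", "pr", "st", "tr")
  vowels <- c("a", "e", "i", "o", "u")
  codas <- if (long_syllables)
    c("", "n", "r", "s", "x", "ct", "nt", "rm", "st") else c("", "n", "s")
  out <- character(0)
  while (length(out) < n) {
    k <- sample(seq(syllable_range[1], syllable_range[2]), 1)
    w <- paste(vapply(seq_len(k), function(i)
      paste0(sample(onsets, 1), sample(vowels, 1), sample(codas, 1)), ""),
      collapse = "")
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

rr_lexicons <- function(config) {
  if (config$vocabulary_driven) {
    # one pool, randomly halved: identical length and frequency profiles,
    # difficulty carried only by which half a word belongs to
    pool <- rr_pseudo_words(config$easy_lexicon_size + config$hard_lexicon_size,
                            c(2, 3))
    pool <- sample(pool)
    easy <- pool[seq_len(config$easy_lexicon_size)]
    hard <- pool[-seq_len(config$easy_lexicon_size)]
    abbrev <- character(0)
  } else {
    easy <- rr_pseudo_words(config$easy_lexicon_size, c(1, 2))
    hard <- setdiff(rr_pseudo_words(config$hard_lexicon_size + 50, c(4, 6),
                                    long_syllables = TRUE), easy)
    hard <- hard[seq_len(config$hard_lexicon_size)]
    cons <- strsplit("BCDFGHJKLMNPQRSTVWXZ", "")[[1]]
    abbrev <- character(0)
    while (length(abbrev) < config$n_abbrev) {
      a <- paste(sample(cons, sample(2:4, 1), replace = TRUE), collapse = "")
      abbrev <- unique(c(abbrev, a))
    }
  }
  list(easy = easy, hard = hard, abbrev = abbrev,
       easy_w = 1 / seq_along(easy), hard_w = 1 / seq_along(hard))
}

# The stated latent difficulty model: monotone in jargon density, mean
# sentence length, and abbreviation rate. Computed from the *realized*
# document (raters respond to the text actually in front of them, not to
# the sampling dials): d = fraction of hard-lexicon tokens, s = realized
# mean tokens per sentence, a = fraction of abbreviation tokens.
rr_latent <- function(d, s_mean, a_rate) {
  5 * d + 0.1 * s_mean + 3 * a_rate
}

#' Generate a synthetic corpus with planted latent difficulty
#'
#' @param config a `readrank_study_config`.
#' @param seed integer seed (default taken from the config); identical
#'   seeds give byte-identical corpora.
#' @return list: `docs` (named list of tokenized documents), `latent`
#'   (named numeric, the hidden difficulty), `lexicons`, `params`
#'   (per-document jargon density, mean sentence length, abbreviation
#'   rate).
#' @export
generate_corpus <- function(config, seed = config$seed) {
  set.seed(derive_seed(seed, "corpus"))
  lex <- rr_lexicons(config)
  docs <- list()
  latent <- numeric(0)
  params <- data.frame()
  for (source in c("wikipedia", "ehr")) {
    for (topic in config$topics) {
      for (i in seq_len(config$n_per_cell)) {
        doc_id <- sprintf("%s_%s_%03d", substr(source, 1, 4),
                          substr(topic, 1, 4), i)
        d <- runif(1, config$jargon_density_range[1],
                   config$jargon_density_range[2])
        s_mean <- runif(1, config$sentence_len_range[1],
                        config$sentence_len_range[2])
        ar <- config$abbrev_rate[[source]]
        a_rate <- if (length(lex$abbrev)) runif(1, ar[1], ar[2]) else 0
        target <- sample(seq(config$target_tokens_range[1],
                             config$target_tokens_range[2]), 1)
        sents <- list()
        total <- 0L
        n_hard <- 0L
        n_abbr <- 0L
        while (total < target) {
          len <- max(2L, rpois(1, s_mean))
          hard_slot <- runif(len) < d
          abbr_slot <- length(lex$abbrev) > 0 & runif(len) < a_rate
          words <- sample(lex$easy, len, replace = TRUE, prob = lex$easy_w)
          if (any(hard_slot))
            words[hard_slot] <- sample(lex$hard, sum(hard_slot),
                                       replace = TRUE, prob = lex$hard_w)
          if (any(abbr_slot))
            words[abbr_slot] <- sample(lex$abbrev, sum(abbr_slot),
                                       replace = TRUE)
          sents[[length(sents) + 1L]] <- words
          total <- total + len
          n_hard <- n_hard + sum(hard_slot & !abbr_slot)
          n_abbr <- n_abbr + sum(abbr_slot)
        }
        render <- vapply(sents, function(ws) {
          s <- paste(ws, collapse = " ")
          paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
        }, "")
        text <- if (source == "ehr") {
          # clinical-note flavor: some sentences as bare list lines
          as_line <- runif(length(render)) < 0.5
          paste(ifelse(as_line, paste0("- ", render),
                       paste0(render, ".")), collapse = "\n")
        } else {
          paste0(paste(render, collapse = ". "), ".")
        }
        doc <- tokenize(document(doc_id, text, source, topic))
        docs[[doc_id]] <- doc
        d_real <- n_hard / total
        s_real <- total / length(sents)
        a_real <- n_abbr / total
        latent[doc_id] <- rr_latent(d_real, s_real, a_real)
        params <- rbind(params, data.frame(
          doc_id = doc_id, source = source, topic = topic,
          jargon_density = d_real, sentence_len = s_real,
          abbrev_rate = a_real, jargon_density_drawn = d,
          sentence_len_drawn = s_mean, abbrev_rate_drawn = a_rate,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(docs = docs, latent = latent, lexicons = lex, params = params)
}

# Eligible pair pools per composition category under the matching
# constraints |delta tokens| <= 50 and |delta FKGL| <= 0.5.
rr_pair_pools <- function(docs, max_token_diff = 50, max_fkgl_diff = 0.5) {
  ids <- names(docs)
  ntok <- vapply(docs, function(d) length(d$tokens), 1L)
  grade <- vapply(docs, fkgl, 1.0)
  src <- vapply(docs, `[[`, "", "source")
  ok <- function(i, j) {
    abs(ntok[i] - ntok[j]) <= max_token_diff &
      abs(grade[i] - grade[j]) <= max_fkgl_diff
  }
  pool_within <- function(s) {
    k <- which(src == s)
    if (length(k) < 2) return(matrix(integer(0), ncol = 2))
    cmb <- utils::combn(k, 2)
    keep <- ok(cmb[1, ], cmb[2, ])
    t(cmb[, keep, drop = FALSE])
  }
  kw <- which(src == "wikipedia")
  ke <- which(src == "ehr")
  mixed <- as.matrix(expand.grid(kw, ke))
  mixed <- mixed[ok(mixed[, 1], mixed[, 2]), , drop = FALSE]
  list(wiki = pool_within("wikipedia"), ehr = pool_within("ehr"),
       mixed = unname(mixed), ids = ids)
}

#' Simulate crowd raters over a synthetic corpus
#'
#' Each rater receives `pairs_per_rater` document pairs respecting the
#' source composition and the length/FKGL matching constraints (sampled
#' without replacement within a rater, with replacement across raters, so
#' most documents collect 2 or more ratings). A rating is the clipped
#' 1-10 rounding of an affine map of the standardized latent difficulty
#' plus Gaussian noise and a per-rater offset; eccentric raters apply the
#' reversed map. The eccentric count is `round(eccentric_fraction *
#' n_raters)`.
#'
#' @param corpus output of [generate_corpus()].
#' @param config the study configuration.
#' @param seed integer seed (default from config).
#' @return list: `ratings` (validated data.frame), `eccentric` (rater
#'   ids).
#' @export
simulate_raters <- function(corpus, config, seed = config$seed) {
  set.seed(derive_seed(seed, "raters"))
  pools <- rr_pair_pools(corpus$docs)
  need <- config$composition
  for (cat in names(need)) {
    if (nrow(pools[[cat]]) < need[[cat]])
      rr_error("readrank_pair_pool_exhausted", sprintf(
        "only %d eligible %s pair(s) for %d needed; loosen constraints or enlarge the corpus",
        nrow(pools[[cat]]), cat, need[[cat]]))
  }
  lz <- as.numeric(scale(corpus$latent))
  names(lz) <- names(corpus$latent)
  slope <- config$rating_slope
  if (is.na(slope)) slope <- 4.49 / max(abs(lz)) # affine map spans 1..10 clip-free
  n_ecc <- round(config$eccentric_fraction * config$n_raters)
  rater_ids <- sprintf("r%03d", seq_len(config$n_raters))
  eccentric <- if (n_ecc > 0) sample(rater_ids, n_ecc) else character(0)
  rows <- vector("list", config$n_raters)
  for (r in seq_len(config$n_raters)) {
    rid <- rater_ids[r]
    sgn <- if (rid %in% eccentric) -1 else 1
    offset <- rnorm(1, 0, config$rater_offset_sd)
    pair_doc <- character(0)
    pair_id <- character(0)
    pair_no <- 0L
    for (cat in names(need)) {
      take <- pools[[cat]][sample(nrow(pools[[cat]]), need[[cat]]), ,
                           drop = FALSE]
      for (p in seq_len(nrow(take))) {
        pair_no <- pair_no + 1L
        pid <- sprintf("%s_p%02d", rid, pair_no)
        pair_doc <- c(pair_doc, pools$ids[take[p, ]])
        pair_id <- c(pair_id, pid, pid)
      }
    }
    # one perceived difficulty per rater x document: a rater who meets the
    # same document in two pairs rates it consistently
    uids <- unique(pair_doc)
    perceived <- sgn * (lz[uids] + rnorm(length(uids), 0, config$noise_sd))
    rating_of <- if (identical(config$rating_model, "quantile")) {
      # range-frequency response: the rater spreads ratings over the
      # deciles of their own sample; strictly monotone up to rounding
      as.integer(ceiling(10 * rank(perceived, ties.method = "average") /
                           length(perceived)))
    } else {
      as.integer(pmin(pmax(round(5.5 + slope * perceived + offset), 1), 10))
    }
    names(rating_of) <- uids
    rows[[r]] <- data.frame(rater_id = rid, pair_id = pair_id,
                            doc_id = pair_doc,
                            rating = unname(rating_of[pair_doc]),
                            stringsAsFactors = FALSE)
  }
  ratings <- do.call(rbind, rows)
  rownames(ratings) <- NULL
  list(ratings = read_ratings(ratings), eccentric = eccentric)
}

#' Simulate a complete study in memory
#'
#' Corpus, latent difficulties, ratings, a topic-stratified 60/20/20
#' document split, the corpus frequency table, the generator's own easy
#' lexicon as easy-word list, and (optionally) the two source-specific
#' embeddings.
#'
#' @param config a `readrank_study_config` (or preset name string).
#' @param seed integer global seed; fans out to per-stage seeds.
#' @param embeddings train the two skip-gram embeddings (default TRUE;
#'   set FALSE when only corpus/ratings structure is needed).
#' @param embedding_dim embedding dimension (default 200, the study
#'   layout).
#' @return a study list consumable by [ablation_run()] and friends:
#'   `docs`, `latent`, `params`, `ratings`, `eccentric`, `split`,
#'   `frequency_table`, `easy_words`, `embedding_wiki`, `embedding_ehr`,
#'   `config`, `seed`.
#' @export
simulate_study <- function(config = study_config("default"), seed = NULL,
                           embeddings = TRUE, embedding_dim = 200L) {
  if (is.character(config)) config <- study_config(config)
  seed <- seed %||% config$seed
  corpus <- generate_corpus(config, seed = seed)
  sim <- simulate_raters(corpus, config, seed = seed)
  split <- stratified_split(corpus$docs, seed = derive_seed(seed, "split"))
  ft <- build_frequency_table(corpus$docs)
  easy <- easy_words_from_vector(
    if (config$vocabulary_driven)
      c(corpus$lexicons$easy, corpus$lexicons$hard)
    else corpus$lexicons$easy)
  ew <- ee <- NULL
  if (embeddings) {
    ew <- train_embedding(corpus$docs, "wikipedia", dim = embedding_dim,
                          seed = derive_seed(seed, "embed_wiki"))
    ee <- train_embedding(corpus$docs, "ehr", dim = embedding_dim,
                          seed = derive_seed(seed, "embed_ehr"))
  }
  list(docs = corpus$docs, latent = corpus$latent, params = corpus$params,
       lexicons = corpus$lexicons, ratings = sim$ratings,
       eccentric = sim$eccentric, split = split, frequency_table = ft,
       easy_words = easy, embedding_wiki = ew, embedding_ehr = ee,
       config = config, seed = seed)
}

#' Write a study fixture to disk
#'
#' Materializes the external interface of a study: a corpus directory
#' with `manifest.csv`, `ratings.csv`, the hidden `latent.csv` (for
#' oracle tests), `easy_words.txt`, `freq.tsv`, and `split.json`.
#'
#' @param config a `readrank_study_config` or preset name.
#' @param dir output directory.
#' @param seed integer seed.
#' @return invisibly, a list of the written paths plus the in-memory
#'   study (without embeddings).
#' @export
make_study_fixture <- function(config = study_config("tiny"), dir,
                               seed = NULL) {
  study <- simulate_study(config, seed = seed, embeddings = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corpus_dir <- file.path(dir, "corpus")
  write_corpus(study$docs, corpus_dir)
  write_ratings(study$ratings, file.path(dir, "ratings.csv"))
  write.csv(data.frame(doc_id = names(study$latent),
                       latent = unname(study$latent)),
            file.path(dir, "latent.csv"), row.names = FALSE)
  writeLines(unclass(study$easy_words), file.path(dir, "easy_words.txt"))
  write_frequency_counts(study$frequency_table$counts,
                         file.path(dir, "freq.tsv"))
  jsonlite::write_json(study$split, file.path(dir, "split.json"),
                       dataframe = "columns")
  invisible(list(dir = dir, corpus = corpus_dir,
                 manifest = file.path(corpus_dir, "manifest.csv"),
                 ratings = file.path(dir, "ratings.csv"),
                 latent = file.path(dir, "latent.csv"),
                 split = file.path(dir, "split.json"),
                 study = study))
}
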