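# Non-embedding feature families and feature-vector assembly.
#
# The default feature layout has five named blocks:
#   formula[4]    avg words/sentence, avg syllables/word,
#                 polysyllabic proportion (> 3 syllables),
#                 difficult-word percentage (off the easy-word list)
#   freq_bins[10] proportion of tokens in each corpus log-frequency decile
#   length[2]     token count, sentence count
#   embed_wiki[200], embed_ehr[200]
# for a total of 416 dimensions. Ablation drops whole blocks; the layout
# version string records exactly which blocks (and widths) are active so a
# model can never be applied to a mismatched feature order.

#' Surface statistics of a tokenized document
#'
#' @param doc a tokenized `readrank_document`.
#' @param easy a `readrank_easy_words` list (used for the difficult-word
#'   count); tokens that are purely numeric count as easy.
#' @return list with `n_tokens`, `n_sentences`, `n_syllables`,
#'   `n_polysyllabic` (words with more than 3 syllables), `n_difficult`.
#' @export
surface_stats <- function(doc, easy = default_easy_words()) {
  assert_tokenized(doc)
  syl <- count_syllables_vec(doc$tokens)
  low <- tolower(doc$tokens)
  numeric_tok <- grepl("^[0-9][0-9/.,-]*$", low)
  list(
    n_tokens = length(doc$tokens),
    n_sentences = nrow(doc$sentences),
    n_syllables = sum(syl),
    n_polysyllabic = sum(syl > 3L),
    n_difficult = sum(!(low %in% unclass(easy)) & !numeric_tok)
  )
}

assert_tokenized <- function(doc) {
  if (is.null(doc$tokens) || is.null(doc$sentences))
    rr_error("readrank_not_tokenized",
             sprintf("document '%s' must be tokenized first", doc$doc_id))
  if (length(doc$tokens) == 0L || nrow(doc$sentences) == 0L)
    rr_error("readrank_degenerate_document",
             sprintf("document '%s' has no tokens", doc$doc_id))
  invisible(doc)
}

#' Readability-formula features
#'
#' The four surface features borrowed from classic formulas: average words
#' per sentence and average syllables per word (Flesch-Kincaid), the
#' proportion of polysyllabic words — strictly more than 3 syllables —
#' (Gunning Fog), and the percentage of difficult words, i.e. words absent
#' from the easy-word list (New Dale-Chall).
#'
#' @param stats a [surface_stats()] list.
#' @return numeric vector of length 4 named
#'   `words_per_sentence`, `syllables_per_word`, `polysyllabic_prop`,
#'   `difficult_pct`.
#' @export
formula_features <- function(stats) {
  if (stats$n_sentences < 1L || stats$n_tokens < 1L)
    rr_error("readrank_degenerate_document", "zero tokens or sentences")
  c(words_per_sentence = stats$n_tokens / stats$n_sentences,
    syllables_per_word = stats$n_syllables / stats$n_tokens,
    polysyllabic_prop = stats$n_polysyllabic / stats$n_tokens,
    difficult_pct = 100 * stats$n_difficult / stats$n_tokens)
}

#' Flesch-Kincaid Grade Level
#'
#' `0.39 * words/sentence + 11.8 * syllables/word - 15.59`, unclipped (can
#' be negative for very simple text).
#'
#' @param doc a tokenized `readrank_document` (tokenized on the fly if
#'   needed).
#' @return grade level, a single number.
#' @export
fkgl <- function(doc) {
  if (is.null(doc$tokens)) doc <- tokenize(doc)
  assert_tokenized(doc)
  nw <- length(doc$tokens)
  ns <- nrow(doc$sentences)
  nsyl <- sum(count_syllables_vec(doc$tokens))
  0.39 * nw / ns + 11.8 * nsyl / nw - 15.59
}

#' Build a corpus word-frequency table with decile bins
#'
#' Counts lowercased tokens over the whole corpus (both sources combined
#' by default — a config input, so a general-English table can be supplied
#' instead) and places 11 bin edges at the deciles of the log-frequency
#' distribution over word *types*. Duplicate decile values (typical Zipf
#' tails where most types have count 1) are nudged so edges stay strictly
#' ascending; the affected bins are simply empty.
#'
#' @param corpus named list of tokenized documents, or a named numeric
#'   count vector from [read_frequency_counts()].
#' @return a `readrank_frequency_table` with `counts` and `bin_edges`.
#' @export
build_frequency_table <- function(corpus) {
  counts <- if (is.numeric(corpus)) corpus else {
    toks <- unlist(lapply(corpus, function(d) {
      assert_tokenized(d); tolower(d$tokens)
    }), use.names = FALSE)
    c(table(toks))
  }
  if (length(counts) < 10L)
    rr_error("readrank_too_few_types",
             sprintf("%d distinct types; need >= 10 to form 10 bins",
                     length(counts)))
  lf <- sort(log(as.numeric(counts)))
  n <- length(lf)
  edges <- numeric(11)
  edges[1] <- lf[1] - 1
  edges[11] <- lf[n] + 1
  for (j in 1:9) {
    k <- j * n / 10
    lo <- lf[max(1L, floor(k))]
    hi <- lf[min(n, floor(k) + 1L)]
    # ties spanning a cut all stay in the lower (rarer) bin
    edges[j + 1] <- if (hi > lo) (lo + hi) / 2 else lo + 1e-9
  }
  for (j in 2:11) {
    if (edges[j] <= edges[j - 1]) edges[j] <- edges[j - 1] + 1e-9
  }
  structure(list(counts = counts, bin_edges = edges),
            class = "readrank_frequency_table")
}

# Bin index in 1..10 for a log-frequency value; out-of-vocabulary tokens
# (count 0) always land in bin 1 (unseen ~ rarest).
freq_bin_index <- function(logfreq, table) {
  idx <- 1L + findInterval(logfreq, table$bin_edges[2:10], left.open = FALSE)
  pmin(pmax(idx, 1L), 10L)
}

#' Frequency-bin features of a document
#'
#' The proportion of the document's tokens whose corpus frequency falls in
#' each of the table's 10 bins; proportions sum to 1. Tokens absent from
#' the table are counted in the lowest-frequency bin.
#'
#' @param doc tokenized document.
#' @param table a `readrank_frequency_table`.
#' @return numeric vector of 10 proportions, names `freq_bin_1..10`.
#' @export
frequency_bin_features <- function(doc, table) {
  assert_tokenized(doc)
  if (!inherits(table, "readrank_frequency_table") || length(table$counts) == 0)
    rr_error("readrank_bad_frequency_table", "empty or invalid frequency table")
  low <- tolower(doc$tokens)
  cnt <- table$counts[low]
  cnt[is.na(cnt)] <- 0
  bins <- ifelse(cnt == 0, 1L, freq_bin_index(log(pmax(cnt, 1e-300)), table))
  out <- tabulate(bins, nbins = 10L) / length(bins)
  names(out) <- paste0("freq_bin_", 1:10)
  out
}

#' Length features (token and sentence counts)
#' @param doc tokenized document.
#' @return numeric vector `c(n_tokens, n_sentences)`.
#' @export
length_features <- function(doc) {
  assert_tokenized(doc)
  c(n_tokens = length(doc$tokens), n_sentences = nrow(doc$sentences))
}

DEFAULT_BLOCKS <- c(formula = 4L, freq_bins = 10L, length = 2L,
                    embed_wiki = 200L, embed_ehr = 200L)

layout_version_string <- function(blocks) {
  paste0("v1:", paste(sprintf("%s=%d", names(blocks), blocks), collapse = "+"))
}

#' Build a featurizer
#'
#' Bundles everything needed to map a document to its fixed-layout feature
#' vector: the easy-word list, the corpus frequency table, and the two
#' source-specific embeddings. Both embeddings are applied to *every*
#' document regardless of its own source, so documents of unknown
#' provenance can be scored at inference time.
#'
#' @param frequency_table `readrank_frequency_table`, or a tokenized corpus
#'   to build one from.
#' @param easy_words `readrank_easy_words` (default: bundled list).
#' @param embedding_wiki,embedding_ehr `readrank_embedding` models (NULL
#'   drops the corresponding block from the layout).
#' @param drop character vector of block groups to exclude: any of
#'   `"formula"`, `"frequency"`, `"length"`, `"embedding"`.
#' @return a `readrank_featurizer`.
#' @export
build_featurizer <- function(frequency_table, easy_words = default_easy_words(),
                             embedding_wiki = NULL, embedding_ehr = NULL,
                             drop = character()) {
  bad <- setdiff(drop, c("formula", "frequency", "length", "embedding"))
  if (length(bad))
    rr_error("readrank_bad_config", sprintf("unknown feature group '%s'", bad[1]))
  if (setequal(drop, c("formula", "frequency", "length", "embedding")))
    rr_error("readrank_bad_config", "cannot drop every feature group")
  if (!inherits(frequency_table, "readrank_frequency_table") &&
      !is.null(frequency_table))
    frequency_table <- build_frequency_table(frequency_table)
  blocks <- integer()
  if (!"formula" %in% drop) blocks["formula"] <- 4L
  if (!"frequency" %in% drop) blocks["freq_bins"] <- 10L
  if (!"length" %in% drop) blocks["length"] <- 2L
  if (!"embedding" %in% drop) {
    if (!is.null(embedding_wiki)) blocks["embed_wiki"] <- embedding_wiki$dim
    if (!is.null(embedding_ehr)) blocks["embed_ehr"] <- embedding_ehr$dim
  }
  if (length(blocks) == 0L)
    rr_error("readrank_bad_config", "featurizer has no active feature blocks")
  structure(
    list(blocks = blocks, layout_version = layout_version_string(blocks),
         frequency_table = frequency_table, easy_words = easy_words,
         embedding_wiki = embedding_wiki, embedding_ehr = embedding_ehr),
    class = "readrank_featurizer"
  )
}

#' @export
print.readrank_featurizer <- function(x, ...) {
  cat(sprintf("<featurizer %s> (%d dims)\n", x$layout_version, sum(x$blocks)))
  invisible(x)
}

#' Featurize one document
#'
#' @param featurizer a `readrank_featurizer`.
#' @param doc a `readrank_document` (tokenized on the fly if needed).
#' @return named numeric vector with attribute `layout_version`; length
#'   416 under the default layout, no NaN/NA entries, frequency-bin block
#'   summing to 1.
#' @export
featurize <- function(featurizer, doc) {
  stopifnot(inherits(featurizer, "readrank_featurizer"))
  if (is.null(doc$tokens)) doc <- tokenize(doc)
  assert_tokenized(doc)
  parts <- list()
  b <- featurizer$blocks
  if ("formula" %in% names(b)) {
    parts$formula <- formula_features(surface_stats(doc, featurizer$easy_words))
  }
  if ("freq_bins" %in% names(b)) {
    if (is.null(featurizer$frequency_table))
      rr_error("readrank_bad_frequency_table", "featurizer has no frequency table")
    parts$freq_bins <- frequency_bin_features(doc, featurizer$frequency_table)
  }
  if ("length" %in% names(b)) parts$length <- length_features(doc)
  if ("embed_wiki" %in% names(b)) {
    v <- embed_document(doc, featurizer$embedding_wiki)
    names(v) <- paste0("wiki_", seq_along(v))
    parts$embed_wiki <- v
  }
  if ("embed_ehr" %in% names(b)) {
    v <- embed_document(doc, featurizer$embedding_ehr)
    names(v) <- paste0("ehr_", seq_along(v))
    parts$embed_ehr <- v
  }
  out <- unlist(parts, use.names = TRUE)
  if (anyNA(out) || any(!is.finite(out)))
    rr_error("readrank_bad_features",
             sprintf("non-finite feature for document '%s'", doc$doc_id))
  attr(out, "layout_version") <- featurizer$layout_version
  out
}

#' Featurize a corpus into a matrix
#'
#' @param featurizer a `readrank_featurizer`.
#' @param docs named list of documents.
#' @return numeric matrix, one row per document (rownames = doc_id), with
#'   attribute `layout_version`.
#' @export
featurize_corpus <- function(featurizer, docs) {
  rows <- lapply(docs, function(d) featurize(featurizer, d))
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(docs, `[[`, "", "doc_id")
  attr(mat, "layout_version") <- featurizer$layout_version
  attr(mat, "blocks") <- featurizer$blocks
  mat
}
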