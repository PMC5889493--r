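# Source-specific skip-gram embeddings and document-level aggregation.
#
# Two 200-dimensional skip-gram models are trained separately on the
# Wikipedia-source and EHR-source halves of the corpus; both are applied
# to every document (a document's source is unknown at inference time).
# Training is the classic SGNS objective, single-threaded with an
# internal RNG, so identical corpus + seed gives identical vectors.

new_embedding <- function(vectors, source_tag, config = NULL) {
  structure(list(source_tag = source_tag, dim = ncol(vectors),
                 vectors = vectors, config = config),
            class = "readrank_embedding")
}

#' @export
print.readrank_embedding <- function(x, ...) {
  cat(sprintf("<embedding %s> %d types x %d dims\n", x$source_tag,
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Train a skip-gram embedding on one source's documents
#'
#' @param corpus named list of tokenized documents (pre-filtered to one
#'   source, or filtered here via `source_tag`).
#' @param source_tag `"wikipedia"` or `"ehr"`; documents of other sources
#'   are dropped before training.
#' @param dim vector dimension (default 200).
#' @param window maximum context window (dynamic, word2vec style).
#' @param min_count minimum token frequency to enter the vocabulary.
#' @param epochs training passes over the corpus.
#' @param negative negative samples per positive pair.
#' @param alpha initial learning rate.
#' @param seed integer seed; same corpus + seed reproduces the vectors
#'   bit-identically.
#' @return a `readrank_embedding` with a `vectors` matrix (rownames =
#'   vocabulary, lowercased).
#' @export
train_embedding <- function(corpus, source_tag = c("wikipedia", "ehr"),
                            dim = 200L, window = 5L, min_count = 2L,
                            epochs = 10L, negative = 5L, alpha = 0.025,
                            seed = 1L) {
  source_tag <- match.arg(source_tag)
  corpus <- Filter(function(d) d$source == source_tag, corpus)
  if (length(corpus) == 0L)
    rr_error("readrank_empty_corpus",
             sprintf("no documents with source '%s'", source_tag))
  sents <- unlist(lapply(corpus, function(d) {
    assert_tokenized(d)
    lapply(seq_len(nrow(d$sentences)), function(i)
      tolower(d$tokens[d$sentences[i, 1]:d$sentences[i, 2]]))
  }), recursive = FALSE)
  counts <- c(table(unlist(sents, use.names = FALSE)))
  vocab <- names(counts)[counts >= min_count]
  vocab <- sort(vocab) # stable order independent of table() internals
  if (length(vocab) == 0L)
    rr_error("readrank_empty_corpus",
             sprintf("no token reaches min_count=%d for source '%s'",
                     min_count, source_tag))
  id <- seq_along(vocab) - 1L
  names(id) <- vocab
  sent_ids <- lapply(sents, function(s) {
    v <- id[s]
    as.integer(v[!is.na(v)])
  })
  sent_ids <- sent_ids[vapply(sent_ids, length, 1L) > 1L]
  noise <- as.numeric(counts[vocab])^0.75
  noise_cum <- cumsum(noise / sum(noise))
  vec <- if (length(sent_ids) == 0L) {
    matrix(0, nrow = length(vocab), ncol = dim)
  } else {
    .sgns_train(sent_ids, length(vocab), noise_cum, as.integer(dim),
                as.integer(window), as.integer(negative), as.integer(epochs),
                alpha, alpha * 1e-4, as.integer(seed))
  }
  rownames(vec) <- vocab
  new_embedding(vec, source_tag,
                config = list(dim = dim, window = window, min_count = min_count,
                              epochs = epochs, negative = negative,
                              alpha = alpha, seed = seed))
}

#' Document embedding by mean pooling
#'
#' Unweighted mean of the vectors of in-vocabulary tokens (lowercased);
#' documents with no in-vocabulary token get the all-zero vector. The
#' result is invariant to token order and to duplicating every token.
#'
#' @param doc tokenized document.
#' @param model a `readrank_embedding`.
#' @return numeric vector of length `model$dim`.
#' @export
embed_document <- function(doc, model) {
  stopifnot(inherits(model, "readrank_embedding"))
  assert_tokenized(doc)
  idx <- match(tolower(doc$tokens), rownames(model$vectors))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(numeric(model$dim))
  colMeans(model$vectors[idx, , drop = FALSE])
}
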