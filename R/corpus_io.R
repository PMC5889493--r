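# Readers and writers for every on-disk artifact: document corpora
# (directory of .txt + manifest.csv), ratings tables, word-frequency
# tables, easy-word lists, word vectors in the standard text format, and
# serialized rank models. All downstream modules consume only the types
# constructed here.

DOC_SOURCES <- c("wikipedia", "ehr")
DOC_TOPICS  <- c("cancer", "diabetes", "hypertension", "other")

#' Construct a document
#'
#' @param doc_id unique identifier string.
#' @param text raw document text.
#' @param source `"wikipedia"` or `"ehr"`.
#' @param topic one of `"cancer"`, `"diabetes"`, `"hypertension"`, `"other"`.
#' @return a `readrank_document`; `tokens`/`sentences` are unset until
#'   [tokenize()] is called.
#' @export
document <- function(doc_id, text, source = "wikipedia", topic = "other") {
  if (!source %in% DOC_SOURCES)
    rr_error("readrank_bad_metadata", sprintf("unknown source '%s'", source))
  if (!topic %in% DOC_TOPICS)
    rr_error("readrank_bad_metadata", sprintf("unknown topic '%s'", topic))
  structure(
    list(doc_id = as.character(doc_id), text = text, source = source,
         topic = topic, tokens = NULL, sentences = NULL),
    class = "readrank_document"
  )
}

#' @export
print.readrank_document <- function(x, ...) {
  cat(sprintf("<document %s> source=%s topic=%s, %s\n", x$doc_id, x$source,
              x$topic,
              if (is.null(x$tokens)) "not tokenized"
              else sprintf("%d tokens, %d sentences", length(x$tokens),
                           nrow(x$sentences))))
  invisible(x)
}

#' Read a corpus from a directory of text files plus a manifest
#'
#' The manifest is a CSV with columns `doc_id,source,topic,filename`; each
#' filename is resolved relative to `path`.
#'
#' @param path directory holding one UTF-8 plain-text file per document.
#' @param manifest path to `manifest.csv` (default `file.path(path,
#'   "manifest.csv")`), or a data.frame with the same columns.
#' @return named list of `readrank_document` (names = doc_id), untokenized.
#' @export
read_corpus <- function(path, manifest = file.path(path, "manifest.csv")) {
  man <- if (is.data.frame(manifest)) manifest else {
    if (!file.exists(manifest))
      rr_error("readrank_missing_file", sprintf("manifest not found: %s", manifest))
    read.csv(manifest, stringsAsFactors = FALSE, colClasses = "character")
  }
  need <- c("doc_id", "source", "topic", "filename")
  if (!all(need %in% names(man)))
    rr_error("readrank_bad_manifest",
             sprintf("manifest must have columns %s", paste(need, collapse = ",")))
  if (anyDuplicated(man$doc_id))
    rr_error("readrank_bad_manifest", "duplicate doc_id in manifest")
  docs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(path, man$filename[i])
    if (!file.exists(f))
      rr_error("readrank_missing_file",
               sprintf("no file for doc_id '%s': %s", man$doc_id[i], f))
    txt <- paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    docs[[i]] <- document(man$doc_id[i], txt, man$source[i], man$topic[i])
  }
  names(docs) <- man$doc_id
  docs
}

#' Write a corpus and manifest to a directory
#'
#' @param docs named list of `readrank_document`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(
    doc_id = vapply(docs, `[[`, "", "doc_id"),
    source = vapply(docs, `[[`, "", "source"),
    topic = vapply(docs, `[[`, "", "topic"),
    filename = paste0(vapply(docs, `[[`, "", "doc_id"), ".txt"),
    stringsAsFactors = FALSE
  )
  for (d in docs) {
    writeLines(d$text, file.path(path, paste0(d$doc_id, ".txt")), useBytes = TRUE)
  }
  write.csv(man, file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a ratings table
#'
#' Expects a delimited file (or data.frame) with header
#' `rater_id,pair_id,doc_id,rating`. A (rater_id, pair_id) group in the
#' input that does not contain exactly 2 distinct documents is a hard
#' error (structural corruption). Rows whose rating is outside 1-10 are
#' then dropped with a warning and counted in the `n_rejected` attribute;
#' the orphaned partner of a rejected row is dropped too, preserving pair
#' integrity.
#'
#' @param path CSV path or data.frame.
#' @return data.frame of validated rating records with attribute
#'   `n_rejected`.
#' @export
read_ratings <- function(path) {
  r <- if (is.data.frame(path)) path else {
    if (!file.exists(path))
      rr_error("readrank_missing_file", sprintf("ratings file not found: %s", path))
    read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("rater_id", "pair_id", "doc_id", "rating")
  if (!all(need %in% names(r)))
    rr_error("readrank_bad_ratings",
             sprintf("ratings must have columns %s", paste(need, collapse = ",")))
  r <- r[need]
  r$rater_id <- as.character(r$rater_id)
  r$pair_id <- as.character(r$pair_id)
  r$doc_id <- as.character(r$doc_id)
  r$rating <- suppressWarnings(as.integer(r$rating))
  # structural pair-arity check on the raw input: corruption is fatal
  if (nrow(r) > 0) {
    key <- paste(r$rater_id, r$pair_id, sep = "\r")
    arity <- tapply(r$doc_id, key, function(d) length(unique(d)))
    if (any(arity != 2L)) {
      offender <- names(arity)[arity != 2L][1]
      rr_error("readrank_bad_pair",
               sprintf("pair group '%s' has %d distinct documents (need 2)",
                       gsub("\r", "/", offender), arity[arity != 2L][1]))
    }
  }
  bad <- is.na(r$rating) | r$rating < 1L | r$rating > 10L
  if (any(bad)) {
    rr_warn("readrank_rejected_ratings",
            sprintf("rejected %d rating row(s) outside 1-10", sum(bad)))
    r <- r[!bad, , drop = FALSE]
    # a rejected row orphans its pair partner; keep pair integrity
    key <- paste(r$rater_id, r$pair_id, sep = "\r")
    sizes <- table(key)
    r <- r[key %in% names(sizes)[sizes == 2L], , drop = FALSE]
  }
  rownames(r) <- NULL
  structure(r, n_rejected = sum(bad))
}

#' Write a ratings table to CSV
#' @param ratings data.frame of rating records.
#' @param path output file.
#' @export
write_ratings <- function(ratings, path) {
  write.csv(ratings[c("rater_id", "pair_id", "doc_id", "rating")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read a token frequency table (`token<TAB>count`)
#' @param path TSV path.
#' @return named numeric vector of counts (names = tokens).
#' @export
read_frequency_counts <- function(path) {
  tab <- read.delim(path, header = FALSE, col.names = c("token", "count"),
                    stringsAsFactors = FALSE, quote = "")
  counts <- as.numeric(tab$count)
  names(counts) <- as.character(tab$token)
  if (any(counts < 0) || anyNA(counts))
    rr_error("readrank_bad_frequency_table", "negative or missing counts")
  counts
}

#' Write a token frequency table
#' @param counts named numeric vector.
#' @param path output TSV.
#' @export
write_frequency_counts <- function(counts, path) {
  writeLines(paste(names(counts), format(counts, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Read an easy-word list (one word per line, case-insensitive lookup)
#' @param path text file.
#' @return `readrank_easy_words`: a character vector of lowercase words.
#' @export
read_easy_words <- function(path) {
  words <- tolower(trimws(readLines(path, warn = FALSE, encoding = "UTF-8")))
  words <- unique(words[nzchar(words)])
  if (length(words) == 0)
    rr_error("readrank_bad_easy_words", "easy-word list is empty")
  structure(words, class = "readrank_easy_words")
}

#' Build an easy-word list from a character vector
#' @param words character vector; lowercased and deduplicated.
#' @return `readrank_easy_words`.
#' @export
easy_words_from_vector <- function(words) {
  structure(unique(tolower(words)), class = "readrank_easy_words")
}

#' The bundled stand-in easy-word list
#'
#' A constructed list of ~900 common English words shipped with the
#' package. It is a synthetic stand-in for the New Dale-Chall 3000-word
#' list (which is not redistributed here); supply your own list via
#' [read_easy_words()] for faithful Dale-Chall percentages on real text.
#' @return `readrank_easy_words`.
#' @export
default_easy_words <- function() {
  read_easy_words(system.file("extdata", "easy_words_synthetic.txt",
                              package = "readrank", mustWork = TRUE))
}

#' Read word vectors in the standard text format
#'
#' First line `vocab_size dim`, then one `token v1 ... v_dim` per line.
#'
#' @param path file path.
#' @param source_tag `"wikipedia"` or `"ehr"` tag to attach.
#' @return a `readrank_embedding` (see [train_embedding()]).
#' @export
read_word_vectors <- function(path, source_tag = "wikipedia") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    rr_error("readrank_bad_vectors", "malformed word-vector header")
  n <- hdr[1]; dim <- hdr[2]
  if (length(lines) - 1L != n)
    rr_error("readrank_bad_vectors",
             sprintf("header promises %d vectors, file has %d", n, length(lines) - 1L))
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  toks <- vapply(parts, `[[`, "", 1L)
  mat <- matrix(NA_real_, nrow = n, ncol = dim, dimnames = list(toks, NULL))
  for (i in seq_len(n)) {
    v <- as.numeric(parts[[i]][-1])
    if (length(v) != dim || anyNA(v))
      rr_error("readrank_bad_vectors", sprintf("bad vector line for '%s'", toks[i]))
    mat[i, ] <- v
  }
  new_embedding(mat, source_tag)
}

#' Write word vectors in the standard text format
#' @param model a `readrank_embedding`.
#' @param path output file.
#' @export
write_word_vectors <- function(model, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(model$vectors), model$dim), con)
  for (i in seq_len(nrow(model$vectors))) {
    writeLines(paste(rownames(model$vectors)[i],
                     paste(rr_num(model$vectors[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Serialize a trained rank model to a single JSON file
#'
#' Weights are written at full precision (17 significant digits) so the
#' round-trip is bit-identical; the feature-layout version is stored and
#' checked on read, preventing scoring with a mismatched feature order.
#'
#' @param model a `readrank_model` from [train_ranker()] or [fit_ranker()].
#' @param path output file.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "readrank_model"))
  payload <- list(
    format = "readrank_model",
    layout_version = model$layout_version,
    c_tradeoff = rr_num(model$c_tradeoff),
    weights = rr_num(model$weights),
    center = if (is.null(model$center)) NULL else rr_num(model$center),
    scale = if (is.null(model$scale)) NULL else rr_num(model$scale),
    diagnostics = model$diagnostics,
    config = model$config
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized rank model
#'
#' @param path file written by [write_model()].
#' @param expected_layout optional layout-version string; a mismatch is a
#'   hard error.
#' @return a `readrank_model`.
#' @export
read_model <- function(path, expected_layout = NULL) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        rr_error("readrank_corrupt_model",
                                 sprintf("cannot parse model file: %s",
                                         conditionMessage(e))))
  if (!identical(payload$format, "readrank_model"))
    rr_error("readrank_corrupt_model", "not a readrank model file")
  if (!is.null(expected_layout) &&
      !identical(payload$layout_version, expected_layout))
    rr_error("readrank_layout_mismatch",
             sprintf("model layout '%s' does not match expected '%s'",
                     payload$layout_version, expected_layout))
  new_rank_model(
    weights = as.numeric(payload$weights),
    c_tradeoff = as.numeric(payload$c_tradeoff),
    layout_version = payload$layout_version,
    diagnostics = payload$diagnostics,
    center = if (is.null(payload$center)) NULL else as.numeric(payload$center),
    scale = if (is.null(payload$scale)) NULL else as.numeric(payload$scale),
    config = payload$config
  )
}
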