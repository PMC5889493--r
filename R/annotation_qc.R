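# Rater-behavior analytics: pairwise rater concordance over shared
# documents, conformity (a rater's mean W against all peers), eccentric
# rater flagging, the controversial-document screen (max rating
# difference), and dataset filtering for retraining.

#' Pairwise rater concordance
#'
#' For each pair of raters sharing at least 2 documents, with each rater
#' giving at least two distinct ratings on the shared set, the Kendall W
#' of their two orderings over that shared set. Pairs with fewer than 2
#' usable shared documents are omitted, not errors.
#'
#' @param ratings validated ratings data.frame.
#' @return a `readrank_conformity` report with `pairwise_w` (data.frame
#'   rater_i, rater_j, n_shared, w) and `raters`.
#' @export
pairwise_rater_concordance <- function(ratings) {
  raters <- sort(unique(ratings$rater_id))
  if (length(raters) < 2L)
    rr_error("readrank_bad_rankings", "need at least 2 raters")
  per_doc <- lapply(raters, function(rid) {
    rr <- ratings[ratings$rater_id == rid, , drop = FALSE]
    tapply(rr$rating, rr$doc_id, mean)
  })
  names(per_doc) <- raters
  out <- data.frame()
  for (i in seq_along(raters)[-length(raters)]) {
    for (j in (i + 1):length(raters)) {
      shared <- intersect(names(per_doc[[i]]), names(per_doc[[j]]))
      if (length(shared) < 2L) next
      a <- per_doc[[i]][shared]
      b <- per_doc[[j]][shared]
      if (length(unique(a)) < 2L || length(unique(b)) < 2L) next
      out <- rbind(out, data.frame(
        rater_i = raters[i], rater_j = raters[j], n_shared = length(shared),
        w = kendall_w(rbind(as.numeric(a), as.numeric(b))),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(pairwise_w = out, raters = raters),
            class = "readrank_conformity")
}

#' Conformity: per-rater mean W against all peers
#'
#' @param report a `readrank_conformity` from
#'   [pairwise_rater_concordance()].
#' @return named numeric vector (rater -> mean W over available pairs);
#'   raters with no usable pair are excluded with a warning.
#' @export
conformity <- function(report) {
  pw <- report$pairwise_w
  if (is.null(pw) || nrow(pw) == 0L) {
    rr_warn("readrank_no_peers",
            sprintf("%d rater(s) share no usable documents with any peer",
                    length(report$raters)))
    return(stats::setNames(numeric(0), character(0)))
  }
  vals <- c(tapply(c(pw$w, pw$w), c(pw$rater_i, pw$rater_j), mean))
  missing <- setdiff(report$raters, names(vals))
  if (length(missing))
    rr_warn("readrank_no_peers",
            sprintf("%d rater(s) share no usable documents with any peer",
                    length(missing)))
  vals[order(names(vals))]
}

#' Flag eccentric raters
#'
#' Raters whose conformity (mean W with peers) falls below the threshold;
#' the study this emulates used .5, with "highly conforming" at >= .7.
#'
#' @param report a `readrank_conformity`, or a conformity vector.
#' @param threshold conformity cutoff (default 0.5, strict `<`).
#' @return character vector of flagged rater ids.
#' @export
flag_eccentric <- function(report, threshold = 0.5) {
  conf <- if (inherits(report, "readrank_conformity")) conformity(report)
          else report
  names(conf)[conf < threshold]
}

#' Flag controversial documents
#'
#' Among documents rated by at least `min_raters` raters, those whose
#' maximum pairwise rating difference strictly exceeds
#' `max_diff_threshold` (so {3,9} with difference 6 is flagged, {3,8} with
#' difference 5 is not).
#'
#' @param ratings validated ratings data.frame.
#' @param min_raters minimum distinct raters per document (default 2).
#' @param max_diff_threshold flag when max difference > this (default 5).
#' @return list: `flagged` (doc ids), `max_diff` (named vector over all
#'   screened documents), `mean_max_diff`, `n_screened`.
#' @export
flag_controversial <- function(ratings, min_raters = 2L,
                               max_diff_threshold = 5) {
  n_raters <- tapply(ratings$rater_id, ratings$doc_id,
                     function(x) length(unique(x)))
  eligible <- names(n_raters)[n_raters >= min_raters]
  sub <- ratings[ratings$doc_id %in% eligible, , drop = FALSE]
  max_diff <- if (nrow(sub)) {
    c(tapply(sub$rating, sub$doc_id, function(x) max(x) - min(x)))
  } else numeric(0)
  list(flagged = names(max_diff)[max_diff > max_diff_threshold],
       max_diff = max_diff,
       mean_max_diff = if (length(max_diff)) mean(max_diff) else NA_real_,
       n_screened = length(max_diff))
}

#' Filter a ratings table for retraining
#'
#' Removes every rating touching a dropped rater or dropped document;
#' pairs reduced to a single document lose their remaining record too (a
#' lone rating has no within-pair context).
#'
#' @param ratings validated ratings data.frame.
#' @param drop_raters character vector of rater ids (may be empty).
#' @param drop_documents character vector of doc ids (may be empty).
#' @return filtered ratings data.frame.
#' @export
filter_study <- function(ratings, drop_raters = character(),
                         drop_documents = character()) {
  keep <- !(ratings$rater_id %in% drop_raters) &
          !(ratings$doc_id %in% drop_documents)
  out <- ratings[keep, , drop = FALSE]
  key <- paste(out$rater_id, out$pair_id, sep = "\r")
  sizes <- table(key)
  out <- out[key %in% names(sizes)[sizes == 2L], , drop = FALSE]
  if (length(unique(out$rater_id)) < 2L ||
      length(unique(out$doc_id)) < 4L)
    rr_error("readrank_untrainable",
             "filtering left < 2 raters or < 4 documents")
  rownames(out) <- NULL
  out
}
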