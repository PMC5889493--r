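# The evaluation protocol: Kendall coefficient of concordance (W) between
# each rater's difficulty ordering and the system's predicted ordering of
# that rater's documents, averaged over raters; a Flesch-Kincaid baseline
# under the identical protocol; Wilcoxon signed-rank comparison of the
# paired per-rater W values; stratified 60/20/20 splitting; and the
# feature-ablation harness.

#' Kendall coefficient of concordance (W)
#'
#' Tie-corrected W over m rankings of the same n items:
#' `W = 12 S / (m^2 (n^3 - n) - m * sum_j T_j)` where S is the squared
#' deviation of rank sums from their mean and `T_j = sum_g (t_g^3 - t_g)`
#' over each rater's tie groups. 1 = identical rankings; for two raters,
#' 0 = exactly reversed.
#'
#' @param scores an m x n numeric matrix (rows = raters, columns = items;
#'   any monotone score — ranks are taken per row with average ties), or a
#'   list of named numeric vectors over the same item set.
#' @return W in `[0, 1]`.
#' @export
kendall_w <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    items <- names(scores[[1]])
    if (is.null(items))
      rr_error("readrank_bad_rankings", "list input needs named vectors")
    for (s in scores) {
      if (!setequal(names(s), items))
        rr_error("readrank_bad_rankings", "rankings cover different item sets")
    }
    scores <- do.call(rbind, lapply(scores, function(s) s[items]))
  }
  scores <- as.matrix(scores)
  m <- nrow(scores); n <- ncol(scores)
  if (m < 2L) rr_error("readrank_bad_rankings", "need at least 2 rankings")
  if (n < 2L) rr_error("readrank_bad_rankings", "need at least 2 items")
  if (anyNA(scores)) rr_error("readrank_bad_rankings", "NA in rankings")
  R <- t(apply(scores, 1, rank, ties.method = "average"))
  Tj <- apply(R, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  Rsum <- colSums(R)
  S <- sum((Rsum - mean(Rsum))^2)
  denom <- m^2 * (n^3 - n) - m * sum(Tj)
  if (denom <= 0) return(1) # every rater ties everything: vacuous agreement
  min(max(12 * S / denom, 0), 1)
}

#' Per-rater concordance of a system's scores with human ratings
#'
#' For each rater, the system scores are restricted to that rater's rated
#' documents, both are ranked (rater ties get average ranks), and the
#' two-ranking Kendall W is computed. Raters with fewer than 2 distinctly
#' rated documents are excluded with a warning.
#'
#' @param system_scores named numeric vector of system scores (names =
#'   doc_id), or a function taking a character vector of doc_ids and
#'   returning such scores.
#' @param ratings validated ratings data.frame.
#' @return a `readrank_concordance` report: `per_rater_w`, `mean_w`,
#'   `n_raters`, `excluded_raters`.
#' @export
system_vs_rater_concordance <- function(system_scores, ratings) {
  raters <- unique(ratings$rater_id)
  per <- numeric(0)
  excluded <- character(0)
  for (rid in raters) {
    rr <- ratings[ratings$rater_id == rid, , drop = FALSE]
    per_doc <- tapply(rr$rating, rr$doc_id, mean)
    if (length(per_doc) < 2L || length(unique(per_doc)) < 2L) {
      excluded <- c(excluded, rid)
      next
    }
    ids <- names(per_doc)
    sys <- if (is.function(system_scores)) system_scores(ids)
           else system_scores[ids]
    if (anyNA(sys))
      rr_error("readrank_missing_features",
               sprintf("no system score for document '%s'",
                       ids[which(is.na(sys))[1]]))
    per[rid] <- kendall_w(rbind(rater = as.numeric(per_doc),
                                system = as.numeric(sys)))
  }
  if (length(excluded))
    rr_warn("readrank_excluded_raters",
            sprintf("excluded %d rater(s) with < 2 distinctly rated documents",
                    length(excluded)))
  if (length(per) == 0L)
    rr_error("readrank_bad_rankings", "no rater with usable ratings")
  structure(list(per_rater_w = per, mean_w = mean(per),
                 n_raters = length(per), excluded_raters = excluded),
            class = "readrank_concordance")
}

#' @export
print.readrank_concordance <- function(x, ...) {
  cat(sprintf("<concordance> mean W = %.3f over %d raters\n", x$mean_w,
              x$n_raters))
  if (!is.null(x$comparison))
    cat(sprintf("  baseline mean W = %.3f; Wilcoxon p = %.4g (%s at alpha=%g)\n",
                x$comparison$baseline_mean_w, x$comparison$p_value,
                if (x$comparison$significant) "significant" else "not significant",
                x$comparison$alpha))
  invisible(x)
}

#' Flesch-Kincaid baseline under the identical concordance protocol
#'
#' Uses the FKGL grade of each document as the difficulty score and runs
#' exactly the same per-rater W computation as
#' [system_vs_rater_concordance()].
#'
#' @param ratings validated ratings data.frame.
#' @param docs named list of documents covering all rated doc_ids.
#' @return a `readrank_concordance` report.
#' @export
fkgl_baseline_concordance <- function(ratings, docs) {
  ids <- unique(ratings$doc_id)
  missing <- setdiff(ids, names(docs))
  if (length(missing))
    rr_error("readrank_missing_features",
             sprintf("no document for rated doc_id '%s'", missing[1]))
  grades <- vapply(docs[ids], fkgl, 1.0)
  names(grades) <- ids
  system_vs_rater_concordance(grades, ratings)
}

#' Wilcoxon signed-rank comparison of paired per-rater W values
#'
#' Two-sided; exact distribution for 25 or fewer non-zero differences
#' (when untied), normal approximation with continuity correction
#' otherwise. All-zero differences give p = 1, not an error.
#'
#' @param w_system,w_baseline paired numeric vectors over the same raters
#'   (matched by name when both are named).
#' @param alpha significance level (default 0.05).
#' @return list `statistic`, `p_value`, `significant`, `n`.
#' @export
wilcoxon_compare <- function(w_system, w_baseline, alpha = 0.05) {
  if (!is.null(names(w_system)) && !is.null(names(w_baseline))) {
    common <- intersect(names(w_system), names(w_baseline))
    w_system <- w_system[common]
    w_baseline <- w_baseline[common]
  }
  if (length(w_system) != length(w_baseline))
    rr_error("readrank_bad_rankings", "unpaired W vectors")
  d <- w_system - w_baseline
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(statistic = 0, p_value = 1, significant = FALSE,
                n = length(d)))
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    stats::wilcox.test(w_system, w_baseline, paired = TRUE,
                       alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value < alpha, n = length(d))
}

#' Compare a system report against a baseline report
#'
#' Attaches the baseline mean W and the Wilcoxon comparison to the system
#' report's `comparison` field.
#' @param report system `readrank_concordance`.
#' @param baseline baseline `readrank_concordance`.
#' @param alpha significance level.
#' @return the system report with `comparison` filled in.
#' @export
compare_concordance <- function(report, baseline, alpha = 0.05) {
  wt <- wilcoxon_compare(report$per_rater_w, baseline$per_rater_w, alpha)
  report$comparison <- list(baseline_mean_w = baseline$mean_w,
                            wilcoxon_statistic = wt$statistic,
                            p_value = wt$p_value, alpha = alpha,
                            significant = wt$significant)
  report
}

#' Stratified train/development/test split
#'
#' Shuffles within each stratum and assigns documents so that per-stratum
#' partition sizes hit the proportions within one document (largest
#' remainder rounding). Deterministic given the seed.
#'
#' @param docs named list of documents (or a character vector of ids when
#'   `strata` is given explicitly).
#' @param proportions named numeric `c(train=, dev=, test=)` summing to 1.
#' @param stratum_key document field to stratify on (default `"topic"`),
#'   or a character vector of stratum labels parallel to `docs`.
#' @param seed integer seed.
#' @return a data.frame (doc_id, stratum, partition) — the split
#'   assignment; partitions are disjoint and exhaustive.
#' @export
stratified_split <- function(docs, proportions = c(train = 0.6, dev = 0.2,
                                                   test = 0.2),
                             stratum_key = "topic", seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-8)
    rr_error("readrank_bad_config", "split proportions must sum to 1")
  ids <- if (is.character(docs)) docs else vapply(docs, `[[`, "", "doc_id")
  strata <- if (length(stratum_key) == length(ids) && length(ids) > 1)
    stratum_key
  else if (is.character(docs)) rep("all", length(ids))
  else vapply(docs, `[[`, "", stratum_key)
  out <- data.frame(doc_id = character(0), stratum = character(0),
                    partition = character(0), stringsAsFactors = FALSE)
  withr_seed <- function(code) { # local RNG scope
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    code
  }
  withr_seed({
    for (st in unique(strata)) {
      sid <- ids[strata == st]
      n <- length(sid)
      if (n < 3L)
        rr_warn("readrank_small_stratum",
                sprintf("stratum '%s' has only %d document(s)", st, n))
      sid <- sample(sid)
      exact <- proportions * n
      base <- floor(exact)
      rem <- exact - base
      short <- n - sum(base)
      if (short > 0) {
        give <- order(-rem)[seq_len(short)]
        base[give] <- base[give] + 1
      }
      part <- rep(names(proportions), times = base)
      out <- rbind(out, data.frame(doc_id = sid, stratum = st,
                                   partition = part,
                                   stringsAsFactors = FALSE))
    }
  })
  rownames(out) <- NULL
  out
}

#' Restrict a ratings table to one split partition
#'
#' The split unit is the document: all ratings of a document follow it
#' into its partition, preventing train/test leakage through shared
#' documents.
#' @param ratings validated ratings data.frame.
#' @param split a split assignment from [stratified_split()].
#' @param partition `"train"`, `"dev"` or `"test"`.
#' @return the ratings rows whose document lies in the partition.
#' @export
split_ratings <- function(ratings, split, partition) {
  keep <- split$doc_id[split$partition == partition]
  ratings[ratings$doc_id %in% keep, , drop = FALSE]
}

#' Feature-ablation harness
#'
#' Retrains the system with whole feature groups removed (re-tuning C on
#' the development set each time) and reports the test-set mean W per
#' configuration alongside the full model.
#'
#' @param study a list with `docs`, `ratings`, `split`
#'   ([simulate_study()] output works directly), plus featurizer inputs:
#'   `frequency_table`, `easy_words`, `embedding_wiki`, `embedding_ehr`.
#' @param drop_groups list of character vectors, each a set of groups to
#'   drop from `c("frequency", "formula", "length", "embedding")`;
#'   default: each single group.
#' @param c_grid C grid for tuning.
#' @param seed integer seed.
#' @return data.frame (configuration, dropped, mean_w, n_features).
#' @export
ablation_run <- function(study,
                         drop_groups = list("frequency", "formula", "length",
                                            "embedding"),
                         c_grid = 10^(-3:3), seed = 1L) {
  configs <- c(list(character(0)), drop_groups)
  labels <- c("full", vapply(drop_groups, paste, "", collapse = "+"))
  res <- data.frame()
  for (k in seq_along(configs)) {
    fz <- build_featurizer(study$frequency_table,
                           easy_words = study$easy_words %||% default_easy_words(),
                           embedding_wiki = study$embedding_wiki,
                           embedding_ehr = study$embedding_ehr,
                           drop = configs[[k]])
    feats <- featurize_corpus(fz, study$docs)
    tr <- split_ratings(study$ratings, study$split, "train")
    dv <- split_ratings(study$ratings, study$split, "dev")
    te <- split_ratings(study$ratings, study$split, "test")
    m <- fit_ranker(feats, tr, dev_ratings = dv, c_grid = c_grid, seed = seed)
    rep <- suppressWarnings(
      system_vs_rater_concordance(score(m, feats), te))
    res <- rbind(res, data.frame(configuration = labels[k],
                                 dropped = paste(configs[[k]], collapse = "+"),
                                 mean_w = rep$mean_w,
                                 n_features = ncol(feats),
                                 best_c = m$c_tradeoff,
                                 stringsAsFactors = FALSE))
  }
  res
}
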