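# The pairwise ranking model. Per-rater difficulty ratings are reduced to
# feature difference vectors x' = x_harder - x_easier (never across
# raters: different raters' scales need not form one consistent ranking),
# and a linear max-margin scorer w is learned by solving
#   min_w 1/2 ||w||^2 + C sum max(0, 1 - w.x')
# with dual coordinate descent. No intercept is fitted: it cancels in
# differences and would be unidentifiable. Rating magnitude beyond its
# sign is ignored (a 9-vs-2 pair contributes like a 6-vs-5 pair).

new_rank_model <- function(weights, c_tradeoff, layout_version, diagnostics,
                           center = NULL, scale = NULL, config = NULL) {
  structure(list(weights = weights, c_tradeoff = c_tradeoff,
                 layout_version = layout_version, diagnostics = diagnostics,
                 center = center, scale = scale, config = config),
            class = "readrank_model")
}

#' @export
print.readrank_model <- function(x, ...) {
  cat(sprintf("<rank model %s> %d weights, C=%g, %d training examples, %d discordant\n",
              x$layout_version, length(x$weights), x$c_tradeoff,
              x$diagnostics$n_examples %||% NA,
              x$diagnostics$n_discordant_on_train %||% NA))
  invisible(x)
}

#' Generate pairwise training examples from ratings
#'
#' For each rater, one example per unordered pair of their rated documents
#' with *different* ratings, oriented so the difference vector is
#' x(harder) - x(easier) with label +1. No cross-rater pairs are formed.
#'
#' @param ratings validated ratings data.frame ([read_ratings()]).
#' @param features numeric matrix of document feature vectors, rownames =
#'   doc_id (see [featurize_corpus()]).
#' @return list with `diff` (matrix, one row per example), `rater_id`
#'   (provenance), and `layout_version`.
#' @export
generate_pairwise_examples <- function(ratings, features) {
  missing <- setdiff(unique(ratings$doc_id), rownames(features))
  if (length(missing))
    rr_error("readrank_missing_features",
             sprintf("no feature vector for rated document '%s'", missing[1]))
  hi <- integer(0); lo <- integer(0); who <- character(0)
  for (rid in unique(ratings$rater_id)) {
    rr <- ratings[ratings$rater_id == rid, , drop = FALSE]
    # a rater may rate the same document in two pairs; use its mean rating
    per_doc <- tapply(rr$rating, rr$doc_id, mean)
    ids <- names(per_doc)
    n <- length(ids)
    if (n < 2L) next
    cmb <- utils::combn(n, 2L)
    d <- per_doc[cmb[1, ]] - per_doc[cmb[2, ]]
    keep <- d != 0
    if (!any(keep)) next
    a <- cmb[1, keep]; b <- cmb[2, keep]; dd <- d[keep]
    harder <- ifelse(dd > 0, a, b)
    easier <- ifelse(dd > 0, b, a)
    hi <- c(hi, match(ids[harder], rownames(features)))
    lo <- c(lo, match(ids[easier], rownames(features)))
    who <- c(who, rep(rid, sum(keep)))
  }
  diff <- features[hi, , drop = FALSE] - features[lo, , drop = FALSE]
  rownames(diff) <- NULL
  list(diff = diff, rater_id = who,
       layout_version = attr(features, "layout_version"))
}

#' Train the ranking SVM on pairwise difference vectors
#'
#' Solves the no-intercept hinge-loss problem on the given difference
#' vectors (all labelled +1); the solver is equivalent to training on the
#' mirrored two-class set. Training diagnostics report the number of
#' discordant training pairs (w.diff <= 0) and the total slack.
#'
#' @param examples output of [generate_pairwise_examples()], or a plain
#'   numeric matrix of difference vectors.
#' @param C trade-off between margin size and training error (>= 0).
#' @param tol solver stopping tolerance on the projected gradient.
#' @param max_epochs solver epoch cap.
#' @param seed seed for the solver's coordinate permutation.
#' @return a `readrank_model` (no standardization; see [fit_ranker()] for
#'   the full pipeline).
#' @export
train_ranker <- function(examples, C = 1, tol = 1e-4, max_epochs = 1000L,
                         seed = 1L) {
  X <- if (is.matrix(examples)) examples else examples$diff
  layout <- if (is.matrix(examples)) attr(examples, "layout_version") %||% "raw"
            else examples$layout_version %||% "raw"
  if (is.null(X) || nrow(X) < 1L)
    rr_error("readrank_no_examples", "need at least one pairwise example")
  if (all(abs(X) < 1e-12))
    rr_error("readrank_degenerate_examples",
             "all difference vectors are zero; nothing to learn")
  if (C < 0) rr_error("readrank_bad_config", "C must be >= 0")
  fit <- .svm_dcd(X, rep(1, nrow(X)), C, as.integer(max_epochs), tol,
                  as.integer(seed))
  if (!fit$converged && fit$epochs >= max_epochs)
    rr_warn("readrank_solver", sprintf(
      "solver hit the epoch cap (%d) before tolerance %g", max_epochs, tol))
  w <- as.numeric(fit$weights)
  margins <- as.numeric(X %*% w)
  new_rank_model(
    weights = w, c_tradeoff = C, layout_version = layout,
    diagnostics = list(n_examples = nrow(X),
                       n_discordant_on_train = sum(margins <= 0),
                       total_slack = sum(pmax(0, 1 - margins)),
                       solver_epochs = fit$epochs,
                       converged = fit$converged)
  )
}

#' Score documents with a trained model
#'
#' A pure linear functional `w . x` (after applying the model's stored
#' standardization, if any); higher score = predicted more difficult.
#'
#' @param model a `readrank_model`.
#' @param features a feature vector, or a matrix with one row per document.
#' @return numeric score(s), named by doc_id when `features` has rownames.
#' @export
score <- function(model, features) {
  stopifnot(inherits(model, "readrank_model"))
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  layout <- attr(features, "layout_version")
  if (!is.null(layout) && !identical(layout, model$layout_version))
    rr_error("readrank_layout_mismatch",
             sprintf("features layout '%s' vs model layout '%s'",
                     layout, model$layout_version))
  if (ncol(X) != length(model$weights))
    rr_error("readrank_layout_mismatch",
             sprintf("feature length %d vs weight length %d",
                     ncol(X), length(model$weights)))
  if (!is.null(model$center))
    X <- sweep(X, 2, model$center, "-")
  if (!is.null(model$scale))
    X <- sweep(X, 2, model$scale, "/")
  s <- as.numeric(X %*% model$weights)
  names(s) <- rownames(X)
  if (is.matrix(features)) s else s[[1]]
}

#' Rank documents, most difficult first
#'
#' @param model a `readrank_model`.
#' @param features feature matrix with doc_id rownames.
#' @return data.frame (doc_id, score, rank) sorted by descending score,
#'   ties broken by doc_id lexicographic order.
#' @export
rank_documents <- function(model, features) {
  s <- score(model, features)
  ord <- order(-s, names(s), method = "radix")
  data.frame(doc_id = names(s)[ord], score = unname(s[ord]),
             rank = seq_along(s), stringsAsFactors = FALSE)
}

#' Tune the trade-off parameter C on a development set
#'
#' Trains one model per grid value and picks the C maximizing mean
#' per-rater Kendall W on the development ratings; ties go to the
#' smallest C.
#'
#' @param train_examples pairwise examples (already standardized if the
#'   pipeline standardizes; [fit_ranker()] handles this).
#' @param dev_ratings ratings restricted to development documents.
#' @param dev_features feature matrix covering the development documents,
#'   on the same scale as the training examples.
#' @param c_grid candidate C values (default `10^(-3:3)`).
#' @param ... passed to [train_ranker()].
#' @return list with `best_c`, `dev_w` (named mean W per grid value), and
#'   `models`.
#' @export
tune_c <- function(train_examples, dev_ratings, dev_features,
                   c_grid = 10^(-3:3), ...) {
  if (length(c_grid) == 0)
    rr_error("readrank_bad_config", "empty C grid")
  if (nrow(dev_ratings) == 0)
    rr_error("readrank_bad_config", "empty development set")
  c_grid <- sort(c_grid)
  models <- lapply(c_grid, function(C) train_ranker(train_examples, C = C, ...))
  dev_w <- vapply(models, function(m) {
    rep <- suppressWarnings(
      system_vs_rater_concordance(score(m, dev_features), dev_ratings))
    rep$mean_w
  }, 1.0)
  names(dev_w) <- as.character(c_grid)
  best <- which(dev_w >= max(dev_w) - 1e-12)[1] # ties -> smallest C
  list(best_c = c_grid[best], dev_w = dev_w, models = models)
}

#' Fit the full ranking pipeline from features and ratings
#'
#' Standardizes document features (z-score over the training documents,
#' constant columns left centered) and additionally divides each column
#' by the square root of its feature-block width (when the matrix carries
#' a `blocks` attribute from [featurize_corpus()]) so that a 200-wide
#' embedding block contributes the same aggregate variance as a 4-wide
#' formula block rather than drowning it. It then generates within-rater
#' pairwise difference vectors, optionally tunes C on a development set,
#' trains the final model, and stores the standardization in the model so
#' [score()] applies it transparently.
#'
#' @param features feature matrix over (at least) all rated documents.
#' @param train_ratings ratings used for difference-vector generation.
#' @param dev_ratings optional ratings for C tuning; when NULL, `C` is
#'   used as is.
#' @param C fixed trade-off when not tuning (default 1).
#' @param c_grid grid for tuning when `dev_ratings` is given.
#' @param ... passed to [train_ranker()].
#' @return a `readrank_model` with `center`, `scale`, and tuning info in
#'   `config`.
#' @export
fit_ranker <- function(features, train_ratings, dev_ratings = NULL, C = 1,
                       c_grid = 10^(-3:3), ...) {
  train_docs <- intersect(rownames(features), unique(train_ratings$doc_id))
  ctr <- colMeans(features[train_docs, , drop = FALSE])
  scl <- apply(features[train_docs, , drop = FALSE], 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  blocks <- attr(features, "blocks")
  if (!is.null(blocks) && sum(blocks) == ncol(features)) {
    scl <- scl * sqrt(rep(unname(blocks), unname(blocks)))
  }
  Z <- sweep(sweep(features, 2, ctr, "-"), 2, scl, "/")
  attr(Z, "layout_version") <- attr(features, "layout_version")
  ex <- generate_pairwise_examples(train_ratings, Z)
  tuning <- NULL
  if (!is.null(dev_ratings) && nrow(dev_ratings) > 0) {
    tuning <- tune_c(ex, dev_ratings, Z, c_grid = c_grid, ...)
    C <- tuning$best_c
  }
  m <- train_ranker(ex, C = C, ...)
  m$center <- ctr
  m$scale <- scl
  m$config <- list(tuned = !is.null(tuning),
                   c_grid = if (is.null(tuning)) NULL else as.numeric(names(tuning$dev_w)),
                   dev_w = if (is.null(tuning)) NULL else unname(tuning$dev_w))
  m
}
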