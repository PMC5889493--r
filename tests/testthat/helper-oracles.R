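# Independent oracles, deliberately written as plain loops so they share
# no code path with the implementation they check.

# Tie-corrected Kendall W straight from the rank-sum-variance definition;
# average ranks are computed by counting, not via rank().
brute_kendall_w <- function(x) {
  m <- nrow(x)
  n <- ncol(x)
  R <- matrix(0, m, n)
  for (j in 1:m) {
    for (i in 1:n) {
      less <- 0
      equal <- 0
      for (k in 1:n) {
        if (x[j, k] < x[j, i]) less <- less + 1
        if (x[j, k] == x[j, i]) equal <- equal + 1
      }
      R[j, i] <- less + (equal + 1) / 2
    }
  }
  Rsum <- numeric(n)
  for (i in 1:n) Rsum[i] <- sum(R[, i])
  S <- sum((Rsum - mean(Rsum))^2)
  TT <- 0
  for (j in 1:m) {
    for (v in unique(R[j, ])) {
      t <- sum(R[j, ] == v)
      TT <- TT + (t^3 - t)
    }
  }
  denom <- m^2 * (n^3 - n) - m * TT
  if (denom <= 0) return(1)
  12 * S / denom
}

# All weak orders (rankings with ties) of n items, as score vectors.
weak_orders <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  rec <- function(assigned, next_level) {
    k <- length(assigned)
    if (k == n) {
      out[[length(out) + 1L]] <<- assigned
      return()
    }
    for (lvl in seq_len(next_level)) {
      rec(c(assigned, lvl), max(next_level, lvl + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

# Hinge-loss primal objective of the no-intercept ranking SVM.
svm_objective <- function(w, X, C) {
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - as.numeric(X %*% w)))
}

# Grid-with-refinement minimizer of the primal over w in R^d, d <= 3.
# Coarse box, then repeated zoom around the incumbent.
grid_svm_oracle <- function(X, C, radius = NULL, steps = 13, zooms = 8) {
  d <- ncol(X)
  stopifnot(d <= 3)
  if (is.null(radius)) radius <- max(3, 3 * C * nrow(X))
  center <- rep(0, d)
  half <- radius
  best_w <- center
  best_f <- svm_objective(center, X, C)
  for (z in seq_len(zooms)) {
    axes <- lapply(seq_len(d), function(i)
      seq(center[i] - half, center[i] + half, length.out = steps))
    grid <- as.matrix(do.call(expand.grid, axes))
    vals <- apply(grid, 1, function(wrow) svm_objective(wrow, X, C))
    k <- which.min(vals)
    if (vals[k] < best_f) {
      best_f <- vals[k]
      best_w <- as.numeric(grid[k, ])
    }
    center <- best_w
    half <- half * 2.2 / (steps - 1) # keep neighbours of the incumbent
  }
  list(w = best_w, objective = best_f)
}
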