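# Shared internal helpers: classed conditions, seed fan-out, small checks.

rr_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "readrank_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

rr_warn <- function(class, message) {
  warning(structure(
    class = c(class, "readrank_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

#' Derive a stage seed from a global seed
#'
#' One global seed fans out to per-stage seeds through a stable string hash,
#' so individual pipeline stages can be re-run in isolation and still be
#' reproducible. The result is always a positive 32-bit integer.
#'
#' @param seed integer global seed.
#' @param stage character stage label, e.g. `"corpus"`, `"raters"`.
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h + 1)
}

# Fixed-precision double formatting that round-trips IEEE doubles exactly.
rr_num <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
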