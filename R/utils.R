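# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(msg) stop(structure(
  class = c("nursemkt_config_error", "error", "condition"),
  list(message = msg, call = NULL)
))

abort_domain <- function(msg) stop(structure(
  class = c("nursemkt_domain_error", "error", "condition"),
  list(message = msg, call = NULL)
))

abort_validation <- function(msg) stop(structure(
  class = c("nursemkt_validation_error", "error", "condition"),
  list(message = msg, call = NULL)
))

# categorical sampler from a named probability vector
sample_cat <- function(n, probs) {
  stopifnot(!is.null(names(probs)))
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

check_dist <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort_config(sprintf("distribution '%s' must be non-negative and sum to 1", what))
  }
  invisible(p)
}

# round-half-up to one decimal, as in published percentage tables
round1 <- function(x) floor(x * 10 + 0.5) / 10
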