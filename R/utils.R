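# internal helpers shared across stages

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats qnorm pnorm quantile median sd cor var complete.cases
NULL

# stop with a classed condition so tests can target failures precisely
ps_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "plateletscore_error"), ...)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ps_abort(sprintf("`%s` must be a single finite number.", name),
             "ps_bad_argument")
  }
  if (x < lower || x > upper) {
    ps_abort(sprintf("`%s` must lie in [%s, %s], got %s.",
                     name, format(lower), format(upper), format(x)),
             "ps_bad_argument")
  }
  invisible(x)
}

# mid-rank (average rank), the rank convention used throughout
mid_rank <- function(x) rank(x, ties.method = "average")

# derive a stream-specific 31-bit seed from a master seed
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647L)
}

is_binary <- function(x) length(unique(x[!is.na(x)])) == 2L
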