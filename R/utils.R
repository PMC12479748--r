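#' @keywords internal
"_PACKAGE"

# Validation helpers shared across modules. Errors always name the offending
# field so callers can surface actionable messages.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    abort_field(field, sprintf("must be in [%s, %s], got %s", lower, upper, x))
  }
  x
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_field(field, "must be TRUE or FALSE")
  }
  x
}

check_odd <- function(x, field, min = 3) {
  check_number(x, field, lower = min)
  if (x %% 2 != 1) abort_field(field, "must be odd")
  as.integer(x)
}

#' Derive a child RNG seed from a base seed and a stream label
#'
#' All stochastic stages draw their seeds through this helper so that a single
#' pipeline seed reproduces every artifact. Kept below 2^31 - 1.
#' @param seed integer base seed.
#' @param stream character label of the consuming stage.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Moving average with edge shrinkage (window clipped at the borders).
moving_mean <- function(x, w) {
  n <- length(x)
  w <- max(1L, as.integer(w))
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
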