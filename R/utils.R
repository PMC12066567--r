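#' Min-max normalize a numeric vector to [0, 1]
#'
#' Rescales a vector as `(v - min) / (max - min)`. Constant vectors carry no
#' signal and map to all zeros rather than producing `0/0`; `NA` entries are
#' ignored for the range and preserved in the output.
#'
#' @param v Numeric vector, length >= 1.
#' @return Numeric vector of the same length with non-`NA` values in [0, 1].
#' @examples
#' minmax_normalize(c(1, 2, 3))   # 0.0 0.5 1.0
#' minmax_normalize(c(5, 5, 5))   # 0 0 0
#' @export
minmax_normalize <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 1L)
  ok <- !is.na(v)
  if (!any(ok)) return(v)
  lo <- min(v[ok])
  hi <- max(v[ok])
  if (hi == lo) {
    v[ok] <- 0
    return(v)
  }
  (v - lo) / (hi - lo)
}

# row-wise min-max over a matrix, NA-aware
.rowwise_minmax <- function(m) {
  out <- t(apply(m, 1L, minmax_normalize))
  dimnames(out) <- dimnames(m)
  out
}

# log transform then min-max, shared by the count-based evidence scores
.log_minmax <- function(x, offset) {
  minmax_normalize(log(x + offset))
}

# deterministic small-integer stream seed from a base seed and string keys;
# stays below 2^31 so set.seed() accepts it on all platforms
.stream_seed <- function(seed, ...) {
  keys <- vapply(list(...), as.character, character(1L))
  h <- 0
  for (k in keys) {
    for (ch in utf8ToInt(k)) h <- (h * 131 + ch) %% 1999999973
  }
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

.assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  invisible(x)
}

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  invisible(x)
}
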