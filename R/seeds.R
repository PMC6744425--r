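#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams (e.g. `"patterns"`, `"behavior"`, `"images"`), so that each
#' component can be regenerated independently and deterministically. The
#' derivation is a small string hash, stable across platforms and R sessions.
#'
#' @param seed Integer root seed.
#' @param ... Character or integer tokens naming the substream
#'   (e.g. `"patterns", subject_id`).
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' substream_seed(1, "patterns", 3)
#' @export
substream_seed <- function(seed, ...) {
  tokens <- vapply(list(...), function(x) paste0(as.character(x), collapse = "/"),
                   character(1))
  h <- as.double(seed %% 2147483629L)
  for (tok in tokens) {
    for (ch in utf8ToInt(tok)) {
      h <- (h * 31 + ch) %% 2147483629
    }
  }
  as.integer(h) + 1L
}

# Evaluate code under a derived substream seed, restoring RNG state after.
with_substream <- function(seed, ..., code) {
  withr::with_seed(substream_seed(seed, ...), code)
}
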