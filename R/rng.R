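#' Derive a reproducible sub-seed from a root seed
#'
#' All pipeline stages draw their randomness from named substreams of a
#' single root seed, so each stage is independently replayable. The
#' derivation hashes the root seed together with a stream name and index
#' into a 31-bit integer.
#'
#' @param root integer root seed.
#' @param stream character stream name (e.g. `"cohort"`, `"session"`).
#' @param index optional non-negative integer distinguishing repeated uses
#'   of the same stream (e.g. observer index).
#' @return an integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @examples
#' substream_seed(1, "cohort")
#' substream_seed(1, "session", 7)
#' @export
substream_seed <- function(root, stream, index = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stream))
  # simple polynomial string hash, kept in double precision below 2^31
  h <- (as.numeric(root) %% 2147483647) + 1
  chars <- utf8ToInt(paste0(stream, ":", format(index, scientific = FALSE)))
  for (ch in chars) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Run expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
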