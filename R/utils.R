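#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Deterministic 31-based string hash folded into [0, 2^31 - 2].
# Used to derive independent RNG substreams from a base seed plus a
# human-readable stream name, so adding e.g. a replicate never perturbs
# the draws of existing streams.
.hash_stream <- function(key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Derive a named RNG substream seed
#'
#' Combines a base seed with a stream name (any number of components,
#' pasted with "/") into a deterministic 32-bit seed. Streams with
#' different names are effectively independent; the same (seed, name)
#' pair always yields the same substream.
#'
#' @param seed Integer base seed.
#' @param ... Character/numeric components naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(..., sep = "/")
  (.hash_stream(key) + (as.double(seed) %% 2147483647) * 31) %% 2147483647
}

# Run code with a temporary RNG state seeded from (seed, name...).
.with_substream <- function(seed, ..., code) {
  withr::with_seed(as.integer(substream_seed(seed, ...)), code)
}

.stop_if_not_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
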