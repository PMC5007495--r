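#' Derive a named random seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' per-stage streams, so any stage can be re-run in isolation and
#' reproduce its output. The derivation is a small multiplicative string
#' hash folded into the root seed modulo 2^31 - 1 (all arithmetic stays
#' below 2^53, so it is exact in doubles).
#'
#' @param seed integer root seed.
#' @param tag character stream name (e.g. `"manifest"`, `"image/RF/3"`).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(as.character(tag))) h <- (h * 31 + c) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Stable hash of a configuration object
#'
#' Multiplicative string hash over the canonical JSON serialisation; used
#' to stamp output files so persisted results can be traced to the exact
#' configuration that produced them.
#'
#' @param x any jsonlite-serialisable object.
#' @return 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  m <- 2147483647
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% m
  sprintf("%08x", as.integer(h))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
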