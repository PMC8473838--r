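# RNG hygiene: all simulator entry points take an explicit seed and leave the
# caller's RNG state untouched. Named substreams are derived from a root seed
# so pipeline stages are independently reproducible.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named substream seed from a root seed
#'
#' Deterministically maps (root seed, label) to a new 31-bit seed so that
#' pipeline stages draw from independent, individually reproducible streams.
#'
#' @param seed integer root seed
#' @param label character stream label (e.g. `"timing"`, `"eeg/pair3"`)
#' @return an integer seed in `[0, 2^31)`
#' @export
substream_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(label, ":", as.integer(seed)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}
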