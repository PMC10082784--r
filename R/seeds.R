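#' Derive a named substream seed from a master seed
#'
#' All stochastic stages (cohort, ratings, scores, bootstrap, audit) draw
#' their seeds from one master seed through named substreams, so any stage is
#' reproducible in isolation without replaying the stages before it. The
#' derivation is a small deterministic string hash folded into the master
#' seed modulo 2^31 - 1; it is stable across platforms and R versions.
#'
#' @param seed integer master seed.
#' @param stream character scalar naming the substream (e.g. `"ratings"`).
#' @return a positive integer seed below 2^31.
#' @examples
#' substream_seed(1, "cohort")
#' substream_seed(1, "ratings")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed),
            is.character(stream), length(stream) == 1)
  m <- 2147483647 # 2^31 - 1, keeps products within double precision
  s <- abs(as.numeric(seed)) %% m
  for (ch in utf8ToInt(stream)) {
    s <- (s * 31 + ch) %% m
  }
  as.integer(s + 1)
}
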