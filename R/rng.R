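## Named RNG streams.
##
## A campaign draws randomness for ideation, oracle noise, and selection from
## separate streams so that, e.g., changing the noise level never perturbs the
## ideation sequence. Each stream is an independently seeded Mersenne state;
## substream seeds are derived from the campaign seed by integer mixing.

## SplitMix-style 32-bit mixer, done in double arithmetic (exact below 2^53).
.mixSeed <- function(seed, k) {
  x <- (as.numeric(seed) + 1111111111 * as.numeric(k)) %% 2147483647
  for (i in 1:3) x <- (x * 48271) %% 2147483647
  as.integer(x)
}

#' Create a set of named random-number streams
#'
#' Streams keep their own `.Random.seed` state so that draws on one stream
#' never perturb another. Used to isolate ideation randomness from oracle
#' noise and selection randomness within a campaign.
#'
#' @param seed integer master seed.
#' @param names character vector of stream names.
#' @return an environment holding one saved RNG state per stream.
#' @export
rngStreams <- function(seed, names = c("ideation", "noise", "selection")) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  for (i in seq_along(names)) {
    set.seed(.mixSeed(seed, i), kind = "Mersenne-Twister")
    assign(names[i], get(".Random.seed", globalenv()), envir = env)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  env
}

#' Evaluate an expression using a named stream
#'
#' Swaps the stream's saved state into `.Random.seed`, runs `expr`, saves the
#' advanced state back, and restores the global state.
#'
#' @param streams environment from [rngStreams()].
#' @param name stream name.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withStream <- function(streams, name, expr) {
  if (!exists(name, envir = streams, inherits = FALSE))
    stop("unknown RNG stream: ", name)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = streams)
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  expr
}
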