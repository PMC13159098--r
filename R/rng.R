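# Named random substreams derived from one master seed.
#
# Every source of randomness in the package draws from a stream obtained as
# make_rng(seed, "stage-name"), so that changing one stage's draws never
# shifts another's, and a single --seed reproduces an entire run.

hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

substream_seed <- function(seed, name) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + hash_string(name)) %% 2147483647)
}

#' Create a named random substream
#'
#' Returns a set of draw functions backed by an isolated RNG state seeded
#' from `(seed, name)`. Draws from a stream never touch, and are never
#' affected by, the global RNG state or other streams.
#'
#' @param seed Master integer seed.
#' @param name Stream name (e.g. `"pretrain-bulk"`).
#' @return List of functions `runif`, `rnorm`, `rpois`, `sample_int`,
#'   `shuffle`.
#' @keywords internal
make_rng <- function(seed, name = "default") {
  state_env <- new.env(parent = emptyenv())
  with_stream <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    if (is.null(state_env$state)) {
      set.seed(substream_seed(seed, name))
    } else {
      assign(".Random.seed", state_env$state, globalenv())
    }
    res <- expr
    state_env$state <- get(".Random.seed", globalenv())
    res
  }
  list(
    runif = function(n, min = 0, max = 1) with_stream(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_stream(stats::rnorm(n, mean, sd)),
    rpois = function(n, lambda) with_stream(stats::rpois(n, lambda)),
    sample_int = function(n, size = n, replace = FALSE)
      with_stream(sample.int(n, size, replace)),
    shuffle = function(x) with_stream(x[sample.int(length(x))])
  )
}
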