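#' Derive a reproducible substream seed
#'
#' One global integer seed drives every random stage of the toolkit; each
#' stage (and each item within a stage) gets its own derived seed so stages
#' can run independently, in parallel, or be re-run in isolation without
#' disturbing one another's streams.
#'
#' @param seed integer master seed.
#' @param stream character stream name (e.g. `"render"`, `"epoch"`).
#' @param index nonnegative integer item index within the stream.
#' @return a single integer in `[1, 2^31 - 20]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "render", 5)
#' @export
derive_seed <- function(seed, stream, index = 0) {
  m <- 2147483629  # prime below 2^31; keeps arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(stream)) h <- (h * 31 + c) %% m
  h <- (h * 1000003 + as.numeric(index)) %% m
  as.integer(h + 1)
}

# evaluate expr under a local RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
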