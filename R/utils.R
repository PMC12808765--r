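#' @import methods
#' @importFrom stats quantile rnbinom rnorm runif rexp rbinom rlnorm
#'   p.adjust pt t.test wilcox.test ks.test cor median setNames sd var
#'   kmeans uniroot pexp
#' @importFrom utils head read.delim write.table
NULL

## Named RNG substreams: every stochastic operation draws from a stream
## derived from (seed, stream-name) so partial pipelines are reproducible
## and generators do not perturb each other or the caller's RNG state.

.substreamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  ## keep well inside 32-bit integer range
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587L) + 1L
}

withSubstream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.substreamSeed(seed, stream))
  force(code)
}

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
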