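#' @importFrom rlang abort warn %||%
#' @importFrom stats cor dnorm lm coef rnorm rpois runif sd var
NULL

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. `seed = NULL` uses the current stream.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream label,
# keeping the result inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

# Count events in the half-open window [t0, t1).
count_in_window <- function(times, t0, t1) {
  sum(times >= t0 & times < t1)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
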