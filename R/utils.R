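#' @useDynLib taskconn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov coef convolve cor dgamma filter lm median
#'   p.adjust predict pt qbinom qnorm qt quantile rnorm runif sd
#'   setNames t.test var
#' @importFrom utils head read.delim tail write.csv read.csv write.table
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stream child seed below 2^31, derived from a master
# seed and a stream index (distinct streams for subjects, runs, stages).
derive_seed <- function(master, stream) {
  master <- as.double(master)
  stream <- as.double(stream)
  ((master * 69069 + stream * 104729 + 12345) %% 2147483629) + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name))
  invisible(x)
}
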