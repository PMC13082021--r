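# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Seeds the global RNG, evaluates `code`, and restores the previous RNG
#' state so callers never perturb the session stream.
#'
#' @param seed integer seed, or `NULL` to evaluate without reseeding.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive independent 32-bit substream seeds from a base seed: drawn from a
# master stream seeded once, so nearby base seeds or stream indices do not
# produce correlated streams.
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

substream_seed <- function(seed, stream) {
  substream_seeds(seed, stream)[stream]
}

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
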