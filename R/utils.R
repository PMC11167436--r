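#' @keywords internal
"_PACKAGE"

## Argument checking helpers ------------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_invalid("`%s` must be a single integer >= %d (got %s)",
                 name, min, paste(format(x), collapse = ","))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_invalid("`%s` must be in [%g, %g]", name, lo, hi)
  as.numeric(x)
}

## Seed substreams -----------------------------------------------------------

#' Derive a reproducible substream seed
#'
#' Generators take one user-facing seed and derive independent per-stream
#' seeds by a fixed counter scheme, so adding a new random stream to a
#' generator never perturbs the existing ones. The map is
#' `(seed * 48271 + 7919 * stream) mod (2^31 - 1)`.
#'
#' @param seed integer master seed.
#' @param stream integer stream counter (>= 0).
#' @return an integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  seed <- check_count(seed, "seed", min = 0L)
  stream <- check_count(stream, "stream", min = 0L)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
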