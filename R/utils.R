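# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps generators reproducible without
# clobbering the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Stable non-negative integer (< 2^31) derived from a base seed and a string
# key. Order-independent across cohort iteration: depends only on the key
# content, so shuffling subject order cannot change per-subject streams.
derive_seed <- function(base_seed, key) {
  h <- 0
  for (v in utf8ToInt(as.character(key))) h <- (h * 31 + v) %% 2147483647
  as.integer((as.numeric(base_seed) %% 2147483647 * 2654435 + h) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
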