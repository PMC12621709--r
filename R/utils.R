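## Internal helpers: validation and seeded sub-stream derivation.

.stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

.check_number <- function(x, field, positive = TRUE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stop_config(field, "must be a single finite number")
  if (positive && x <= 0) .stop_config(field, "must be strictly positive")
  if (integer && x != round(x)) .stop_config(field, "must be an integer")
  invisible(x)
}

#' Stable 31-bit string hash
#'
#' Deterministic polynomial rolling hash of a character string, used to derive
#' per-cell random substreams that do not depend on cell order. Not
#' cryptographic; stable across platforms and sessions.
#'
#' @param x character vector.
#' @return integer vector in `[0, 2^31 - 1)`.
#' @keywords internal
stableHash <- function(x) {
  mod <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% mod
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

## Seed for a per-entity substream: combine the master seed with a stable
## hash of the entity id, staying inside 32-bit integer range.
.substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stableHash(id))) %% 2147483647)
}

## Evaluate `expr` under a local RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
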