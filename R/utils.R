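# Internal helpers shared across modules.

# Derive an independent RNG substream seed from (seed, operation name).
# Each generator call seeds its own stream so reusing one config across
# generators never cross-contaminates draws. Horner polynomial hash of the
# operation name folded with the user seed, kept in exact double range.
deriveSeed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(op) == 1L)
  h <- 17
  for (b in utf8ToInt(op)) h <- (h * 31 + b) %% (2^31 - 1)
  as.integer((h * 2971 + as.numeric(seed) * 7919) %% (2^31 - 1))
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
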