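# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never disturb the
# session stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
    if (had_seed) old <- get(".Random.seed", envir = genv)
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = genv)
      } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}
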